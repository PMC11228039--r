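#' Per-gene fold change between two sample groups
#'
#' Computes, for every gene, the expression ratio of condition B over
#' condition A. Inputs are stored on the log2 scale, so by default the two
#' group means are anti-logged (`2^mean - 1`, undoing the `log2(g + 1)`
#' transform) before the ratio is taken
#' (`scale = "ratio_of_antilogged_means"`); `"ratio_of_means"` divides the
#' log2-scale means directly. A zero denominator yields `Inf` with a
#' warning.
#'
#' @param expr Log2-scale expression tibble.
#' @param group_a,group_b Character vectors of sample ids (condition A is
#'   the reference denominator, e.g. the Normal group).
#' @param scale How to form the ratio.
#' @return A tibble with `gene_id`, `group_a_mean`, `group_b_mean` (log2
#'   scale), `fc` and `log_fc` (`group_b_mean - group_a_mean`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 5))
#' a <- cohort$annot$sample_id[cohort$annot$stage == "Normal"]
#' b <- cohort$annot$sample_id[cohort$annot$stage == "Definite AD"]
#' fold_change(cohort$expr, a, b)
#' @export
fold_change <- function(expr, group_a, group_b,
                        scale = c("ratio_of_antilogged_means",
                                  "ratio_of_means")) {
  scale <- match.arg(scale)
  check_expr(expr)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both sample groups must be non-empty.")
  }
  vals <- expr_values(expr)
  missing <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(missing)) {
    abort(paste0("Unknown sample id(s): ", paste(missing, collapse = ", ")))
  }
  mean_a <- rowMeans(vals[, group_a, drop = FALSE])
  mean_b <- rowMeans(vals[, group_b, drop = FALSE])
  if (scale == "ratio_of_antilogged_means") {
    num <- 2^mean_b - 1
    den <- 2^mean_a - 1
  } else {
    num <- mean_b
    den <- mean_a
  }
  fc <- num / den
  if (any(den == 0)) {
    warn(paste0(sum(den == 0), " gene(s) have zero condition-A expression; ",
                "fold change reported as Inf."))
    fc[den == 0] <- Inf
  }
  tibble::tibble(
    gene_id = rownames(vals),
    group_a_mean = unname(mean_a),
    group_b_mean = unname(mean_b),
    fc = unname(fc),
    log_fc = unname(mean_b - mean_a)
  )
}

#' Select genes by fold-change thresholds
#'
#' Keeps genes whose fold change is strictly greater than `upper` or
#' strictly less than `lower`. The defaults are the screen's published
#' cuts, 1.5 and 0.06; note their asymmetry (0.06 is far more extreme than
#' 1/1.5 ~ 0.67), which is kept verbatim rather than symmetrized — both
#' cuts are configurable.
#'
#' @param records Tibble from [fold_change()] (needs `gene_id`, `fc`).
#' @param upper,lower Positive thresholds, `lower < upper`.
#' @return Sorted character vector of selected gene ids.
#' @examples
#' recs <- tibble::tibble(gene_id = c("a", "b"), fc = c(2, 1.2))
#' select_by_fc(recs)
#' @export
select_by_fc <- function(records, upper = 1.5, lower = 0.06) {
  if (lower >= upper) abort("`lower` must be smaller than `upper`.")
  if (lower <= 0 || upper <= 0) abort("Thresholds must be positive.")
  sort(records$gene_id[records$fc > upper | records$fc < lower])
}

#' Moderated-t differential expression between two groups
#'
#' Fits the standard two-group linear model per gene with empirical-Bayes
#' variance moderation (the limma moderated t): per-gene variances are
#' shrunk toward a common prior estimated from all genes, and the
#' moderated statistic is referred to a t distribution with augmented
#' degrees of freedom. A plain per-gene Welch t (no shrinkage, Satterthwaite
#' degrees of freedom) is selectable with `method = "welch"`.
#'
#' @param expr Log2-scale expression tibble.
#' @param group_a,group_b Sample id vectors, each of size >= 2.
#' @param method `"limma"` (default) or `"welch"`.
#' @return An object of class `"hemo_deg_fit"`: use [tidy()] for the
#'   per-gene table (`gene_id`, `group_a_mean`, `group_b_mean`, `log_fc`,
#'   `t_stat`, `p_value`, `df`), [glance()] for the fit summary, and
#'   [autoplot()] for a volcano plot.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 6))
#' a <- cohort$annot$sample_id[cohort$annot$stage == "Normal"]
#' b <- cohort$annot$sample_id[cohort$annot$stage == "Definite AD"]
#' fit <- moderated_t(cohort$expr, a, b)
#' tidy(fit)
#' @export
moderated_t <- function(expr, group_a, group_b,
                        method = c("limma", "welch")) {
  method <- match.arg(method)
  check_expr(expr)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 samples.")
  }
  vals <- expr_values(expr)
  missing <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(missing)) {
    abort(paste0("Unknown sample id(s): ", paste(missing, collapse = ", ")))
  }
  a <- vals[, group_a, drop = FALSE]
  b <- vals[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)

  if (method == "limma") {
    m <- cbind(a, b)
    design <- cbind(intercept = 1,
                    group_b = rep(c(0, 1), c(ncol(a), ncol(b))))
    fit <- limma::eBayes(limma::lmFit(m, design))
    t_stat <- fit$t[, "group_b"]
    p_value <- fit$p.value[, "group_b"]
    df <- fit$df.total
    prior <- list(df_prior = fit$df.prior, var_prior = fit$s2.prior)
  } else {
    va <- apply(a, 1, var)
    vb <- apply(b, 1, var)
    se2 <- va / ncol(a) + vb / ncol(b)
    t_stat <- (mean_b - mean_a) / sqrt(se2)
    df <- se2^2 / ((va / ncol(a))^2 / (ncol(a) - 1) +
                     (vb / ncol(b))^2 / (ncol(b) - 1))
    p_value <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
    prior <- list(df_prior = NA_real_, var_prior = NA_real_)
  }

  structure(
    list(
      table = tibble::tibble(
        gene_id = rownames(vals),
        group_a_mean = unname(mean_a),
        group_b_mean = unname(mean_b),
        log_fc = unname(mean_b - mean_a),
        t_stat = unname(t_stat),
        p_value = unname(p_value),
        df = unname(df)
      ),
      method = method,
      n_a = length(group_a), n_b = length(group_b),
      df_prior = prior$df_prior, var_prior = prior$var_prior
    ),
    class = "hemo_deg_fit"
  )
}

#' @export
print.hemo_deg_fit <- function(x, ...) {
  cat("<hemo_deg_fit> ", nrow(x$table), " genes, ", x$n_a, " vs ", x$n_b,
      " samples, method: ", x$method, "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @rdname moderated_t
#' @param x,object A `"hemo_deg_fit"`.
#' @param ... Unused.
#' @method tidy hemo_deg_fit
#' @export
tidy.hemo_deg_fit <- function(x, ...) x$table

#' @rdname moderated_t
#' @param min_abs_logfc,max_p Significance cuts used for the `n_significant`
#'   column of `glance()` (the screen's published defaults).
#' @method glance hemo_deg_fit
#' @export
glance.hemo_deg_fit <- function(x, min_abs_logfc = 0.5, max_p = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_a = x$n_a, n_b = x$n_b,
    method = x$method,
    df_prior = x$df_prior,
    var_prior = x$var_prior,
    n_significant = length(select_by_lm(x, min_abs_logfc, max_p))
  )
}

#' Select genes by moderated-t significance
#'
#' Keeps genes with `|log_fc| >= min_abs_logfc` and `p_value <= max_p`
#' (both boundaries inclusive). No multiple-testing correction is applied
#' by default, matching the screen's published use of the raw p value; set
#' `adjust = "BH"` for a Benjamini-Hochberg-adjusted screen.
#'
#' @param records A `"hemo_deg_fit"` or its [tidy()] table.
#' @param min_abs_logfc,max_p Inclusive thresholds (defaults 0.5 and 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Sorted character vector of selected gene ids.
#' @export
select_by_lm <- function(records, min_abs_logfc = 0.5, max_p = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(records, "hemo_deg_fit")) records <- records$table
  p <- records$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sort(records$gene_id[abs(records$log_fc) >= min_abs_logfc & p <= max_p])
}

#' Intersect gene sets from independent screens
#'
#' The fold-change and moderated-t screens (and screens on independent
#' cohorts) are combined by set intersection; the result is sorted so it
#' does not depend on input order.
#'
#' @param sets A list of two or more character vectors of gene ids.
#' @return Sorted character vector of genes present in every set.
#' @examples
#' intersect_screens(list(c("HBB", "A"), c("HBB", "B")))
#' @export
intersect_screens <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    abort("`sets` must be a list of at least two gene sets.")
  }
  sort(Reduce(intersect, sets))
}

#' @method autoplot hemo_deg_fit
#' @export
autoplot.hemo_deg_fit <- function(object, min_abs_logfc = 0.5, max_p = 0.05,
                                  ...) {
  tab <- object$table |>
    dplyr::mutate(significant = abs(.data$log_fc) >= min_abs_logfc &
                    .data$p_value <= max_p)
  ggplot2::ggplot(tab, ggplot2::aes(.data$log_fc, -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_logfc,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(max_p),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant")
}
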