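#' Collapse duplicate gene rows to their per-sample median
#'
#' Microarray tables often carry several probes per gene symbol; following
#' standard practice each duplicated gene id is collapsed to the per-sample
#' median of its rows (the median of an even number of rows is the mean of
#' the central pair). With no duplicates the input is returned unchanged.
#'
#' @param expr Expression tibble (`gene_id` plus sample columns), raw or
#'   log2 scale.
#' @return Expression tibble with one row per gene id, original first-seen
#'   gene order preserved.
#' @examples
#' tbl <- tibble::tibble(gene_id = c("HBB", "HBB"), s1 = c(2, 4))
#' aggregate_duplicates(set_expr_scale(tbl, "raw"))
#' @export
aggregate_duplicates <- function(expr) {
  check_expr(expr)
  scale <- expr_scale(expr)
  if (!anyDuplicated(expr$gene_id)) return(expr)
  out <- expr |>
    dplyr::mutate(.order = match(.data$gene_id, unique(.data$gene_id))) |>
    dplyr::group_by(.data$.order, .data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), median),
                     .groups = "drop") |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order")
  if (!is.na(scale)) out <- set_expr_scale(out, scale)
  out
}

#' Log2-transform raw expression values
#'
#' Applies `g -> log2(g + 1)` to every value, turning multiplicative
#' expression differences into additive ones; the scale tag becomes
#' `"log2"`. Values already on the log2 scale must not be re-logged: the
#' function refuses input tagged `"log2"` or `"standardized"`.
#'
#' @param expr Expression tibble on the raw scale (values >= 0).
#' @return Log2-scale expression tibble.
#' @examples
#' tbl <- set_expr_scale(tibble::tibble(gene_id = "HBB", s1 = 7), "raw")
#' log2_transform(tbl)  # log2(8) = 3
#' @export
log2_transform <- function(expr) {
  check_expr(expr)
  scale <- expr_scale(expr)
  if (scale %in% c("log2", "standardized")) {
    abort(paste0("`expr` is already on the ", scale,
                 " scale; re-logging would corrupt it."))
  }
  vals <- expr_values(expr)
  if (any(vals < 0, na.rm = TRUE)) {
    abort("Raw expression values must be >= 0 for the log2(g + 1) transform.")
  }
  expr_from_values(log2(vals + 1), "log2")
}

#' Z-score expression per gene
#'
#' Standardizes each gene row (subtract mean, divide by standard
#' deviation) so that samples from different regions and subjects are
#' comparable. The default groups all samples together
#' (`mode = "per_gene_global"`), preserving between-region level
#' differences within each gene; `"per_gene_within_region"` standardizes
#' each gene separately inside every region (requires `annot`).
#' Zero-variance rows map to all zeros with a warning. The default uses
#' the sample (n-1) standard deviation, which makes standardization
#' idempotent; `sd_type = "population"` divides by the population (n)
#' standard deviation instead.
#'
#' @param expr Log2-scale expression tibble.
#' @param mode Grouping of samples for the z-score.
#' @param annot Sample annotation (needed for the within-region mode).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Expression tibble tagged `"standardized"`.
#' @export
standardize <- function(expr,
                        mode = c("per_gene_global", "per_gene_within_region"),
                        annot = NULL,
                        sd_type = c("sample", "population")) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  check_expr(expr)
  vals <- expr_values(expr)

  zscore_block <- function(m) {
    mu <- rowMeans(m)
    centred <- m - mu
    denom <- sqrt(rowSums(centred^2) /
                    (ncol(m) - if (sd_type == "sample") 1L else 0L))
    zero <- denom < .Machine$double.eps
    if (any(zero)) {
      warn(paste0(sum(zero), " zero-variance gene row(s) set to 0: ",
                  paste(head(rownames(m)[zero], 5), collapse = ", ")))
      denom[zero] <- 1
      centred[zero, ] <- 0
    }
    centred / denom
  }

  if (mode == "per_gene_global") {
    out <- zscore_block(vals)
  } else {
    if (is.null(annot) || is.null(annot$region)) {
      abort("Within-region standardization needs `annot` with a `region` column.")
    }
    check_alignment(expr, annot)
    out <- vals
    for (r in unique(annot$region)) {
      idx <- which(annot$region == r)
      out[, idx] <- zscore_block(vals[, idx, drop = FALSE])
    }
  }
  expr_from_values(out, "standardized")
}

#' Subset a cohort by region, stage or gene
#'
#' Returns the aligned (expression, annotation) views restricted to the
#' requested labels; any label absent from the data raises an error naming
#' the offender. `genes = hemoglobin_genes()` gives the three-row
#' hemoglobin panel.
#'
#' @param expr Expression tibble (or a `"hemo_cohort"`).
#' @param annot Sample annotation tibble (ignored when `expr` is a cohort).
#' @param regions,stages,genes Optional label vectors to keep.
#' @return A list of class `"hemo_cohort"` with the filtered `expr`, `annot`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 3))
#' hb <- subset_cohort(cohort, genes = hemoglobin_genes(), regions = "HC")
#' nrow(hb$expr)
#' @export
subset_cohort <- function(expr, annot = NULL, regions = NULL, stages = NULL,
                          genes = NULL) {
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  check_expr(expr)
  check_alignment(expr, annot)
  scale <- expr_scale(expr)

  check_known <- function(wanted, have, what) {
    missing <- setdiff(wanted, have)
    if (length(missing)) {
      abort(paste0("Unknown ", what, ": ", paste(missing, collapse = ", ")))
    }
  }
  keep <- rep(TRUE, nrow(annot))
  if (!is.null(regions)) {
    check_known(regions, unique(annot$region), "region(s)")
    keep <- keep & annot$region %in% regions
  }
  if (!is.null(stages)) {
    check_known(stages, unique(annot$stage), "stage(s)")
    keep <- keep & annot$stage %in% stages
  }
  annot <- annot[keep, , drop = FALSE]
  expr <- expr[, c("gene_id", annot$sample_id)]
  if (!is.null(genes)) {
    check_known(genes, expr$gene_id, "gene(s)")
    expr <- expr[match(genes, expr$gene_id), , drop = FALSE]
  }
  if (!is.na(scale)) expr <- set_expr_scale(expr, scale)
  structure(list(expr = expr, annot = annot), class = "hemo_cohort")
}
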