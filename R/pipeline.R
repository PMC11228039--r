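#' Region x stage summary of hemoglobin-subunit expression
#'
#' Mean, median and quartiles of each subunit's expression in every
#' (region, stage) cell — the table behind a box-and-whisker view of how
#' hemoglobin expression falls along the pathway as disease progresses.
#'
#' @param expr Expression tibble containing the subunit rows (or a
#'   `"hemo_cohort"`).
#' @param annot Sample annotation.
#' @param genes Genes to summarize (default the hemoglobin panel).
#' @return A tibble of class `"hemo_expr_summary"`: `region`, `stage`,
#'   `gene_id`, `n`, `mean`, `q1`, `median`, `q3`.
#' @export
summarize_expression <- function(expr, annot = NULL,
                                 genes = hemoglobin_genes()) {
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  check_expr(expr)
  check_alignment(expr, annot)
  missing <- setdiff(genes, expr$gene_id)
  if (length(missing)) {
    abort(paste0("Unknown gene(s): ", paste(missing, collapse = ", ")))
  }
  stage_order <- unique(annot$stage)
  long <- expr[match(genes, expr$gene_id), ] |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(annot[, c("sample_id", "region", "stage")],
                     by = "sample_id")
  out <- long |>
    dplyr::group_by(.data$region, .data$stage, .data$gene_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      q1 = unname(quantile(.data$value, 0.25)),
      median = median(.data$value),
      q3 = unname(quantile(.data$value, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_order)) |>
    dplyr::arrange(.data$region, .data$stage, .data$gene_id)
  class(out) <- c("hemo_expr_summary", class(out))
  out
}

#' @method autoplot hemo_expr_summary
#' @export
autoplot.hemo_expr_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$stage, .data$median,
                                       group = .data$gene_id,
                                       colour = .data$gene_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             position = ggplot2::position_dodge(width = 0.4),
                             fatten = 1.5) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "expression (median, IQR)",
                  colour = "subunit")
}

#' Run the full hemoglobin-coordination pipeline
#'
#' Orchestrates every stage on one cohort: (optionally) simulate, screen
#' for differential expression between the baseline and final stages
#' (fold change and moderated t, intersected), summarize subunit
#' expression per region and stage, compute the entropy grid, the
#' region-pair Pearson table over the pathway edges, and the NFT-binned
#' coordination trends. All randomness flows from the synthetic
#' configuration's seed, so identical configurations give identical
#' reports.
#'
#' @param cohort A `"hemo_cohort"` (e.g. from [generate_cohort()] or
#'   [read_cohort()]), or a `"synthetic_config"` to simulate first.
#' @param run_deg,run_entropy,run_coordination Stage switches.
#' @param fc_upper,fc_lower Fold-change screen cuts.
#' @param min_abs_logfc,max_p Moderated-t screen cuts.
#' @param n_bins NFT bins for the coordination trends.
#' @param pairing Pairing rule for [pair_regions_with_nft()].
#' @param out_dir Optional directory; when given, every table is written
#'   as TSV alongside a `config.txt` snapshot.
#' @return A list of class `"hemo_report"` with elements `counts`,
#'   `deg` (fit, gene sets and their intersection), `expression_summary`,
#'   `entropy`, `region_pair`, `nft_bins`, `config`.
#' @examples
#' report <- run_pipeline(synthetic_config(n_subjects_per_stage = 6))
#' report$counts
#' @export
run_pipeline <- function(cohort,
                         run_deg = TRUE, run_entropy = TRUE,
                         run_coordination = TRUE,
                         fc_upper = 1.5, fc_lower = 0.06,
                         min_abs_logfc = 0.5, max_p = 0.05,
                         n_bins = 10,
                         pairing = "all_pairs_within_stage",
                         out_dir = NULL) {
  if (inherits(cohort, "synthetic_config")) {
    cohort <- generate_cohort(cohort)
  }
  if (!inherits(cohort, "hemo_cohort")) {
    abort("`cohort` must be a hemo_cohort or a synthetic_config.")
  }
  expr <- cohort$expr
  annot <- cohort$annot
  stages <- unique(annot$stage)

  report <- list(config = cohort$config)
  report$counts <- annot |>
    dplyr::count(.data$region, .data$stage, name = "n_samples")

  if (run_deg) {
    baseline <- annot$sample_id[annot$stage == stages[1]]
    disease <- annot$sample_id[annot$stage %in% stages[-1]]
    fc <- fold_change(expr, baseline, disease)
    fit <- moderated_t(expr, baseline, disease)
    fc_set <- select_by_fc(fc, upper = fc_upper, lower = fc_lower)
    lm_set <- select_by_lm(fit, min_abs_logfc = min_abs_logfc, max_p = max_p)
    report$deg <- list(
      fold_change = fc, fit = fit,
      fc_genes = fc_set, lm_genes = lm_set,
      intersection = intersect_screens(list(fc_set, lm_set))
    )
  }

  report$expression_summary <- summarize_expression(expr, annot)

  if (run_entropy) {
    report$entropy <- entropy_profile(expr, annot, stages = stages)
  }

  if (run_coordination) {
    vectors <- hemo_vectors(expr, annot)
    edges <- pathway_edges()
    edges <- edges[edges$region_a %in% annot$region &
                     edges$region_b %in% annot$region, ]
    if (nrow(edges) > 0) {
      report$region_pair <- purrr::list_rbind(
        purrr::map2(edges$region_a, edges$region_b,
                    function(a, b) region_pair_pearson(vectors, a, b))
      )
      records <- pair_regions_with_nft(vectors, edges, pairing = pairing)
      report$pair_records <- records
      report$nft_bins <- summarize_vs_nft(records, n_bins = n_bins)
    }
  }

  class(report) <- "hemo_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write every report table as TSV
#'
#' @param report A `"hemo_report"`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(tbl, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }
  put(report$counts, "sample_counts")
  put(report$expression_summary, "expression_summary")
  if (!is.null(report$deg)) {
    put(tidy(report$deg$fit), "deg_moderated_t")
    put(report$deg$fold_change, "deg_fold_change")
    put(tibble::tibble(gene_id = report$deg$intersection), "deg_intersection")
  }
  if (!is.null(report$entropy)) put(report$entropy, "entropy_grid")
  if (!is.null(report$region_pair)) put(report$region_pair, "region_pair_pearson")
  if (!is.null(report$nft_bins)) {
    put(report$nft_bins$bins, "nft_bins")
    put(report$nft_bins$trends, "nft_trends")
  }
  cfg <- report$config
  if (!is.null(cfg)) {
    writeLines(
      vapply(names(cfg), function(nm) {
        paste0(nm, ": ", paste(format(cfg[[nm]], digits = 10), collapse = ", "))
      }, character(1)),
      file.path(out_dir, "config.txt")
    )
    paths <- c(paths, file.path(out_dir, "config.txt"))
  }
  invisible(paths)
}

#' @export
print.hemo_report <- function(x, ...) {
  cat("<hemo_report>\n")
  cat("  samples: ", sum(x$counts$n_samples), " over ",
      length(unique(x$counts$region)), " regions x ",
      length(unique(x$counts$stage)), " stages\n", sep = "")
  if (!is.null(x$deg)) {
    cat("  DEG: ", length(x$deg$fc_genes), " by fold change, ",
        length(x$deg$lm_genes), " by moderated t, ",
        length(x$deg$intersection), " in the intersection",
        if (length(x$deg$intersection)) {
          paste0(" (", paste(head(x$deg$intersection, 6), collapse = ", "), ")")
        } else "",
        "\n", sep = "")
  }
  if (!is.null(x$entropy)) {
    rng <- range(x$entropy$shannon_bits, na.rm = TRUE)
    cat("  entropy (bits): ", sprintf("%.3f", rng[1]), " to ",
        sprintf("%.3f", rng[2]), " across the region x stage grid\n",
        sep = "")
  }
  if (!is.null(x$region_pair)) {
    cat("  region-pair Pearson over ", nrow(x$region_pair),
        " (edge, stage) cells\n", sep = "")
  }
  if (!is.null(x$nft_bins)) {
    tr <- x$nft_bins$trends
    sc <- tr[tr$statistic == "size_corr", ]
    cat("  size-correlation trend vs NFT: rho(mean) = ",
        sprintf("%.2f", sc$spearman_rho_mean), ", rho(variance) = ",
        sprintf("%.2f", sc$spearman_rho_variance), "\n", sep = "")
  }
  invisible(x)
}
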