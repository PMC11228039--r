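#' Per-sample hemoglobin expression vectors
#'
#' Extracts, for every sample, the 3-component hemoglobin expression vector
#' (HBB, HBA1, HBA2) on the expression table's working scale, joined with
#' the sample's region, stage, subject and NFT burden. These vectors are
#' the objects all coordination statistics operate on.
#'
#' @param expr Expression tibble containing the three subunit rows (or a
#'   `"hemo_cohort"`).
#' @param annot Sample annotation aligned with `expr`.
#' @return A tibble with one row per sample: `sample_id`, `subject_id`
#'   (if present), `region`, `stage`, `nft`, and columns `HBB`, `HBA1`,
#'   `HBA2`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 3))
#' hemo_vectors(cohort)
#' @export
hemo_vectors <- function(expr, annot = NULL) {
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  check_expr(expr)
  check_alignment(expr, annot)
  hb <- hemoglobin_genes()
  missing <- setdiff(hb, expr$gene_id)
  if (length(missing)) {
    abort(paste0("Expression table lacks hemoglobin subunit(s): ",
                 paste(missing, collapse = ", ")))
  }
  vals <- t(expr_values(expr)[hb, , drop = FALSE])
  out <- tibble::tibble(
    sample_id = annot$sample_id,
    region = annot$region,
    stage = annot$stage,
    nft = annot$NFT %||% rep(NA_real_, nrow(annot))
  )
  if (!is.null(annot$subject_id)) {
    out <- dplyr::mutate(out, subject_id = annot$subject_id,
                         .after = "sample_id")
  }
  dplyr::bind_cols(out, tibble::as_tibble(vals))
}

vec_matrix <- function(x) {
  hb <- hemoglobin_genes()
  if (is.data.frame(x)) {
    as.matrix(x[, hb, drop = FALSE])
  } else if (is.numeric(x) && is.null(dim(x))) {
    matrix(x, nrow = 1)
  } else {
    as.matrix(x)
  }
}

#' Coordination statistics of hemoglobin expression vectors
#'
#' The size of a hemoglobin expression vector is its Euclidean (l2) length;
#' three pairwise statistics compare the vectors of two (usually adjacent)
#' brain regions:
#' \describe{
#'   \item{size correlation}{`|x| * |y|` — large only when both regions are
#'     hemoglobin-rich.}
#'   \item{proportion correlation}{`cos(theta) = (x . y) / (|x| |y|)` —
#'     1 when both regions keep the same subunit proportions (ideally the
#'     2:1:1 HBB:HBA1:HBA2 stoichiometry); undefined (`NA` with a warning)
#'     when either vector is zero.}
#'   \item{synthesized correlation}{the inner product `x . y = size *
#'     proportion` — small when either the amounts or the proportions are
#'     discoordinated.}
#' }
#' All four functions are vectorized: `x` and `y` may be length-3 numeric
#' vectors, 3-column matrices, or [hemo_vectors()] tibbles (rows are
#' recycled to a common length).
#'
#' @param x,y Hemoglobin vectors (see above).
#' @return A numeric vector.
#' @examples
#' magnitude(c(0.3, 0.2, 0.3))                      # sqrt(0.22)
#' synthesized_correlation(c(0.3, 0.2, 0.3), c(0.2, 0.4, 0.4))  # 0.26
#' proportion_correlation(c(2, 1, 1), c(4, 2, 2))   # 1: ideal stoichiometry
#' @export
magnitude <- function(x) {
  m <- vec_matrix(x)
  sqrt(rowSums(m^2))
}

#' @rdname magnitude
#' @export
size_correlation <- function(x, y) {
  magnitude(x) * magnitude(y)
}

#' @rdname magnitude
#' @export
proportion_correlation <- function(x, y) {
  mx <- magnitude(x)
  my <- magnitude(y)
  out <- synthesized_correlation(x, y) / (mx * my)
  zero <- mx == 0 | my == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " pair(s) involve a zero vector; proportion ",
                "correlation undefined there, reported as NA."))
    out[zero] <- NA_real_
  }
  pmin(1, pmax(-1, out))
}

#' @rdname magnitude
#' @export
synthesized_correlation <- function(x, y) {
  mx <- vec_matrix(x)
  my <- vec_matrix(y)
  if (nrow(mx) == 1 && nrow(my) > 1) mx <- mx[rep(1, nrow(my)), , drop = FALSE]
  if (nrow(my) == 1 && nrow(mx) > 1) my <- my[rep(1, nrow(mx)), , drop = FALSE]
  rowSums(mx * my)
}

#' Pair adjacent-region vectors with geometric-mean NFT burden
#'
#' For each edge of the Visual-Hippocampal pathway, forms sample pairs
#' (one sample from each region) and records the geometric mean
#' `sqrt(m * n)` of the two samples' NFT values together with the three
#' coordination statistics of their hemoglobin vectors. The default
#' pairing takes all cross pairs within the same stage; `"same_subject"`
#' pairs only a subject's own two regional samples. Pairs with a missing
#' NFT value are dropped (count reported).
#'
#' @param vectors A [hemo_vectors()] tibble.
#' @param edges Tibble of region pairs (`region_a`, `region_b`); default
#'   the five pathway edges ([pathway_edges()]). Set `check_adjacent =
#'   FALSE` to allow arbitrary pairs.
#' @param pairing `"all_pairs_within_stage"` (default) or `"same_subject"`.
#' @param stages Optional stage subset.
#' @param check_adjacent Require `edges` to be pathway edges.
#' @return A tibble of class `"hemo_pair_records"`: `region_a`, `region_b`,
#'   `stage`, `sample_a`, `sample_b`, `gm_nft`, `size_corr`,
#'   `proportion_corr`, `synthesized_corr`.
#' @export
pair_regions_with_nft <- function(vectors,
                                  edges = pathway_edges(),
                                  pairing = c("all_pairs_within_stage",
                                              "same_subject"),
                                  stages = NULL,
                                  check_adjacent = TRUE) {
  pairing <- match.arg(pairing)
  if (check_adjacent) {
    known <- pathway_edges()
    key <- function(e) paste(pmin(e$region_a, e$region_b),
                             pmax(e$region_a, e$region_b))
    bad <- setdiff(key(edges), key(known))
    if (length(bad)) {
      abort(paste0("Not adjacent on the V-H pathway: ",
                   paste(bad, collapse = "; "),
                   ". Use check_adjacent = FALSE to override."))
    }
  }
  if (!is.null(stages)) vectors <- vectors[vectors$stage %in% stages, ]
  if (pairing == "same_subject" && is.null(vectors$subject_id)) {
    abort("`pairing = \"same_subject\"` needs a subject_id column.")
  }

  hb <- hemoglobin_genes()
  one_edge <- function(ra, rb) {
    va <- vectors[vectors$region == ra, ]
    out <- purrr::map(unique(va$stage), function(st) {
      a <- vectors[vectors$region == ra & vectors$stage == st, ]
      b <- vectors[vectors$region == rb & vectors$stage == st, ]
      if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
      if (pairing == "same_subject") {
        common <- intersect(a$subject_id, b$subject_id)
        ia <- match(common, a$subject_id)
        ib <- match(common, b$subject_id)
      } else {
        grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
        ia <- grid$ia
        ib <- grid$ib
      }
      if (length(ia) == 0) return(NULL)
      xa <- a[ia, ]
      xb <- b[ib, ]
      tibble::tibble(
        region_a = ra, region_b = rb, stage = st,
        sample_a = xa$sample_id, sample_b = xb$sample_id,
        gm_nft = sqrt(xa$nft * xb$nft),
        size_corr = size_correlation(xa[, hb], xb[, hb]),
        proportion_corr = suppressWarnings(
          proportion_correlation(xa[, hb], xb[, hb])),
        synthesized_corr = synthesized_correlation(xa[, hb], xb[, hb])
      )
    })
    purrr::list_rbind(out)
  }

  records <- purrr::list_rbind(
    purrr::map2(edges$region_a, edges$region_b, one_edge)
  )
  n_missing <- sum(is.na(records$gm_nft))
  if (n_missing > 0) {
    inform(paste0(n_missing, " pair(s) dropped for missing NFT."))
    records <- records[!is.na(records$gm_nft), ]
  }
  class(records) <- c("hemo_pair_records", class(records))
  records
}

#' Pearson correlation between two regions' hemoglobin vectors
#'
#' Matches each sample in region A with one in region B (by subject when
#' subject ids exist, otherwise by stage-stratified order with a message),
#' optionally scales every vector to unit length (the default, so only
#' subunit proportions are compared), and computes one Pearson coefficient
#' over the pooled component pairs (3 pairs per matched sample). Each
#' component is centred across samples before pooling; without this the
#' fixed subunit profile, identical in both regions, would dominate the
#' pooled series and report strong correlation even between completely
#' uncoupled regions. Degenerate (zero-variance) pooled series yield `NA`
#' with a warning rather than a silent NaN.
#'
#' @param vectors A [hemo_vectors()] tibble.
#' @param region_a,region_b Region labels.
#' @param stage Optional single stage; default uses all samples of each
#'   stage and returns one row per stage.
#' @param unitize Scale each vector to unit length first (default `TRUE`).
#' @return A tibble: `region_a`, `region_b`, `stage`, `r`, `n_pairs`.
#'   `r` is `NA` when fewer than 3 matched pairs exist.
#' @export
region_pair_pearson <- function(vectors, region_a, region_b, stage = NULL,
                                unitize = TRUE) {
  stages <- if (is.null(stage)) unique(vectors$stage) else stage
  hb <- hemoglobin_genes()
  by_subject <- !is.null(vectors$subject_id)
  if (!by_subject) {
    inform("No subject ids: matching samples by stage-stratified order.")
  }

  rows <- purrr::map(stages, function(st) {
    a <- vectors[vectors$region == region_a & vectors$stage == st, ]
    b <- vectors[vectors$region == region_b & vectors$stage == st, ]
    if (by_subject) {
      common <- intersect(a$subject_id, b$subject_id)
      a <- a[match(common, a$subject_id), ]
      b <- b[match(common, b$subject_id), ]
    } else {
      k <- min(nrow(a), nrow(b))
      a <- a[seq_len(k), ]
      b <- b[seq_len(k), ]
    }
    n_pairs <- nrow(a)
    if (n_pairs < 3) {
      warn(paste0("Fewer than 3 matched pairs for ", region_a, "-", region_b,
                  " at stage ", st, "; correlation undefined."))
      return(tibble::tibble(region_a = region_a, region_b = region_b,
                            stage = st, r = NA_real_, n_pairs = n_pairs))
    }
    ma <- as.matrix(a[, hb])
    mb <- as.matrix(b[, hb])
    if (unitize) {
      ma <- ma / magnitude(ma)
      mb <- mb / magnitude(mb)
    }
    # centre each component across samples before pooling, so the fixed
    # subunit profile (shared by both regions) cannot inflate r: the
    # coefficient then reflects how sample-to-sample deviations co-vary
    # between the two regions
    ma <- sweep(ma, 2, colMeans(ma))
    mb <- sweep(mb, 2, colMeans(mb))
    xs <- as.vector(t(ma))
    ys <- as.vector(t(mb))
    if (sd(xs) == 0 || sd(ys) == 0) {
      warn(paste0("Degenerate (zero-variance) component series for ",
                  region_a, "-", region_b, " at stage ", st,
                  "; correlation undefined."))
      r <- NA_real_
    } else {
      r <- cor(xs, ys)
    }
    tibble::tibble(region_a = region_a, region_b = region_b, stage = st,
                   r = r, n_pairs = n_pairs)
  })
  purrr::list_rbind(rows)
}

#' Bin coordination statistics against NFT burden
#'
#' Splits the pair records into equal-count bins of geometric-mean NFT and
#' reports the per-bin mean and variance of each coordination statistic,
#' plus a Spearman trend test of bin means against bin centers. A falling
#' mean and rising variance of the size correlation with NFT are the
#' discoordination signatures of disease progression.
#'
#' @param records A [pair_regions_with_nft()] tibble.
#' @param n_bins Number of equal-count bins (>= 2); collapsed to 1 with a
#'   warning when all NFT values coincide.
#' @return A list of class `"hemo_nft_bins"`: `bins` (tibble with
#'   `statistic`, `bin`, `nft_center`, `mean`, `variance`, `n`) and
#'   `trends` (tibble with `statistic`, `spearman_rho_mean`,
#'   `spearman_rho_variance`).
#' @export
summarize_vs_nft <- function(records, n_bins = 10) {
  if (nrow(records) == 0) abort("`records` is empty.")
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  if (length(unique(records$gm_nft)) == 1) {
    warn("All NFT values are equal; using a single bin.")
    n_bins <- 1
  }
  records$bin <- dplyr::ntile(records$gm_nft, n_bins)

  bins <- records |>
    tidyr::pivot_longer(cols = c("size_corr", "proportion_corr",
                                 "synthesized_corr"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::group_by(.data$statistic, .data$bin) |>
    dplyr::summarise(
      nft_center = mean(.data$gm_nft),
      mean = mean(.data$value, na.rm = TRUE),
      variance = if (sum(!is.na(.data$value)) > 1) {
        var(.data$value, na.rm = TRUE)
      } else {
        0
      },
      n = dplyr::n(),
      .groups = "drop"
    )

  trends <- bins |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      spearman_rho_mean = if (dplyr::n() > 2) {
        suppressWarnings(cor(.data$nft_center, .data$mean,
                             method = "spearman"))
      } else {
        NA_real_
      },
      spearman_rho_variance = if (dplyr::n() > 2) {
        suppressWarnings(cor(.data$nft_center, .data$variance,
                             method = "spearman"))
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  structure(list(bins = bins, trends = trends), class = "hemo_nft_bins")
}

#' @export
print.hemo_nft_bins <- function(x, ...) {
  cat("<hemo_nft_bins> ", length(unique(x$bins$bin)), " bins\n", sep = "")
  print(x$trends, ...)
  invisible(x)
}

#' @method autoplot hemo_nft_bins
#' @export
autoplot.hemo_nft_bins <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(.data$nft_center, .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - sqrt(.data$variance),
                                        ymax = .data$mean + sqrt(.data$variance)),
                           width = 0, alpha = 0.4) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "geometric-mean NFT burden",
                  y = "bin mean (whiskers: +/- SD)")
}
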