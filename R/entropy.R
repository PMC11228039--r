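#' Hemoglobin-subunit Pearson correlation matrix for one (region, stage)
#'
#' Partitions the samples by disease stage, keeps one (region, stage) cell,
#' and computes the 3x3 Pearson correlation matrix of HBB, HBA1 and HBA2
#' over its complete observations. At least 3 samples are required; a
#' zero-variance subunit has its correlations set to 0 with a warning so
#' that the matrix stays well defined.
#'
#' @param expr Expression tibble containing the subunit rows (or a
#'   `"hemo_cohort"`).
#' @param annot Sample annotation aligned with `expr`.
#' @param region,stage The cell to summarize.
#' @return A list of class `"subunit_correlation"`: `region`, `stage`,
#'   `matrix` (3x3, unit diagonal), `n_samples` — or `NULL` (with a
#'   warning) when fewer than 3 complete samples exist.
#' @export
subunit_correlation <- function(expr, annot = NULL, region, stage) {
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  check_expr(expr)
  check_alignment(expr, annot)
  hb <- hemoglobin_genes()
  keep <- annot$region == region & annot$stage == stage
  vals <- t(expr_values(expr)[hb, keep, drop = FALSE])
  vals <- vals[complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3) {
    warn(paste0("Fewer than 3 complete samples for region ", region,
                ", stage ", stage, "; correlation matrix unavailable."))
    return(NULL)
  }
  sds <- apply(vals, 2, sd)
  C <- diag(3)
  dimnames(C) <- list(hb, hb)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      r <- if (sds[i] == 0 || sds[j] == 0) {
        warn(paste0("Zero-variance subunit in region ", region, ", stage ",
                    stage, "; its correlations set to 0."))
        0
      } else {
        cor(vals[, i], vals[, j])
      }
      C[i, j] <- C[j, i] <- r
    }
  }
  structure(list(region = region, stage = stage, matrix = C,
                 n_samples = nrow(vals)),
            class = "subunit_correlation")
}

#' Eigenvalue probabilities of a subunit correlation matrix
#'
#' The eigenvalues of a 3x3 correlation matrix are non-negative and sum to
#' its trace (3); dividing by their sum turns the spectrum into a
#' probability distribution over the system's principal modes. Perfect
#' correlation concentrates all mass on one mode; independence spreads it
#' uniformly. Tiny negative eigenvalues (>= -1e-10, floating-point error)
#' are clipped to zero; anything below -1e-6 is rejected as not a
#' correlation matrix.
#'
#' @param corr A `"subunit_correlation"` or a symmetric numeric matrix.
#' @return Numeric probabilities in descending order, summing to 1.
#' @examples
#' eigen_probabilities(diag(3))             # 1/3, 1/3, 1/3
#' eigen_probabilities(matrix(1, 3, 3))     # 1, 0, 0
#' @export
eigen_probabilities <- function(corr) {
  m <- if (inherits(corr, "subunit_correlation")) corr$matrix else corr
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-6)) {
    abort(paste0("Matrix has eigenvalue ", format(min(ev)),
                 " < -1e-6: not a correlation matrix."))
  }
  ev <- pmax(ev, 0)
  sort(ev / sum(ev), decreasing = TRUE)
}

#' Shannon entropy of a probability distribution
#'
#' `-sum(p * log2(p))` in bits, with `0 * log2(0) = 0`. For the 3-mode
#' eigenvalue distribution of the subunit correlation matrix the entropy
#' ranges from 0 (perfect correlation, one mode) to `log2(3)`
#' (independent subunits, uniform modes); larger values mean a more
#' disordered hemoglobin system.
#'
#' @param p Non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(1 / 3, 3))   # log2(3)
#' shannon_entropy(c(1, 0, 0))      # 0
#' @export
shannon_entropy <- function(p) {
  if (any(p < -1e-9)) abort("Probabilities must be non-negative.")
  if (abs(sum(p) - 1) > 1e-6) abort("Probabilities must sum to 1.")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Convert Shannon entropy (bits) to Gibbs entropy
#'
#' Gibbs entropy `-k * sum(p * ln(p))` differs from Shannon entropy only
#' by the constant `k * ln(2)`, so `S_Gibbs = k * ln(2) * S_Shannon`.
#'
#' @param shannon_bits Entropy in bits.
#' @param k Boltzmann-like constant (default 1, i.e. natural units).
#' @return Gibbs entropy in units of `k`.
#' @examples
#' gibbs_entropy(log2(3))   # ln(3)
#' @export
gibbs_entropy <- function(shannon_bits, k = 1) {
  k * log(2) * shannon_bits
}

#' Gibbs free-energy differential at constant enthalpy
#'
#' At constant temperature, pressure and enthalpy, `dG = dH - T dS`
#' reduces to `d(dG) = -T * d(dS)`: an entropy increase of 0.02 units
#' lowers the free energy available to the hemoglobin system by `0.02 T`,
#' weakening its oxygen-transport capacity.
#'
#' @param d_entropy Change in entropy (units of `k`).
#' @param temperature Absolute temperature (K), must be positive.
#' @return The free-energy change `-temperature * d_entropy`.
#' @examples
#' free_energy_delta(0.02, temperature = 310)
#' @export
free_energy_delta <- function(d_entropy, temperature) {
  if (any(temperature <= 0)) abort("`temperature` must be positive (kelvin).")
  -temperature * d_entropy
}

#' Closed-form entropy of an equicorrelated subunit triple
#'
#' A 3x3 equicorrelation matrix with off-diagonal `rho` has eigenvalues
#' `(1 + 2 rho, 1 - rho, 1 - rho)`, hence mode probabilities
#' `((1 + 2 rho) / 3, (1 - rho) / 3, (1 - rho) / 3)`. This closed form is
#' the analytic oracle for entropy computed from sampled data: sample
#' entropy converges to it as the number of samples grows, and it is
#' strictly decreasing in `rho` on `[0, 1)`.
#'
#' @param rho Equicorrelation in `(-0.5, 1]`.
#' @return Entropy in bits.
#' @examples
#' equicorrelation_entropy(0)     # log2(3)
#' equicorrelation_entropy(0.5)   # approximately 1.2516
#' @export
equicorrelation_entropy <- function(rho) {
  if (any(rho < -0.5) || any(rho > 1)) abort("`rho` must lie in [-0.5, 1].")
  vapply(rho, function(r) {
    shannon_entropy(c(1 + 2 * r, 1 - r, 1 - r) / 3)
  }, numeric(1))
}

#' Entropy profile over the region x stage grid
#'
#' Computes, for every (region, stage) cell with enough samples, the
#' subunit correlation matrix, its eigenvalue probabilities, the Shannon
#' entropy (bits) and the Gibbs entropy, plus each cell's entropy change
#' relative to the baseline (first) stage of its region. Rising entropy
#' along the stage axis is the disorder signature of disease progression.
#'
#' @param expr Expression tibble (or `"hemo_cohort"`).
#' @param annot Sample annotation.
#' @param k Boltzmann-like constant for the Gibbs conversion.
#' @param stages Optional ordered stage vector (default: order of
#'   appearance in `annot`).
#' @return A tibble of class `"hemo_entropy"`: `region`, `stage`,
#'   `n_samples`, `lambda1..lambda3` (descending eigenvalues), `p1..p3`,
#'   `shannon_bits`, `gibbs`, `delta_vs_baseline`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 10))
#' entropy_profile(cohort)
#' @export
entropy_profile <- function(expr, annot = NULL, k = 1, stages = NULL) {
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  stages <- stages %||% unique(annot$stage)
  regions <- unique(annot$region)

  grid <- expand.grid(region = regions, stage = stages,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(region, stage) {
    sc <- subunit_correlation(expr, annot, region, stage)
    if (is.null(sc)) {
      return(tibble::tibble(region = region, stage = stage,
                            n_samples = NA_integer_,
                            lambda1 = NA_real_, lambda2 = NA_real_,
                            lambda3 = NA_real_,
                            p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                            shannon_bits = NA_real_, gibbs = NA_real_))
    }
    p <- eigen_probabilities(sc)
    lambda <- sort(pmax(eigen(sc$matrix, symmetric = TRUE,
                              only.values = TRUE)$values, 0),
                   decreasing = TRUE)
    s <- shannon_entropy(p)
    tibble::tibble(region = region, stage = stage,
                   n_samples = sc$n_samples,
                   lambda1 = lambda[1], lambda2 = lambda[2],
                   lambda3 = lambda[3],
                   p1 = p[1], p2 = p[2], p3 = p[3],
                   shannon_bits = s, gibbs = gibbs_entropy(s, k))
  })
  out <- purrr::list_rbind(rows) |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages)) |>
    dplyr::arrange(match(.data$region, regions), .data$stage) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(delta_vs_baseline =
                    .data$shannon_bits - .data$shannon_bits[1]) |>
    dplyr::ungroup()
  class(out) <- c("hemo_entropy", class(out))
  out
}

#' @method autoplot hemo_entropy
#' @export
autoplot.hemo_entropy <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$stage, .data$shannon_bits,
                               group = .data$region,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = log2(3), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "eigenvalue entropy (bits)",
                  colour = "region")
}
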