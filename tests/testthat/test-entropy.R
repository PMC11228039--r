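test_that("subunit correlation matrix has unit diagonal and detects clones", {
  m <- matrix(c(1, 2, 3, 4, 5,
                5, 3, 4, 1, 2,
                5, 3, 4, 1, 2), nrow = 3, byrow = TRUE,
              dimnames = list(hemoglobin_genes(), paste0("s", 1:5)))
  expr <- make_expr(m)
  annot <- make_annot(expr)
  sc <- subunit_correlation(expr, annot, "HC", "Normal")
  expect_equal(diag(sc$matrix), c(HBB = 1, HBA1 = 1, HBA2 = 1))
  expect_equal(sc$matrix["HBA1", "HBA2"], 1)   # duplicated subunit
  expect_identical(sc$n_samples, 5L)
  expect_true(isSymmetric(sc$matrix))
})

test_that("independent subunits give near-zero off-diagonals at large n", {
  cfg <- synthetic_config(n_subjects_per_stage = 2000, regions = "HC",
                          stages = "Normal", stage_downregulation = 0,
                          subunit_rho = 0, cross_region_rho = 0,
                          nft_mean = 1, n_background_genes = 0, seed = 13)
  cohort <- generate_cohort(cfg)
  sc <- subunit_correlation(cohort$expr, cohort$annot, "HC", "Normal")
  expect_true(all(abs(sc$matrix[upper.tri(sc$matrix)]) < 0.05))
})

test_that("underpowered or flat cells are flagged", {
  m <- matrix(rep(c(1, 2, 3), 2), nrow = 3,
              dimnames = list(hemoglobin_genes(), c("s1", "s2")))
  expr <- make_expr(m)
  expect_warning(
    out <- subunit_correlation(expr, make_annot(expr), "HC", "Normal"),
    "Fewer than 3")
  expect_null(out)

  flat <- matrix(c(5, 5, 5, 5,
                   1, 2, 3, 4,
                   4, 3, 2, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(hemoglobin_genes(), paste0("s", 1:4)))
  fexpr <- make_expr(flat)
  warns <- capture_warnings(
    sc <- subunit_correlation(fexpr, make_annot(fexpr), "HC", "Normal"))
  expect_true(any(grepl("Zero-variance", warns)))
  expect_equal(sc$matrix["HBB", "HBA1"], 0)
  expect_equal(sc$matrix["HBA1", "HBA2"], -1)
})

test_that("eigenvalue probabilities match the closed-form spectra", {
  expect_equal(eigen_probabilities(diag(3)), rep(1 / 3, 3))
  expect_equal(eigen_probabilities(matrix(1, 3, 3)), c(1, 0, 0))
  eq <- matrix(0.5, 3, 3); diag(eq) <- 1
  # equicorrelation spectrum (1 + 2 rho, 1 - rho, 1 - rho) = (2, 0.5, 0.5)
  expect_equal(eigen_probabilities(eq), c(2 / 3, 1 / 6, 1 / 6))
  bad <- matrix(-0.6, 3, 3); diag(bad) <- 1
  expect_error(eigen_probabilities(bad), "not a correlation matrix")
})

test_that("Shannon entropy evaluates the frozen reference points", {
  expect_equal(shannon_entropy(rep(1 / 3, 3)), 1.5849625007211561)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(2 / 3, 1 / 6, 1 / 6)), 1.2516291673878228)
  expect_error(shannon_entropy(c(0.6, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2, 0)), "non-negative")
})

test_that("entropy of a 3x3 correlation matrix stays within [0, log2 3]", {
  set.seed(6)
  for (i in 1:50) {
    x <- matrix(rnorm(30), 10, 3)
    h <- shannon_entropy(eigen_probabilities(cor(x)))
    expect_gte(h, 0)
    expect_lte(h, log2(3) + 1e-12)
  }
  expect_equal(shannon_entropy(eigen_probabilities(diag(3))), log2(3))
  expect_equal(shannon_entropy(eigen_probabilities(matrix(1, 3, 3))), 0)
})

test_that("Gibbs entropy is k ln 2 times the Shannon entropy", {
  expect_equal(gibbs_entropy(0), 0)
  expect_equal(gibbs_entropy(log2(3)), log(3))
  expect_equal(gibbs_entropy(2 * 0.7), 2 * gibbs_entropy(0.7))
  s <- c(0.3, 0.9, 1.5)
  expect_equal(gibbs_entropy(s, k = 2.5) / s, rep(2.5 * log(2), 3))
})

test_that("free-energy differential is -T times the entropy differential", {
  expect_equal(free_energy_delta(0.02, temperature = 1), -0.02)
  expect_equal(free_energy_delta(0, temperature = 310), 0)
  expect_equal(free_energy_delta(-0.01, temperature = 300), 3)
  expect_error(free_energy_delta(0.1, temperature = 0), "positive")
})

test_that("equicorrelation entropy is strictly decreasing in rho", {
  grid <- c(0, 0.25, 0.5, 0.75, 0.99)
  h <- equicorrelation_entropy(grid)
  expect_true(all(diff(h) < 0))
  expect_equal(h[1], log2(3))
  expect_equal(equicorrelation_entropy(1), 0)
  expect_error(equicorrelation_entropy(-0.7), "rho")
})

test_that("sample entropy approaches the closed form as n grows", {
  cfg <- synthetic_config(n_subjects_per_stage = 1000, regions = "HC",
                          stages = "Normal", stage_downregulation = 0,
                          subunit_rho = 0.7, cross_region_rho = 0,
                          nft_mean = 1, n_background_genes = 0, seed = 17)
  cohort <- generate_cohort(cfg)
  prof <- entropy_profile(cohort)
  expect_equal(prof$shannon_bits, equicorrelation_entropy(0.7),
               tolerance = 0.05)
})

test_that("stage-wise decorrelation raises entropy in every region", {
  cfg <- synthetic_config(n_subjects_per_stage = 400,
                          regions = c("MTG", "HC"),
                          subunit_rho = c(0.9, 0.65, 0.35, 0),
                          stage_downregulation = 0, noise_sd = 0.3,
                          n_background_genes = 0, seed = 19)
  prof <- entropy_profile(generate_cohort(cfg))
  for (r in c("MTG", "HC")) {
    h <- prof$shannon_bits[prof$region == r]
    expect_true(all(diff(h) > 0),
                label = paste("entropy strictly increasing in", r))
  }
  expect_true(all(prof$delta_vs_baseline[prof$stage == "Definite AD"] > 1))
})

test_that("constant correlation structure yields a flat entropy profile", {
  cfg <- synthetic_config(n_subjects_per_stage = 400, regions = "HC",
                          subunit_rho = 0.5, stage_downregulation = 0,
                          n_background_genes = 0, seed = 23)
  prof <- entropy_profile(generate_cohort(cfg))
  # 3 x the sampling SD of the entropy difference at n = 400, rho = 0.5
  expect_true(all(abs(prof$delta_vs_baseline) < 0.2))
})

test_that("perfectly collinear subunits give zero entropy", {
  base <- c(1, 2, 3, 4, 5)
  m <- rbind(HBB = base, HBA1 = 2 * base, HBA2 = 0.5 * base)
  colnames(m) <- paste0("s", 1:5)
  expr <- make_expr(m)
  prof <- entropy_profile(expr, make_annot(expr))
  expect_equal(prof$shannon_bits, 0)
  expect_equal(prof$p1, 1)
})
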