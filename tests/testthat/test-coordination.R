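# The worked MTG/PHG vector pair and its frozen arithmetic.
mtg <- c(0.3, 0.2, 0.3)
phg <- c(0.2, 0.4, 0.4)

test_that("magnitude is the Euclidean length of the subunit triple", {
  expect_equal(magnitude(c(2, 1, 1)), sqrt(6))
  expect_equal(magnitude(c(0, 0, 0)), 0)
  expect_equal(magnitude(mtg), 0.46904157598234297)
})

test_that("size correlation is the product of the two magnitudes", {
  expect_equal(size_correlation(c(1, 0, 0), c(0, 1 / sqrt(2), 1 / sqrt(2))), 1)
  expect_equal(size_correlation(mtg, phg), 0.28142494558940578)
  expect_equal(size_correlation(c(0, 0, 0), phg), 0)
})

test_that("proportion correlation is the cosine, perfect for 2:1:1 pairs", {
  expect_equal(proportion_correlation(3 * c(2, 1, 1), 0.5 * c(2, 1, 1)), 1)
  expect_equal(proportion_correlation(c(1, 0, 0), c(0, 1, 0)), 0)
  # the worked pair: cosine 0.9239, distinct from its inner product 0.26
  expect_equal(proportion_correlation(mtg, phg), 0.92386977087431188)
  expect_warning(out <- proportion_correlation(c(0, 0, 0), phg), "zero vector")
  expect_true(is.na(out))
})

test_that("synthesized correlation is the inner product and is bilinear", {
  expect_equal(synthesized_correlation(mtg, phg), 0.26)
  expect_equal(synthesized_correlation(c(0, 0, 0), phg), 0)
  expect_equal(synthesized_correlation(5 * mtg, phg),
               5 * synthesized_correlation(mtg, phg))
})

test_that("the three statistics are mutually consistent and symmetric", {
  set.seed(2)
  x <- matrix(rnorm(300), ncol = 3)
  y <- matrix(rnorm(300), ncol = 3)
  expect_equal(synthesized_correlation(x, y),
               size_correlation(x, y) * proportion_correlation(x, y),
               tolerance = 1e-9)
  expect_equal(size_correlation(x, y), size_correlation(y, x))
  expect_equal(proportion_correlation(x, y), proportion_correlation(y, x))
  expect_equal(synthesized_correlation(x, y), synthesized_correlation(y, x))
  # scale invariance of the cosine, including sign flips
  expect_equal(proportion_correlation(2.5 * x, 0.3 * y),
               proportion_correlation(x, y))
  expect_equal(proportion_correlation(-2 * x, 3 * y),
               -proportion_correlation(x, y))
})

test_that("NFT pairing uses the geometric mean and all cross pairs in a stage", {
  cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 10,
                                             n_background_genes = 0, seed = 3))
  v <- hemo_vectors(cohort)
  recs <- pair_regions_with_nft(v, edges = pathway_edges()[3, ],  # MTG-PHG
                                stages = "Normal")
  expect_identical(nrow(recs), 100L)
  # geometric mean against the annotated NFT values
  nft <- setNames(v$nft, v$sample_id)
  expect_equal(recs$gm_nft, sqrt(nft[recs$sample_a] * nft[recs$sample_b]),
               ignore_attr = TRUE)
  expect_equal(recs$synthesized_corr,
               recs$size_corr * recs$proportion_corr, tolerance = 1e-9)
})

test_that("same-subject pairing emits one record per shared subject", {
  cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 7,
                                             n_background_genes = 0))
  v <- hemo_vectors(cohort)
  recs <- pair_regions_with_nft(v, edges = pathway_edges()[5, ],  # PHG-HC
                                pairing = "same_subject")
  expect_identical(nrow(recs), 7L * 4L)
  # m = n for a subject's own pair, so gm_nft equals the subject's NFT
  expect_equal(recs$gm_nft,
               v$nft[match(recs$sample_a, v$sample_id)], ignore_attr = TRUE)
})

test_that("non-adjacent region pairs are rejected unless overridden", {
  cohort <- generate_cohort(tiny_config(n_background_genes = 0))
  v <- hemo_vectors(cohort)
  far <- tibble::tibble(region_a = "OVC", region_b = "HC")
  expect_error(pair_regions_with_nft(v, edges = far), "adjacent")
  recs <- pair_regions_with_nft(v, edges = far, check_adjacent = FALSE)
  expect_gt(nrow(recs), 0)
})

test_that("region-pair Pearson is 1 for identical and -1 for opposite vectors", {
  cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 6,
                                             regions = c("MTG", "PHG"),
                                             n_background_genes = 0, seed = 2))
  v <- hemo_vectors(cohort)
  # make PHG an exact copy of MTG, subject by subject
  hb <- hemoglobin_genes()
  v[v$region == "PHG", hb] <- v[v$region == "MTG", hb]
  same <- region_pair_pearson(v, "MTG", "PHG", stage = "Normal")
  expect_equal(same$r, 1)
  expect_identical(same$n_pairs, 6L)
  v[v$region == "PHG", hb] <- -v[v$region == "MTG", hb]
  opp <- region_pair_pearson(v, "MTG", "PHG", stage = "Normal",
                             unitize = FALSE)
  expect_equal(opp$r, -1)
})

test_that("uncoupled regions give region-pair Pearson near zero", {
  cfg <- synthetic_config(n_subjects_per_stage = 500,
                          regions = c("MTG", "PHG"),
                          stages = "Normal", stage_downregulation = 0,
                          subunit_rho = 0.5, cross_region_rho = 0,
                          nft_mean = 1, n_background_genes = 0, seed = 21)
  v <- hemo_vectors(generate_cohort(cfg))
  r <- region_pair_pearson(v, "MTG", "PHG")$r
  expect_lt(abs(r), 0.1)
})

test_that("degenerate unitized vectors are reported, not silently NaN", {
  # equal-component vectors unitize to (1,1,1)/sqrt(3) for every sample, so
  # the pooled component series has zero variance
  cohort <- generate_cohort(synthetic_config(
    n_subjects_per_stage = 4, regions = c("MTG", "PHG"), noise_sd = 0,
    stage_downregulation = 0,
    baseline_mean = c(HBB = 5, HBA1 = 5, HBA2 = 5),
    n_background_genes = 0))
  v <- hemo_vectors(cohort)
  expect_warning(out <- region_pair_pearson(v, "MTG", "PHG", stage = "Normal"),
                 "[Dd]egenerate|zero-variance")
  expect_true(is.na(out$r))
})

test_that("fewer than 3 matched pairs yields a missing correlation", {
  cohort <- generate_cohort(synthetic_config(n_subjects_per_stage = 2,
                                             regions = c("MTG", "PHG"),
                                             n_background_genes = 0))
  v <- hemo_vectors(cohort)
  expect_warning(out <- region_pair_pearson(v, "MTG", "PHG", stage = "Normal"),
                 "Fewer than 3")
  expect_true(is.na(out$r))
})

test_that("NFT binning: constant statistics give flat means and zero variance", {
  recs <- tibble::tibble(
    region_a = "MTG", region_b = "PHG", stage = "Normal",
    sample_a = paste0("a", 1:40), sample_b = paste0("b", 1:40),
    gm_nft = seq(0.5, 20, length.out = 40),
    size_corr = 2, proportion_corr = 1, synthesized_corr = 2
  )
  out <- summarize_vs_nft(recs, n_bins = 4)
  expect_identical(nrow(out$bins), 12L)  # 3 statistics x 4 bins
  expect_true(all(out$bins$variance == 0))
  expect_true(all(out$bins$mean[out$bins$statistic == "size_corr"] == 2))
  expect_true(all(out$bins$n == 10))
})

test_that("NFT binning collapses to one bin when all NFT coincide", {
  recs <- tibble::tibble(
    region_a = "MTG", region_b = "PHG", stage = "Normal",
    sample_a = "a", sample_b = "b",
    gm_nft = rep(3, 5), size_corr = rnorm(5),
    proportion_corr = runif(5, -1, 1), synthesized_corr = rnorm(5)
  )
  expect_warning(out <- summarize_vs_nft(recs, n_bins = 4), "single bin")
  expect_identical(length(unique(out$bins$bin)), 1L)
  expect_error(summarize_vs_nft(recs, n_bins = 1), "n_bins")
})
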