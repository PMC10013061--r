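test_that("pair counting and the Bonferroni threshold are exact", {
  expect_equal(count_variable_pairs(7), 21)
  expect_equal(count_variable_pairs(2), 1)
  expect_equal(count_variable_pairs(5), 10)
  expect_error(count_variable_pairs(1), "at least 2")

  thr <- bonferroni_threshold(0.05, 21)
  expect_equal(thr, 0.05 / 21)
  expect_equal(round(thr, 4), 0.0024)
  expect_equal(thr * 21, 0.05)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("Spearman screening uses midranks and pairwise deletion", {
  d <- data.frame(x = 1:5, y = c(2, 4, 6, 8, 10))
  expect_equal(spearman_pairwise(d, "x", "y", min_pair_n = 5)$rho, 1)
  d$y <- 5:1
  expect_equal(spearman_pairwise(d, "x", "y", min_pair_n = 5)$rho, -1)

  d2 <- data.frame(x = 1:8, y = c(1, 3, 2, 4, 6, 5, 8, 7))
  res <- spearman_pairwise(d2, "x", "y", min_pair_n = 5)
  expect_equal(res$rho, spearman_oracle(d2$x, d2$y), tolerance = 1e-12)

  # midrank tie handling against the rank-Pearson oracle
  d3 <- data.frame(x = c(1, 2, 2, 3, 4, 5, 5, 6),
                   y = c(2, 1, 3, 3, 5, 4, 6, 6))
  res3 <- spearman_pairwise(d3, "x", "y", min_pair_n = 5)
  expect_equal(res3$rho, spearman_oracle(d3$x, d3$y), tolerance = 1e-12)

  d4 <- data.frame(x = 1:8, y = c(1, NA, 2, 4, 6, NA, 8, 7))
  res4 <- spearman_pairwise(d4, "x", "y", min_pair_n = 5)
  expect_equal(res4$n_complete, 6)
  keep <- !is.na(d4$y)
  expect_equal(res4$rho, spearman_oracle(d4$x[keep], d4$y[keep]),
               tolerance = 1e-12)

  # too few complete pairs: flagged, not tested
  res5 <- spearman_pairwise(d4, "x", "y", min_pair_n = 7)
  expect_true(res5$insufficient)
  expect_true(is.na(res5$rho))
})

test_that("screening is invariant to monotone transforms of either variable", {
  set.seed(42)
  d <- data.frame(x = rexp(30), y = rnorm(30))
  base <- spearman_pairwise(d, "x", "y", min_pair_n = 10)
  d2 <- data.frame(x = exp(d$x), y = d$y^3)
  trans <- spearman_pairwise(d2, "x", "y", min_pair_n = 10)
  expect_equal(trans$rho, base$rho, tolerance = 1e-12)
  expect_equal(trans$p_value, base$p_value, tolerance = 1e-12)
})

test_that("pair regression is ordinary least squares on complete pairs", {
  d <- data.frame(x = c(0, 1, 2, 3), y = c(1, 3, 5, 7))
  fit <- fit_pair_model(d, "x", "y")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  # closed-form check on three points
  d2 <- data.frame(x = c(0, 1, 2), y = c(0, 1, 0))
  fit2 <- fit_pair_model(d2, "x", "y")
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$intercept, 1 / 3)

  d3 <- data.frame(x = rep(2, 5), y = 1:5)
  expect_error(fit_pair_model(d3, "x", "y"), "constant")
  expect_error(fit_pair_model(d2[1:2, ], "x", "y"), "at least 3")
})

test_that("the default synthetic cohort yields the six-axis survivor map", {
  cohort <- generate_cohort(synthetic_config(), seed = 1)
  refset <- build_reference_set(cohort)
  expect_equal(refset$m, 21)
  expect_equal(refset$threshold, 0.05 / 21)
  expect_equal(nrow(refset$screening), 21)

  survivor_map_axes <- c("ALB_Bil", "ALB_PT", "ALB_HE", "Bil_PT", "PT_HE", "NH4_HE")
  sig <- refset$pairs$pair
  expect_true(all(survivor_map_axes %in% sig))
  # sodium and creatinine stay outside the network
  expect_false(any(grepl("Na|Cr", sig)))
  # every retained pair carries a fitted line and passes the threshold
  expect_true(all(is.finite(refset$pairs$slope)))
  expect_true(all(refset$pairs$p_value <= refset$threshold))
})

test_that("relaxing alpha admits a superset of pairs at threshold alpha/m", {
  cohort <- generate_cohort(synthetic_config(n_survivors = 100,
                                             n_nonsurvivors = 0),
                            seed = 2)
  strict <- build_reference_set(cohort, analysis_config(alpha = 0.05))
  loose <- build_reference_set(cohort, analysis_config(alpha = 0.999999))
  expect_equal(loose$threshold, 0.999999 / 21)
  expect_true(all(strict$pairs$pair %in% loose$pairs$pair))
  # admission is governed by the corrected threshold exactly
  s <- loose$screening
  expect_setequal(loose$pairs$pair,
                  s$pair[!s$insufficient & s$p_value <= loose$threshold])
})

test_that("insufficient-data pairs stay in the Bonferroni denominator", {
  cohort <- generate_cohort(synthetic_config(n_survivors = 60,
                                             n_nonsurvivors = 0,
                                             missing_rate = 0),
                            seed = 9)
  cohort$NH4[seq_len(55)] <- NA
  refset <- build_reference_set(cohort)
  nh4_rows <- grepl("NH4", refset$screening$pair)
  expect_true(all(refset$screening$insufficient[nh4_rows]))
  expect_equal(refset$m, 21)
  expect_equal(refset$threshold, 0.05 / 21)
})
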