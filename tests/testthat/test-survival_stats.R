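test_that("Mann-Whitney separates, equates and matches the exact null", {
  sep <- mann_whitney_compare(c(1, 2, 3, 4), c(10, 11, 12, 13), "sep")
  expect_lt(sep$p_value, 0.05)
  expect_equal(sep$U, 0)

  same <- mann_whitney_compare(c(1, 2, 3, 4), c(1, 2, 3, 4), "same")
  expect_gt(same$p_value, 0.9)

  # normal approximation vs exact permutation enumeration at small n
  set.seed(21)
  for (rep in 1:4) {
    x <- round(rnorm(6, 0, 2), 1)
    y <- round(rnorm(7, 1, 2), 1)
    approx_p <- mann_whitney_compare(x, y)$p_value
    expect_lt(abs(approx_p - exact_mw_p(x, y)), 0.02)
  }

  expect_error(mann_whitney_compare(numeric(0), 1:3), "non-empty")
})

test_that("Cox estimates maximise the Efron partial likelihood", {
  d <- cox_fixture()
  res <- cox_fit(d$time, d$event, data.frame(x = d$x))
  opt <- optimize(function(b) efron_loglik(b, d$time, d$event, d$x),
                  interval = c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(res$beta, opt$maximum, tolerance = 1e-4)
  expect_equal(res$hr, exp(res$beta))
  expect_true(res$ci_lower < res$hr && res$hr < res$ci_upper)
})

test_that("Cox results transform correctly under covariate rescaling", {
  d <- cox_fixture()
  res1 <- cox_fit(d$time, d$event, data.frame(x = d$x))
  res10 <- cox_fit(d$time, d$event, data.frame(x = d$x / 10))
  expect_equal(res10$beta, 10 * res1$beta, tolerance = 1e-6)
  expect_equal(res10$sem, 10 * res1$sem, tolerance = 1e-6)
  expect_equal(res10$p_value, res1$p_value, tolerance = 1e-8)
})

test_that("Cox consistency and CI coverage on simulated data", {
  # two-group exponential data with true hazard ratio 2
  set.seed(31)
  n <- 1000
  g <- rep(0:1, each = n / 2)
  t_true <- rexp(n, rate = 0.01 * 2^g)
  cens <- pmin(t_true, 300)
  res <- cox_fit(cens, as.integer(t_true <= 300), data.frame(g = g))
  expect_lt(abs(res$beta - log(2)), 3 * res$sem)

  # null covariate: CI for the hazard ratio covers 1 at ~95%
  cover <- sapply(1:60, function(s) {
    set.seed(1000 + s)
    tt <- rexp(120, 0.02)
    z <- rnorm(120)
    r <- cox_fit(pmin(tt, 80), as.integer(tt <= 80), data.frame(z = z))
    r$ci_lower <= 1 && 1 <= r$ci_upper
  })
  expect_gte(mean(cover), 0.85)

  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(1, 2))), "events")
  expect_error(cox_fit(c(1, 2, 3), c(1, 0, 1), data.frame(x = rep(1, 3))),
               "constant")
})

test_that("the combined severity-deviation index is the Cox linear predictor", {
  expect_equal(combined_index(0.119, 12, 0.061, 2.08), 1.5549,
               tolerance = 1e-4)
  expect_equal(combined_index(0.119, 12, 0, 2.08), 0.119 * 12)
  expect_equal(combined_index(0, c(10, 20), 0, c(1, 2)), c(0, 0))
})

test_that("AUC equals exhaustive pair counting and the Mann-Whitney identity", {
  roc1 <- roc_with_cutoff(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc1$auc, 1)
  roc2 <- roc_with_cutoff(rep(c(1, 2, 3), 2), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc2$auc, 0.5)

  set.seed(55)
  scores <- round(c(rnorm(7, 1), rnorm(5, 0)), 1)
  labels <- c(rep(1, 7), rep(0, 5))
  roc <- roc_with_cutoff(scores, labels)
  expect_equal(roc$auc, auc_paircount(scores, labels), tolerance = 1e-12)

  # identity with the Mann-Whitney U statistic (tie convention 1/2)
  u <- suppressWarnings(wilcox.test(scores[labels == 1],
                                    scores[labels == 0]))$statistic
  expect_equal(roc$auc, unname(u) / (7 * 5), tolerance = 1e-12)

  # cross-check against an established ROC implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                             direction = "<", quiet = TRUE)))
  expect_equal(roc$auc, proc_auc, tolerance = 1e-12)
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(77)
  scores <- rnorm(40)
  labels <- rep(c(0, 1), 20)
  a1 <- roc_with_cutoff(scores, labels)$auc
  a2 <- roc_with_cutoff(-scores, labels)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("the cutoff maximises Youden's J, breaking ties toward sensitivity", {
  scores <- c(1, 2, 3, 4, 10, 11, 12, 13)
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  roc <- roc_with_cutoff(scores, labels)
  expect_equal(roc$sensitivity + roc$specificity - 1, 1)
  # J = 1 anywhere in (4, 10]; the lowest observed candidate achieving it
  expect_equal(roc$cutoff, 10)

  # inverted score: orientation check flips and flags
  roc_f <- roc_with_cutoff(-scores, labels)
  expect_true(roc_f$flipped)
  expect_equal(roc_f$direction, "<=")
  expect_equal(roc_f$sensitivity + roc_f$specificity - 1, 1)

  expect_error(roc_with_cutoff(1:5, rep(1, 5)), "classes")
})

test_that("log-rank matches hand-tabulated risk sets and degenerates to zero", {
  time <- c(4, 6, 6, 10, 12, 15, 20, 20, 25, 30, 8, 9, 14, 18, 22)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 1, 1, 0)
  group <- rep(c("a", "b"), c(10, 5))
  km <- km_logrank(time, event, group)
  expect_equal(km$chisq, logrank_oracle(time, event, group),
               tolerance = 1e-8)
  expect_equal(km$p_value, pchisq(km$chisq, 1, lower.tail = FALSE))
  # survival step functions start at or below 1 and never increase
  for (g in unique(km$curves$group)) {
    s <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }

  # identical event patterns in both groups: chi-square ~ 0
  t2 <- rep(c(5, 10, 15, 20), 2)
  e2 <- rep(c(1, 1, 0, 1), 2)
  g2 <- rep(c("a", "b"), each = 4)
  expect_lt(km_logrank(t2, e2, g2)$chisq, 1e-10)

  expect_error(km_logrank(t2, rep(0, 8), g2), "events")
  expect_error(km_logrank(t2, e2, rep("a", 8)), "two")
})
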