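test_that("Welch statistic matches the closed form and stats::t.test", {
  w <- welch_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t_stat, 3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p_value, 0.02131164, tolerance = 1e-6)

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ref <- stats::t.test(b, a)
    w <- welch_ttest(a, b)
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
    wp <- welch_ttest(a, b, pooled = TRUE)
    refp <- stats::t.test(b, a, var.equal = TRUE)
    expect_equal(wp$p_value, refp$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate groups follow the stated conventions", {
  w <- welch_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_identical(w$t_stat, 0)
  expect_identical(w$p_value, 1)
  w2 <- welch_ttest(c(1, 1), c(5, 5))
  expect_identical(w2$p_value, 0)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("Welch test is symmetric under group exchange up to the sign of t", {
  set.seed(4)
  a <- rnorm(7); b <- rnorm(9, 1)
  w1 <- welch_ttest(a, b)
  w2 <- welch_ttest(b, a)
  expect_equal(w1$t_stat, -w2$t_stat, tolerance = 1e-12)
  expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)
})

test_that("Welch p agrees with a permutation test on small groups", {
  # oracle: Monte-Carlo permutation null of the mean difference, 6 vs 6
  set.seed(15)
  a <- rnorm(6)
  b <- rnorm(6, mean = 1.2)
  obs <- abs(mean(b) - mean(a))
  pool <- c(a, b)
  perm <- replicate(40000, {
    idx <- sample.int(12, 6)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(welch_ttest(a, b)$p_value - p_perm), 0.02)
})

test_that("a cohort of 10 with min_group 5 admits exactly one candidate split", {
  set.seed(9)
  scores <- seq(100, 1000, by = 100)
  feats <- tibble::tibble(f1 = rnorm(10), f2 = rnorm(10))
  sw <- sweep_splits(scores, feats, min_group = 5)
  expect_identical(nrow(sw$curve), 1L)
  expect_identical(sw$best$n_low, 5L)
  expect_identical(sw$best$cut_score, 600)
})

test_that("sweep counts depend only on score order and not on column order", {
  coh <- generate_cohort(cohort_spec(
    effect_map = c(HF = 1.5, lnHF = 1.5, RSA = 1.5), seed = 33))
  X <- coh$features[, hrv_index_names()]
  s <- coh$scores$score
  sw1 <- sweep_splits(s, X)
  sw2 <- sweep_splits(rank(s, ties.method = "min") * 3 + 7, X)
  expect_identical(sw1$curve$sig_05, sw2$curve$sig_05)
  expect_identical(sw1$best$n_low, sw2$best$n_low)
  sw3 <- sweep_splits(s, X[, rev(seq_len(ncol(X)))])
  expect_identical(sw1$curve$sig_05, sw3$curve$sig_05)
  expect_identical(sort(sw1$markers$feature), sort(sw3$markers$feature))
})

test_that("tied scores are never split and identical scores admit no split", {
  scores <- c(rep(100, 6), rep(900, 6))
  feats <- tibble::tibble(f = rnorm(12))
  sw <- sweep_splits(scores, feats, min_group = 5)
  expect_identical(nrow(sw$curve), 1L)
  expect_identical(sw$best$n_low, 6L)
  expect_error(sweep_splits(rep(500, 12), feats, min_group = 5), "no valid split")
})

test_that("the sweep finds injected markers at a strongly separated cut", {
  inj <- c("HF", "lnHF", "RSA", "LFp", "LF_HF")
  coh <- generate_cohort(cohort_spec(
    n_low = 22, n_high = 26,
    effect_map = stats::setNames(rep(1.5, 5), inj), seed = 11))
  sw <- sweep_splits(coh$scores$score, coh$features[, hrv_index_names()])
  expect_gte(sum(inj %in% sw$markers$feature), 4)
  # the curve rises to its peak and falls off at the extremes
  expect_lt(sw$curve$sig_05[1], max(sw$curve$sig_05))
})

test_that("best-split selection inflates null counts relative to a fixed split", {
  # the selection effect the synthetic null baseline exists to expose
  best_minus_fixed <- vapply(1:40, function(s) {
    coh <- generate_cohort(cohort_spec(n_low = 22, n_high = 26, seed = 1000 + s))
    X <- coh$features[, hrv_index_names()]
    sw <- sweep_splits(coh$scores$score, X)
    fixed <- sw$curve$sig_05[sw$curve$n_low == 22][1]
    max(sw$curve$sig_05) - fixed
  }, numeric(1))
  expect_gt(mean(best_minus_fixed), 0)
})

test_that("marker tiers use strict thresholds and group by feature source", {
  tests <- tibble::tibble(
    feature = c("HF", "variability_lnHF", "instability_LF_HF", "SDNN", "inertia_dHz"),
    t_stat = 1, df = 10,
    p_value = c(0.008, 0.03, 0.05, 0.2, 0.0099),
    low_mean = 0, low_sd = 1, high_mean = 1, high_sd = 1,
    n_low = 22, n_high = 26
  )
  mt <- marker_table(tests)
  expect_identical(sort(mt$feature), sort(c("HF", "variability_lnHF", "inertia_dHz")))
  expect_identical(mt$stars[mt$feature == "HF"], "**")
  expect_identical(mt$stars[mt$feature == "variability_lnHF"], "*")
  expect_identical(mt$stars[mt$feature == "inertia_dHz"], "**")
  expect_false("instability_LF_HF" %in% mt$feature)  # p = 0.05 exactly
  expect_identical(mt$source[mt$feature == "HF"], "HRV")
  expect_identical(mt$source[mt$feature == "inertia_dHz"], "inertia")
})

test_that("normality check is calibrated on its own null and rejects gross skew", {
  set.seed(19)
  norm <- check_normality(rnorm(500))
  expect_gt(norm$p_value, 0.05)
  expect_identical(nrow(norm$qq), 500L)
  expect_lt(check_normality(rexp(500))$p_value, 0.01)
  expect_error(check_normality(rep(5, 20)), "constant")
  expect_error(check_normality(rnorm(5)), "n >= 8")
})

test_that("sweep outputs are written as the four run files", {
  coh <- generate_cohort(cohort_spec(seed = 2))
  sw <- sweep_splits(coh$scores$score, coh$features[, hrv_index_names()])
  dir <- withr::local_tempdir()
  paths <- write_sweep_csv(sw, dir)
  expect_true(all(file.exists(paths)))
  curve <- read.csv(paths["curve"])
  expect_identical(nrow(curve), nrow(sw$curve))
})
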