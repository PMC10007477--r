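test_that("constant spec yields constant intervals and the expected beat count", {
  rr <- generate_rr_series(rr_gen_spec(800, duration = 60, seed = 7))
  expect_true(all(abs(rr$intervals - 800) < 1e-9))
  expect_true(abs(length(rr$intervals) - 75) <= 1)
  expect_identical(rr$beat_times[1], 0)
})

test_that("generated series satisfy the beat-time/interval identity", {
  rr <- sine_rr(0.25, noise_sd = 15, duration = 120, seed = 4)
  expect_equal(rr$intervals, 1000 * diff(rr$beat_times))
  expect_true(all(rr$intervals > 0))
})

test_that("modulation places the dominant tachogram frequency where requested", {
  # oracle: direct discrete Fourier transform of the resampled interval
  # sequence, independent of power_spectrum()
  rr <- sine_rr(0.25, duration = 360)
  tac <- retained_intervals(rr, with_times = TRUE)
  fs <- 4
  grid <- seq(tac$times[1], tac$times[length(tac$times)], by = 1 / fs)
  x <- stats::spline(tac$times, tac$intervals, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  amp <- Mod(stats::fft(x))[2:floor(n / 2)]
  fr <- (1:(floor(n / 2) - 1)) * fs / n
  expect_lt(abs(fr[which.max(amp)] - 0.25), fs / n + 1e-12)
})

test_that("identical specs reproduce bit-identical series", {
  s <- rr_gen_spec(820, list(c(amplitude = 30, frequency = 0.1)),
                   noise_sd = 12, duration = 90, seed = 99)
  expect_identical(generate_rr_series(s)$intervals,
                   generate_rr_series(s)$intervals)
})

test_that("degenerate specs error instead of clipping intervals", {
  # deterministic part goes negative: immediate failure
  expect_error(
    generate_rr_series(rr_gen_spec(10, list(c(amplitude = 50, frequency = 0.1)),
                                   duration = 60)),
    "degenerate"
  )
  # noise never lifts the sub-millisecond mean into range: retries exhaust
  expect_error(
    generate_rr_series(rr_gen_spec(0.5, noise_sd = 0.01, duration = 60, seed = 5)),
    "degenerate"
  )
  expect_error(rr_gen_spec(800, list(c(amplitude = 5, frequency = 0.7))),
               "frequencies")
})

test_that("synthesized ECG places a spike at each beat", {
  fs <- 500
  ecg <- synthesize_ecg(rr_series(0:10), fs = fs)
  expect_s3_class(ecg, "ecg_record")
  expect_identical(ecg$fs, fs)
  for (b in 0:10) {
    span <- (round((b - 0.4) * fs):round((b + 0.4) * fs)) + 1L
    span <- span[span >= 1 & span <= length(ecg$samples)]
    i_max <- span[which.max(ecg$samples[span])]
    expect_lte(abs((i_max - 1) / fs - b), 1 / fs)
  }
})

test_that("ECG synthesis rejects empty input and overlapping templates", {
  expect_error(synthesize_ecg(numeric(0)), "empty")
  expect_error(synthesize_ecg(c(0, 0.05, 0.10), template_width = 80),
               "overlap")
  expect_error(synthesize_ecg(rr_series(0:5), fs = 50), "fs")
})

test_that("cohort null case shows no systematic group differences", {
  coh <- generate_cohort(cohort_spec(n_low = 24, n_high = 24,
                                     effect_map = numeric(0), seed = 21))
  lo <- coh$features$group == "low"
  for (f in hrv_index_names()) {
    d <- mean(coh$features[[f]][!lo]) - mean(coh$features[[f]][lo])
    expect_lt(abs(d), 4 / sqrt(24))
  }
})

test_that("an injected d = 2 effect is detected with near-certain power", {
  # oracle: closed-form power of the two-sample t test at d = 2, n = 24/24
  # exceeds 0.999; over 200 seeds at least 195 significant tests expected
  hits <- vapply(1:200, function(s) {
    coh <- generate_cohort(cohort_spec(n_low = 24, n_high = 24,
                                       effect_map = c(RMSSD = 2), seed = s))
    lo <- coh$features$group == "low"
    stats::t.test(coh$features$RMSSD[lo], coh$features$RMSSD[!lo])$p.value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 195)
})

test_that("cohort scores split exactly at the cut", {
  coh <- generate_cohort(cohort_spec(n_low = 22, n_high = 26,
                                     score_cut = 820, seed = 3))
  expect_identical(sum(coh$scores$score < 820), 22L)
  expect_identical(sum(coh$scores$score >= 820), 26L)
  expect_true(all(coh$scores$score %% 10 == 0))
  expect_identical(coh$scores$group, coh$features$group)
})

test_that("generated responses hit the requested accuracy exactly", {
  for (acc in c(0, 0.5, 0.92, 1)) {
    resp <- generate_responses(100, acc, "LALV", seed = 8)
    expect_equal(domain_accuracy(resp, "LALV"), 100 * acc)
  }
  # zero accuracy contributes zero points
  resp0 <- generate_responses(40, 0, "HAHV", seed = 1)
  expect_identical(sum(score_items(resp0)), 0L)
})

test_that("generators are reproducible and writers round-trip", {
  a <- generate_cohort(cohort_spec(seed = 5))
  b <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(a$features, b$features)
  expect_identical(a$scores, b$scores)

  rr <- sine_rr(0.1, duration = 60, noise_sd = 5, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, tmp)
  rr2 <- read_rr_csv(tmp)
  expect_equal(rr2$beat_times, rr$beat_times)
  expect_identical(rr2$flags, rr$flags)

  ecg <- synthesize_ecg(rr_series(c(0, 0.8, 1.6, 2.4, 3.2, 4.0, 4.8, 5.6,
                                    6.4, 7.2, 8.0, 8.8, 9.6, 10.4)), 250)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(ecg, tmp2)
  ecg2 <- read_ecg_csv(tmp2)
  expect_identical(ecg2$fs, 250)
  expect_equal(ecg2$samples, ecg$samples, tolerance = 1e-8)
})
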