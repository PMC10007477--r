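test_that("time-domain indices match their defining formulas", {
  expect_equal(time_domain_indices(rr_from_intervals(rep(800, 4))),
               c(BPM = 75, SDNN = 0, RMSSD = 0, pNN50 = 0))
  td <- time_domain_indices(rr_from_intervals(c(700, 750, 800, 850)))
  expect_equal(td[["BPM"]], 60000 / 775, tolerance = 1e-9)
  expect_equal(td[["SDNN"]], sqrt(12500 / 3), tolerance = 1e-9)
  expect_equal(td[["RMSSD"]], 50, tolerance = 1e-9)
  expect_identical(td[["pNN50"]], 0)  # differences of exactly 50 do not count
  expect_equal(time_domain_indices(rr_from_intervals(c(800, 860, 800)))[["pNN50"]],
               100)
  expect_error(time_domain_indices(rr_from_intervals(c(800, 810))), "at least 3")
})

test_that("spectrum of a constant tachogram is numerically empty", {
  rr <- rr_from_intervals(rep(800, 500))
  sp <- power_spectrum(rr)
  expect_lt(sum(sp$power) * sp$df, 1e-6)
})

test_that("spectral peak lands within one bin of the modulation frequency", {
  for (f0 in c(0.1, 0.25)) {
    sp <- power_spectrum(sine_rr(f0))
    expect_lte(abs(sp$freq[which.max(sp$power)] - f0), sp$df)
  }
})

test_that("spectrum integrates to the tachogram variance", {
  rr <- sine_rr(0.25, amplitude = 40, noise_sd = 10, seed = 3)
  sp <- power_spectrum(rr)
  tac <- retained_intervals(rr, with_times = TRUE)
  grid <- seq(tac$times[1], tac$times[length(tac$times)], by = 0.25)
  v <- var(stats::spline(tac$times, tac$intervals, xout = grid)$y)
  expect_equal(sum(sp$power) * sp$df, v, tolerance = 0.1)
})

test_that("band powers concentrate in the band of the driving frequency", {
  bp_lf <- band_powers(power_spectrum(sine_rr(0.1, noise_sd = 2, seed = 2)))
  expect_gte(bp_lf[["LFp"]], 0.95)
  bp_hf <- band_powers(power_spectrum(sine_rr(0.25, noise_sd = 2, seed = 2)))
  expect_gte(bp_hf[["HFp"]], 0.95)
})

test_that("frequency-domain identities hold on a real spectrum", {
  bp <- band_powers(power_spectrum(sine_rr(0.25, noise_sd = 8, seed = 9)))
  expect_equal(bp[["VLFp"]] + bp[["LFp"]] + bp[["HFp"]], 1, tolerance = 1e-9)
  expect_equal(exp(bp[["lnVLF"]]), bp[["VLF"]], tolerance = 1e-12)
  expect_equal(exp(bp[["lnLF"]]), bp[["LF"]], tolerance = 1e-12)
  expect_equal(exp(bp[["lnHF"]]), bp[["HF"]], tolerance = 1e-12)
  expect_equal(bp[["LF_HF"]], bp[["LF"]] / bp[["HF"]], tolerance = 1e-12)
  expect_equal(bp[["VLF_HF"]], bp[["VLF"]] / bp[["HF"]], tolerance = 1e-12)
  expect_identical(bp[["tHz"]], bp[["tPow"]])
  expect_gte(bp[["CohRatio"]], 0)
  expect_true(bp[["dHz"]] >= 0.0033 && bp[["dHz"]] <= 0.4)
  expect_equal(bp[["CohRatio"]],
               bp[["dPow"]] / (bp[["tPow"]] - bp[["dPow"]]), tolerance = 1e-12)
})

test_that("band integrals are additive and logs of constructed powers exact", {
  sp <- power_spectrum(sine_rr(0.25, noise_sd = 8, seed = 9))
  whole <- hrvei:::band_integral(sp, c(0.05, 0.35))
  parts <- hrvei:::band_integral(sp, c(0.05, 0.2)) +
    hrvei:::band_integral(sp, c(0.2, 0.35))
  expect_equal(whole, parts, tolerance = 1e-9)

  # constructed flat spectrum: HF power e gives lnHF exactly 1, and
  # relative powers are proportional to band widths 0.0367 : 0.11 : 0.25
  cfg <- spectral_config()
  dens <- exp(1) / 0.25  # flat density making HF integrate to e
  flat <- structure(list(freq = seq(0.002, 0.5, by = 0.002),
                         power = rep(dens, 250), df = 0.002, n_segments = 1,
                         cfg = cfg), class = "hrv_spectrum")
  bp <- band_powers(flat)
  expect_equal(bp[["lnHF"]], 1, tolerance = 1e-9)
  widths <- c(0.0367, 0.11, 0.25)
  expect_equal(unname(bp[c("VLFp", "LFp", "HFp")]), widths / sum(widths),
               tolerance = 1e-3)
})

test_that("a dominant single tone yields the constructed coherence ratio", {
  cfg <- spectral_config()
  f <- seq(0.002, 0.5, by = 0.002)
  # narrow triangular peak at 0.25 Hz carrying 90% of power, rest flat
  peak <- pmax(0, 1 - abs(f - 0.25) / 0.01)
  peak <- peak / (sum(peak) * 0.002) * 0.9
  base <- rep(1, length(f))
  base[f < 0.0033 | f > 0.4 | abs(f - 0.25) <= 0.016] <- 0
  base <- base / (sum(base) * 0.002) * 0.1
  sp <- structure(list(freq = f, power = peak + base, df = 0.002,
                       n_segments = 1, cfg = cfg), class = "hrv_spectrum")
  bp <- band_powers(sp)
  expect_equal(bp[["dHz"]], 0.25, tolerance = 0.002)
  expect_equal(bp[["CohRatio"]], 9, tolerance = 0.5)
})

test_that("scaling interval deviations scales SDNN/RMSSD linearly and power quadratically", {
  rr1 <- sine_rr(0.25, amplitude = 20, duration = 360)
  x <- rr1$intervals
  rr2 <- rr_from_intervals(mean(x) + 2 * (x - mean(x)))
  td1 <- time_domain_indices(rr1)
  td2 <- time_domain_indices(rr2)
  expect_equal(td2[["SDNN"]], 2 * td1[["SDNN"]], tolerance = 1e-9)
  expect_equal(td2[["RMSSD"]], 2 * td1[["RMSSD"]], tolerance = 1e-9)
  hf1 <- band_powers(power_spectrum(rr1))[["HF"]]
  hf2 <- band_powers(power_spectrum(rr2))[["HF"]]
  expect_equal(hf2 / hf1, 4, tolerance = 0.05)  # beat times shift slightly
})

test_that("RSA reflects in-band peak-to-trough excursion", {
  expect_identical(rsa(rr_from_intervals(rep(800, 200))), 0)
  expect_equal(rsa(sine_rr(0.25)), 100, tolerance = 5)
  expect_lt(rsa(sine_rr(0.05)), 5)  # outside the respiratory band
  expect_error(rsa(rr_from_intervals(rep(800, 20))), "60 s")
})

test_that("sliding windows tile the epoch as floor((span - window)/step) + 1", {
  rr <- sine_rr(0.25, noise_sd = 5, duration = 360, seed = 5)
  sh <- sliding_hrv(rr, window = 180, step = 10)
  expect_identical(nrow(sh$values), 19L)
  expect_equal(sh$window_centers[1], 90)
  expect_equal(sh$window_centers[19], 270)
  one <- sliding_hrv(sine_rr(0.25, duration = 180, seed = 2), window = 180)
  expect_identical(nrow(one$values), 1L)
  expect_error(sliding_hrv(sine_rr(0.25, duration = 100, seed = 2),
                           window = 180), "longer than the epoch")
})

test_that("windowed SDNN is steadier for stationary than step-change input", {
  stat_rr <- sine_rr(0.25, noise_sd = 10, duration = 360, seed = 10)
  x <- stat_rr$intervals
  step_x <- x + rep(c(0, 150), c(length(x) %/% 2, length(x) - length(x) %/% 2))
  step_rr <- rr_from_intervals(step_x)
  v_stat <- var(sliding_hrv(stat_rr, 180, 10)$values[, "SDNN"], na.rm = TRUE)
  v_step <- var(sliding_hrv(step_rr, 180, 10)$values[, "SDNN"], na.rm = TRUE)
  expect_lt(v_stat, v_step)
})

test_that("RMSSD squared equals the MSSD of the same interval sequence", {
  set.seed(31)
  iv <- runif(100, 650, 950)
  rr <- rr_from_intervals(iv)
  expect_equal(time_domain_indices(rr)[["RMSSD"]]^2, instability(rr$intervals),
               tolerance = 1e-12)
})
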