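#' Spectral analysis configuration
#'
#' Settings for tachogram spectral estimation: even resampling rate, Welch
#' segmentation, taper, and the frequency bands. Defaults follow the field
#' convention: VLF 0.0033-0.04, LF 0.04-0.15, HF 0.15-0.40 Hz. The
#' alternative overlapping band set sometimes printed in index tables
#' (LF from 0.004 Hz, HF from 0.015 Hz) is available via
#' `printed_bands = TRUE`; it is internally inconsistent (bands overlap) and
#' kept only for comparison.
#'
#' @param resample_rate tachogram resampling rate, Hz.
#' @param segment_length Welch segment length, s.
#' @param overlap Welch segment overlap fraction in `[0, 1)`.
#' @param taper `"hann"` or `"none"`.
#' @param vlf_band,lf_band,hf_band band limits, Hz.
#' @param peak_halfwidth half-width, Hz, of the integration window around
#'   the dominant spectral peak used for `dPow`; a single-bin peak power
#'   would make the coherence ratio depend on frequency resolution.
#' @param printed_bands use the literal overlapping band set.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(resample_rate = 4, segment_length = 120,
                            overlap = 0.5, taper = c("hann", "none"),
                            vlf_band = c(0.0033, 0.04),
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            peak_halfwidth = 0.015,
                            printed_bands = FALSE) {
  taper <- match.arg(taper)
  if (printed_bands) {
    lf_band <- c(0.004, 0.15)
    hf_band <- c(0.015, 0.40)
  }
  bands <- list(vlf = vlf_band, lf = lf_band, hf = hf_band)
  for (b in bands) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] > resample_rate / 2) {
      stop("each band must be an ascending pair within (0, resample_rate/2)")
    }
  }
  if (!printed_bands &&
      (vlf_band[2] > lf_band[1] + 1e-12 || lf_band[2] > hf_band[1] + 1e-12)) {
    stop("bands must be non-overlapping and ascending")
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  structure(
    list(resample_rate = resample_rate, segment_length = segment_length,
         overlap = overlap, taper = taper,
         vlf_band = vlf_band, lf_band = lf_band, hf_band = hf_band,
         total_band = c(vlf_band[1], hf_band[2]),
         peak_halfwidth = peak_halfwidth, printed_bands = printed_bands),
    class = "spectral_config"
  )
}

#' Time-domain HRV indices
#'
#' `BPM = 60000 / mean(RR)`; `SDNN` is the sample standard deviation of the
#' retained intervals; `RMSSD` the root mean square of successive
#' differences; `pNN50` the percentage of successive differences strictly
#' greater than 50 ms in absolute value.
#'
#' @param rr an [rr_series()] with at least 3 retained intervals.
#' @return Named numeric vector `BPM`, `SDNN`, `RMSSD`, `pNN50`.
#' @examples
#' rr <- rr_series(c(0, 0.7, 1.45, 2.25, 3.1))
#' time_domain_indices(rr)
#' @export
time_domain_indices <- function(rr) {
  x <- retained_intervals(rr)
  if (length(x) < 3) stop("need at least 3 retained intervals")
  dx <- diff(x)
  c(BPM = 60000 / mean(x),
    SDNN = sd(x),
    RMSSD = sqrt(mean(dx^2)),
    pNN50 = 100 * mean(abs(dx) > 50 + 1e-9))  # strict: exactly 50 ms does not count
}

# cubic resampling of the retained tachogram onto an even grid
resample_tachogram <- function(rr, rate) {
  tac <- retained_intervals(rr, with_times = TRUE)
  if (length(tac$intervals) < 4) stop("too few retained intervals to resample")
  grid <- seq(tac$times[1], tac$times[length(tac$times)], by = 1 / rate)
  list(t = grid, x = spline(tac$times, tac$intervals, xout = grid)$y)
}

#' Tachogram power spectrum
#'
#' Welch's averaged periodogram of the evenly resampled tachogram: cubic
#' interpolation at `resample_rate`, per-segment linear detrend and taper,
#' one-sided density scaled so that the integral over frequency equals the
#' tachogram variance (for stationary input).
#'
#' @param rr an [rr_series()] whose span is at least one segment.
#' @param cfg a [spectral_config()].
#' @return An object of class `hrv_spectrum`: list with `freq` (Hz),
#'   `power` (ms^2/Hz), `df` (bin width), `n_segments`, `cfg`.
#' @export
power_spectrum <- function(rr, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  rs <- resample_tachogram(rr, cfg$resample_rate)
  n <- length(rs$x)
  segn <- round(cfg$segment_length * cfg$resample_rate)
  if (n < segn) {
    stop("epoch too short for spectral analysis: ",
         sprintf("%.0f s < %g s segment", n / cfg$resample_rate,
                 cfg$segment_length))
  }
  step <- max(1L, round(segn * (1 - cfg$overlap)))
  starts <- seq(1L, n - segn + 1L, by = step)
  w <- if (cfg$taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(segn - 1)) / (segn - 1))
  } else {
    rep(1, segn)
  }
  u <- sum(w^2)
  nf <- floor(segn / 2)
  acc <- numeric(nf)
  tt <- seq_len(segn)
  for (s in starts) {
    seg <- rs$x[s:(s + segn - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)   # linear detrend
    seg <- fit$residuals
    X <- fft(seg * w)
    acc <- acc + (2 / (cfg$resample_rate * u)) * Mod(X[2:(nf + 1L)])^2
  }
  structure(
    list(freq = (1:nf) * cfg$resample_rate / segn,
         power = acc / length(starts),
         df = cfg$resample_rate / segn,
         n_segments = length(starts),
         cfg = cfg),
    class = "hrv_spectrum"
  )
}

# trapezoidal band integral with interpolated band edges; bands clipped to
# the resolvable frequency range of the spectrum
band_integral <- function(spec, band) {
  lo <- max(band[1], spec$freq[1])
  hi <- min(band[2], spec$freq[length(spec$freq)])
  if (hi <= lo) return(0)
  inner <- spec$freq[spec$freq > lo & spec$freq < hi]
  xs <- c(lo, inner, hi)
  ys <- approx(spec$freq, spec$power, xout = xs)$y
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Frequency-domain HRV indices from a spectrum
#'
#' Band powers (`VLF`, `LF`, `HF`, ms^2) by trapezoidal integration over the
#' configured bands; natural logs (`lnVLF`, `lnLF`, `lnHF`, defined only for
#' strictly positive powers); relative powers normalized by the three-band
#' sum so `VLFp + LFp + HFp == 1`; the ratios `VLF_HF` and `LF_HF`; total
#' power `tPow` over the full analysis band (`tHz` is reported as an equal
#' duplicate field, matching the conventional 21-index table); the dominant
#' peak frequency `dHz`, the power `dPow` integrated within
#' `peak_halfwidth` of it, and the coherence ratio
#' `CohRatio = dPow / (tPow - dPow)`.
#'
#' @param spectrum an `hrv_spectrum` from [power_spectrum()]; must resolve
#'   the upper edge of the analysis band.
#' @param cfg a [spectral_config()]; defaults to the one stored in
#'   `spectrum`.
#' @return Named numeric vector of the 16 frequency-domain indices.
#' @export
band_powers <- function(spectrum, cfg = spectrum$cfg) {
  stopifnot(inherits(spectrum, "hrv_spectrum"))
  total_band <- c(cfg$vlf_band[1], cfg$hf_band[2])
  if (spectrum$freq[length(spectrum$freq)] < total_band[2] - 1e-9) {
    stop("spectrum does not cover the analysis band up to ",
         total_band[2], " Hz")
  }
  vlf <- band_integral(spectrum, cfg$vlf_band)
  lf <- band_integral(spectrum, cfg$lf_band)
  hf <- band_integral(spectrum, cfg$hf_band)
  if (min(vlf, lf, hf) <= 0) {
    stop("zero band power: log-scaled indices are undefined")
  }
  three <- vlf + lf + hf
  tpow <- band_integral(spectrum, total_band)
  inband <- spectrum$freq >= total_band[1] & spectrum$freq <= total_band[2]
  fi <- spectrum$freq[inband]
  pi_ <- spectrum$power[inband]
  dhz <- fi[which.max(pi_)]
  dpow <- band_integral(spectrum, c(dhz - cfg$peak_halfwidth,
                                    dhz + cfg$peak_halfwidth))
  if (tpow - dpow <= 0) {
    stop("dominant peak carries the entire band power: coherence ratio undefined")
  }
  c(VLF = vlf, LF = lf, HF = hf,
    lnVLF = log(vlf), lnLF = log(lf), lnHF = log(hf),
    VLFp = vlf / three, LFp = lf / three, HFp = hf / three,
    VLF_HF = vlf / hf, LF_HF = lf / hf,
    tPow = tpow, dPow = dpow, tHz = tpow, dHz = dhz,
    CohRatio = dpow / (tpow - dpow))
}

#' Respiratory sinus arrhythmia, peak-valley estimate
#'
#' Band-passes the evenly resampled tachogram to the respiratory band,
#' identifies cycles from zero crossings and returns the mean peak-to-trough
#' excursion in ms. Listed among the time-domain indices by convention;
#' this peak-valley definition keeps it distinct from HF power. The
#' respiratory band is fixed a priori because no respiration channel is
#' assumed.
#'
#' @param rr an [rr_series()] spanning at least 60 s.
#' @param band respiratory band, Hz.
#' @param resample_rate tachogram resampling rate, Hz.
#' @param edge_trim seconds discarded at each end after filtering (filter
#'   transients).
#' @return RSA in ms; 0 by convention when the band carries essentially no
#'   power (< 1e-6 ms^2 variance).
#' @export
rsa <- function(rr, band = c(0.12, 0.40), resample_rate = 4, edge_trim = 10) {
  span <- diff(rr_span(rr))
  if (span < 60) stop("RSA needs an epoch of at least 60 s")
  rs <- resample_tachogram(rr, resample_rate)
  bf <- signal::butter(3, band / (resample_rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, rs$x - mean(rs$x))
  keep <- rs$t > rs$t[1] + edge_trim & rs$t < rs$t[length(rs$t)] - edge_trim
  xf <- xf[keep]
  if (var(xf) < 1e-6) return(0)
  zc <- which(diff(sign(xf)) != 0)
  if (length(zc) < 3) stop("no complete respiratory cycle in the epoch")
  exc <- vapply(seq_len(length(zc) - 2L), function(i) {
    seg <- xf[zc[i]:zc[i + 2L]]
    max(seg) - min(seg)
  }, numeric(1))
  mean(exc)
}

#' Full 21-index HRV set for one epoch or window
#'
#' Combines [time_domain_indices()], [rsa()] and [band_powers()] of
#' [power_spectrum()] into the canonical index vector (see
#' [hrv_index_names()]).
#'
#' @param rr an [rr_series()].
#' @param cfg a [spectral_config()].
#' @return Named numeric vector of length 21, in canonical order.
#' @export
hrv_indices <- function(rr, cfg = spectral_config()) {
  td <- time_domain_indices(rr)
  fd <- band_powers(power_spectrum(rr, cfg))
  out <- c(td, RSA = rsa(rr, resample_rate = cfg$resample_rate))
  out <- c(out, fd)
  out[hrv_index_names()]
}

#' Sliding-window HRV index time series
#'
#' Advances a fixed-length window in fixed steps across the epoch span and
#' computes the full index set in each window; windows lie entirely inside
#' the epoch, so an epoch of span `S` yields `floor((S - window)/step) + 1`
#' windows. A window whose computation fails (e.g. too few beats after
#' cleaning) contributes a row of `NA`s rather than aborting the series.
#'
#' @param rr an [rr_series()]; the epoch span is taken from its
#'   `t_start`/`t_end` attributes (set by [segment_epochs()] and the
#'   generators) or, failing that, from the beat-time range.
#' @param window window length, s (180 s by default: long enough to resolve
#'   the low end of the LF band while tracking within-session change).
#' @param step window advance, s.
#' @param cfg a [spectral_config()]; its `segment_length` must not exceed
#'   `window`.
#' @return An object of class `hrv_time_series`: list with
#'   `window_centers` (s), `values` (windows x 21 matrix), `window`, `step`.
#' @export
sliding_hrv <- function(rr, window = 180, step = 10, cfg = spectral_config()) {
  span <- rr_span(rr)
  if (window > diff(span) + 1e-9) stop("window longer than the epoch")
  if (cfg$segment_length > window) {
    stop("spectral segment_length exceeds the sliding window")
  }
  n_win <- floor((diff(span) - window) / step + 1e-9) + 1L
  later <- rr$beat_times[-1]
  vals <- matrix(NA_real_, n_win, length(hrv_index_names()),
                 dimnames = list(NULL, hrv_index_names()))
  centers <- numeric(n_win)
  for (k in seq_len(n_win)) {
    s0 <- span[1] + (k - 1L) * step
    s1 <- s0 + window
    centers[k] <- s0 + window / 2
    idx <- which(later >= s0 & later < s1 + 1e-9)
    if (length(idx) < 2) next
    sub <- rr_series(rr$beat_times[min(idx):(max(idx) + 1L)],
                     flags = rr$flags[idx], t_start = s0, t_end = s1)
    vals[k, ] <- tryCatch(hrv_indices(sub, cfg), error = function(e) {
      rep(NA_real_, ncol(vals))
    })
  }
  structure(
    list(window_centers = centers, values = vals, window = window,
         step = step, cfg = cfg),
    class = "hrv_time_series"
  )
}

#' @export
print.hrv_time_series <- function(x, ...) {
  cat(sprintf("<hrv_time_series> %d windows of %g s (step %g s), %d indices\n",
              nrow(x$values), x$window, x$step, ncol(x$values)))
  invisible(x)
}

#' Write per-window HRV indices as tidy CSV
#'
#' Long format: `participant`, `epoch`, `window_center_s`, `index`,
#' `value`.
#'
#' @param hts an `hrv_time_series` from [sliding_hrv()].
#' @param path file path.
#' @param participant,epoch labels stamped on every row.
#' @export
write_hrv_windows_csv <- function(hts, path, participant = NA_character_,
                                  epoch = NA_character_) {
  stopifnot(inherits(hts, "hrv_time_series"))
  df <- data.frame(
    participant = participant,
    epoch = epoch,
    window_center_s = rep(hts$window_centers, ncol(hts$values)),
    index = rep(colnames(hts$values), each = nrow(hts$values)),
    value = as.vector(hts$values)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
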