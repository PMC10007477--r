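#' Canonical HRV index names
#'
#' The 21 indices computed per analysis window: four time-domain statistics,
#' respiratory sinus arrhythmia, and sixteen frequency-domain quantities
#' derived from the tachogram power spectrum. `tHz` duplicates `tPow` (both
#' are the absolute power over the full 0.0033-0.4 Hz analysis band); the two
#' are kept as separate fields for compatibility with the conventional index
#' table, see [band_powers()].
#'
#' @return Character vector of length 21.
#' @export
hrv_index_names <- function() {
  c("BPM", "SDNN", "RMSSD", "pNN50", "RSA",
    "VLF", "LF", "HF", "lnVLF", "lnLF", "lnHF",
    "VLFp", "LFp", "HFp", "VLF_HF", "LF_HF",
    "tPow", "dPow", "tHz", "dHz", "CohRatio")
}

#' Affect-dynamics feature names
#'
#' Expands the 21 HRV index names into the dynamics-derived feature names
#' (`variability_<index>`, `instability_<index>`, `inertia_<index>`) used by
#' [participant_features()] and accepted by [cohort_spec()] effect maps.
#'
#' @param stats which dynamics statistics to expand.
#' @return Character vector.
#' @export
dynamics_feature_names <- function(stats = c("variability", "instability", "inertia")) {
  stats <- match.arg(stats, several.ok = TRUE)
  as.vector(t(outer(stats, hrv_index_names(), paste, sep = "_")))
}

#' RR-interval series
#'
#' The substrate of all HRV computation: strictly increasing beat times in
#' seconds and the successive inter-beat (RR) intervals in milliseconds,
#' with a per-interval quality flag (`"ok"`, `"rejected"` or
#' `"interpolated"`). The interval/time identity
#' `intervals[i] == 1000 * (beat_times[i+1] - beat_times[i])` is enforced at
#' construction and preserved by every operation in the package (rejected
#' intervals are excluded from statistics, never deleted).
#'
#' @param beat_times numeric, beat times in seconds, strictly increasing,
#'   length >= 2.
#' @param flags optional character vector of per-interval quality flags
#'   (length `length(beat_times) - 1`); defaults to all `"ok"`.
#' @param t_start,t_end optional epoch bounds in seconds carried as
#'   attributes; used by [sliding_hrv()] to place windows.
#' @return An object of class `rr_series`: a list with elements
#'   `beat_times`, `intervals` (ms) and `flags`.
#' @examples
#' rr <- rr_series(c(0, 0.8, 1.6, 2.4))
#' rr$intervals
#' @export
rr_series <- function(beat_times, flags = NULL, t_start = NULL, t_end = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    stop("an RR series needs at least 2 beats, got ", length(beat_times))
  }
  if (any(diff(beat_times) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  intervals <- 1000 * diff(beat_times)
  if (is.null(flags)) flags <- rep("ok", length(intervals))
  flags <- as.character(flags)
  if (length(flags) != length(intervals)) {
    stop("flags must have one entry per interval")
  }
  bad <- setdiff(unique(flags), c("ok", "rejected", "interpolated"))
  if (length(bad)) stop("unknown quality flag: ", paste(bad, collapse = ", "))
  out <- structure(
    list(beat_times = beat_times, intervals = intervals, flags = flags),
    class = "rr_series"
  )
  attr(out, "t_start") <- t_start
  attr(out, "t_end") <- t_end
  out
}

#' @export
print.rr_series <- function(x, ...) {
  n_rej <- sum(x$flags == "rejected")
  cat(sprintf(
    "<rr_series> %d beats, %d intervals (%d rejected), %.1f-%.1f s, mean RR %.1f ms\n",
    length(x$beat_times), length(x$intervals), n_rej,
    x$beat_times[1], x$beat_times[length(x$beat_times)],
    mean(retained_intervals(x))
  ))
  invisible(x)
}

#' Retained intervals of an RR series
#'
#' Intervals not flagged `"rejected"`; all downstream statistics are
#' computed on these.
#'
#' @param rr an [rr_series()].
#' @param with_times if `TRUE`, return a list with the intervals and the
#'   time of the later beat of each retained pair (the tachogram sample
#'   time convention used throughout).
#' @return Numeric vector of intervals in ms, or a list
#'   `(times, intervals)`.
#' @export
retained_intervals <- function(rr, with_times = FALSE) {
  stopifnot(inherits(rr, "rr_series"))
  keep <- rr$flags != "rejected"
  if (!with_times) return(rr$intervals[keep])
  list(times = rr$beat_times[-1][keep], intervals = rr$intervals[keep])
}

# epoch span of a series: explicit attributes when present, else beat range
rr_span <- function(rr) {
  t0 <- attr(rr, "t_start")
  t1 <- attr(rr, "t_end")
  if (is.null(t0)) t0 <- rr$beat_times[1]
  if (is.null(t1)) t1 <- rr$beat_times[length(rr$beat_times)]
  c(t0, t1)
}

#' Write / read an RR series as CSV
#'
#' Two data columns (`beat_time_s`, `rr_ms`): one row per beat, with the
#' interval that *ends* at that beat (first beat has `rr_ms = NA`). A third
#' `flag` column carries quality flags so a cleaned series round-trips.
#'
#' @param rr an [rr_series()].
#' @param path file path.
#' @return `write_rr_csv` returns `path` invisibly; `read_rr_csv` returns an
#'   [rr_series()].
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(
    beat_time_s = rr$beat_times,
    rr_ms = c(NA_real_, rr$intervals),
    flag = c(NA_character_, rr$flags)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rr_series(df$beat_time_s, flags = df$flag[-1])
}
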