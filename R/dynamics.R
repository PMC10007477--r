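#' Affect-dynamics statistics of a feature time series
#'
#' The dynamics triad summarises how a per-window HRV index evolves:
#' `variability` is the sample variance (how widely the index ranges),
#' `instability` the mean squared successive difference (MSSD; how abruptly
#' it moves from one window to the next), and `inertia` the lag-1
#' autocorrelation (how strongly the current state carries over).
#'
#' `variability(x)` requires >= 3 non-missing values and uses the n-1
#' denominator. For identical inputs `instability` equals `RMSSD^2` of
#' [time_domain_indices()] exactly.
#'
#' @param x numeric series (per-window index values); `NA`s are dropped
#'   (`variability`) or break the successive-pair chain (`instability`,
#'   `inertia`).
#' @return A single numeric value.
#' @examples
#' variability(c(1, 2, 3, 4))   # 1.667
#' instability(c(1, 2, 3, 4))   # 1
#' inertia(c(1, 2, 1, 2, 1, 2)) # -1
#' @export
variability <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("variability needs at least 3 non-missing values")
  var(x)
}

#' @rdname variability
#' @export
instability <- function(x) {
  n <- length(x)
  if (n < 2) stop("instability needs at least 2 consecutive values")
  a <- x[-n]
  b <- x[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid consecutive pair (gaps break the chain)")
  mean((b[ok] - a[ok])^2)
}

#' @rdname variability
#' @export
inertia <- function(x) {
  a <- x[-length(x)]
  b <- x[-1]
  ok <- !is.na(a) & !is.na(b)
  if (sum(!is.na(x)) < 4 || sum(ok) < 3) {
    stop("inertia needs at least 4 values")
  }
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    stop("inertia is undefined for a constant series")
  }
  cor(a[ok], b[ok])
}

#' Baseline-normalize a feature value
#'
#' Expresses a stimulus-epoch feature relative to the participant's neutral
#' baseline, removing between-person physiological offsets. The default is
#' the difference `stimulus - baseline` (translation-invariant and defined
#' for zero baselines); `mode = "ratio"` gives `stimulus/baseline - 1`.
#'
#' @param stimulus_value,baseline_value finite numeric values of the same
#'   index.
#' @param mode `"difference"` or `"ratio"`.
#' @return The normalized value.
#' @export
normalize_to_baseline <- function(stimulus_value, baseline_value,
                                  mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (!all(is.finite(stimulus_value)) || !all(is.finite(baseline_value))) {
    stop("values must be finite")
  }
  if (mode == "difference") {
    stimulus_value - baseline_value
  } else {
    if (any(baseline_value == 0)) stop("ratio mode needs a nonzero baseline")
    stimulus_value / baseline_value - 1
  }
}

#' Per-participant feature record from per-epoch HRV window series
#'
#' For each of the 21 indices and each stimulus session: the HRV feature is
#' the mean over stimulus-epoch windows minus the mean over baseline-epoch
#' windows, and the three dynamics statistics are computed on the
#' baseline-normalized per-window series spanning the whole session
#' (baseline, stimulus, and any trailing epoch concatenated in time, each
#' window value minus the baseline-window mean). Features are then averaged
#' across the emotional-domain sessions into one record per participant;
#' per-session values are available with `average_sessions = FALSE`.
#'
#' @param sessions a list (one element per emotional-domain session) of
#'   lists with components `baseline` and `stimulus` (both
#'   `hrv_time_series` from [sliding_hrv()]) and optionally `post`.
#' @param average_sessions average across sessions (the default) or return
#'   the per-session matrix.
#' @return A named numeric vector with elements `<index>` (HRV change
#'   scores) and `variability_<index>`, `instability_<index>`,
#'   `inertia_<index>`; or, if `average_sessions = FALSE`, a matrix with
#'   one row per session.
#' @export
participant_features <- function(sessions, average_sessions = TRUE) {
  if (!length(sessions)) stop("no sessions supplied")
  one <- function(sess) {
    if (is.null(sess$baseline) || is.null(sess$stimulus)) {
      miss <- setdiff(c("baseline", "stimulus"),
                      names(sess)[!vapply(sess, is.null, TRUE)])
      stop("session is missing epoch(s): ", paste(miss, collapse = ", "))
    }
    idx <- colnames(sess$baseline$values)
    base_mean <- colMeans(sess$baseline$values, na.rm = TRUE)
    stim_mean <- colMeans(sess$stimulus$values, na.rm = TRUE)
    hrv_feat <- normalize_to_baseline(stim_mean, base_mean)
    parts <- list(sess$baseline$values, sess$stimulus$values)
    if (!is.null(sess$post)) parts <- c(parts, list(sess$post$values))
    series <- do.call(rbind, parts)
    series <- sweep(series, 2, base_mean)
    dyn <- sapply(c(variability = variability, instability = instability,
                    inertia = inertia),
                  function(f) {
                    apply(series, 2, function(v) {
                      tryCatch(f(v), error = function(e) NA_real_)
                    })
                  })
    out <- c(hrv_feat,
             stats::setNames(dyn[, "variability"], paste0("variability_", idx)),
             stats::setNames(dyn[, "instability"], paste0("instability_", idx)),
             stats::setNames(dyn[, "inertia"], paste0("inertia_", idx)))
    out
  }
  per_session <- t(vapply(sessions, one,
                          numeric(4 * length(hrv_index_names()))))
  if (!average_sessions) return(per_session)
  colMeans(per_session, na.rm = TRUE)
}

#' Write a participant-by-feature table as CSV
#'
#' Feature columns are named `<index>` for the baseline-normalized HRV
#' change scores and `<stat>_<index>` (e.g. `instability_lnHF`) for the
#' dynamics expansions.
#'
#' @param features a data frame / tibble of participant feature records.
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
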