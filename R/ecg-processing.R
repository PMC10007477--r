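#' ECG record container
#'
#' A single-lead ECG as a plain sample vector with sampling-rate metadata
#' and optional epoch annotations.
#'
#' @param samples numeric sample values (mV), non-empty.
#' @param fs sampling rate, Hz (> 0).
#' @param participant_id optional participant label.
#' @param annotations optional epoch table, see [epoch_table()].
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, participant_id = NA_character_,
                       annotations = NULL) {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.null(annotations)) {
    validate_epochs(annotations, record_end = (length(samples) - 1) / fs)
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         participant_id = participant_id, annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, (length(x$samples) - 1) / x$fs))
  invisible(x)
}

#' Epoch annotation table
#'
#' Session structure for one stimulus presentation: a ~360 s neutral
#' baseline, a ~360 s emotional stimulus, and a ~180 s trailing neutral
#' epoch. Times are seconds from record start; epochs are half-open
#' `[start, end)` and must not overlap.
#'
#' @param start_s,end_s epoch bounds, s.
#' @param kind one of `"baseline_neutral"`, `"stimulus"`, `"post_neutral"`
#'   per epoch.
#' @param domain emotional domain of stimulus epochs (`"HAHV"`, `"HALV"`,
#'   `"LALV"`, `"LAHV"`); `"none"` for neutral epochs.
#' @return A tibble with one row per epoch.
#' @export
epoch_table <- function(start_s, end_s,
                        kind = c("baseline_neutral", "stimulus", "post_neutral"),
                        domain = "none") {
  out <- tibble::tibble(start_s = start_s, end_s = end_s,
                        kind = kind, domain = domain)
  validate_epochs(out)
  out
}

validate_epochs <- function(ann, record_end = NULL, tol = 5) {
  need <- c("start_s", "end_s", "kind", "domain")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns: ", paste(need, collapse = ", "))
  }
  if (any(!ann$kind %in% c("baseline_neutral", "stimulus", "post_neutral"))) {
    stop("unknown epoch kind")
  }
  if (any(!ann$domain %in% c("HAHV", "HALV", "LALV", "LAHV", "none"))) {
    stop("unknown emotional domain")
  }
  if (any(ann$end_s <= ann$start_s)) stop("epoch end must exceed start")
  o <- order(ann$start_s)
  if (nrow(ann) > 1 &&
      any(ann$start_s[o][-1] < ann$end_s[o][-nrow(ann)] - 1e-9)) {
    stop("epochs must not overlap")
  }
  if (!is.null(record_end) && any(ann$end_s > record_end + tol)) {
    stop("annotation extends past the end of the record")
  }
  invisible(ann)
}

#' Detect R peaks in an ECG record
#'
#' Pan-Tompkins-style detection: band-pass 5-15 Hz (3rd-order Butterworth,
#' zero-phase), differentiate, square, 150-ms moving average, then an
#' adaptive signal/noise threshold over the local maxima of the detection
#' function with a 200-ms refractory period. Each detection is refined to
#' the argmax of the raw signal within +/- 75 ms, so reported times sit on
#' the R wave itself.
#'
#' @param ecg an [ecg_record()], >= 10 s long, `fs >= 100` Hz.
#' @return Beat times in seconds from record start (possibly empty, with a
#'   warning, when no peak exceeds the adaptive threshold).
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  if (fs < 100) stop("fs must be >= 100 Hz for R-peak detection")
  x <- ecg$samples
  if ((length(x) - 1) / fs < 10) stop("record must be at least 10 s long")
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    warning("flat signal: no R peaks detected")
    return(numeric(0))
  }
  # zero-pad so beats at the record edges keep both flanks of their
  # detection-function peak
  pad <- round(0.5 * fs)
  x <- c(numeric(pad), x, numeric(pad))
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  d <- c(0, diff(xf)) * fs
  win <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(d^2, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  if (max(integ) <= 0) {
    warning("no peak exceeds the adaptive threshold")
    return(numeric(0))
  }
  cand <- which(diff(sign(diff(integ))) == -2) + 1L
  if (!length(cand)) {
    warning("no peak exceeds the adaptive threshold")
    return(numeric(0))
  }
  init <- integ[seq_len(min(length(integ), round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init)
  thr <- npki + 0.25 * (spki - npki)
  refr <- round(0.2 * fs)
  peaks <- integer(0)
  for (i in cand) {
    if (integ[i] >= thr) {
      if (length(peaks) && (i - peaks[length(peaks)]) < refr) {
        if (integ[i] > integ[peaks[length(peaks)]]) peaks[length(peaks)] <- i
      } else {
        peaks <- c(peaks, i)
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) {
    warning("no peak exceeds the adaptive threshold")
    return(numeric(0))
  }
  half <- round(0.075 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    (lo + which.max(x[lo:hi]) - 2L - pad) / fs
  }, numeric(1))
  dur <- (length(ecg$samples) - 1) / fs
  sort(unique(refined[refined >= 0 & refined <= dur]))
}

#' RR series from beat times
#'
#' @param beat_times strictly increasing beat times, s (>= 2 beats).
#' @return An [rr_series()] with all intervals flagged `"ok"`.
#' @examples
#' rr_from_peaks(c(0, 0.7, 1.45, 2.25))$intervals  # 700 750 800
#' @export
rr_from_peaks <- function(beat_times) {
  if (length(beat_times) < 2) stop("need at least 2 beats")
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  rr_series(beat_times)
}

#' Flag artifactual RR intervals
#'
#' An interval is rejected when it falls outside `bounds` or deviates by
#' more than `max_dev` (fraction) from the median of its 5 nearest
#' in-bounds neighbours. Flags are recomputed from the interval values
#' alone, so the operation is idempotent. Rejected intervals are excluded
#' from all downstream statistics; with `interpolate = TRUE` their values
#' are replaced by a cubic-spline estimate from retained neighbours and
#' flagged `"interpolated"` (beat times are left untouched).
#'
#' No cleaning thresholds are dictated by the underlying protocol; these
#' conservative defaults are recorded in the result's `"cleaning"`
#' attribute.
#'
#' @param rr an [rr_series()].
#' @param bounds physiologically plausible interval range, ms.
#' @param max_dev maximal fractional deviation from the local median.
#' @param max_reject maximal tolerated rejected fraction before the epoch
#'   is declared unusable.
#' @param interpolate replace rejected values by cubic interpolation.
#' @return The flagged [rr_series()].
#' @export
clean_rr <- function(rr, bounds = c(300, 2000), max_dev = 0.25,
                     max_reject = 0.2, interpolate = FALSE) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  inb <- x >= bounds[1] & x <= bounds[2]
  flags <- ifelse(inb, "ok", "rejected")
  ret <- which(inb)
  for (i in ret) {
    nb <- ret[ret != i]
    if (!length(nb)) next
    nb <- nb[order(abs(nb - i))][seq_len(min(5, length(nb)))]
    med <- median(x[nb])
    if (abs(x[i] - med) / med > max_dev) flags[i] <- "rejected"
  }
  frac <- mean(flags == "rejected")
  if (frac > max_reject) {
    stop(sprintf("epoch quality too low: %.0f%% of intervals rejected", 100 * frac))
  }
  out <- rr
  out$flags <- flags
  if (interpolate && any(flags == "rejected")) {
    keep <- which(flags == "ok")
    bad <- which(flags == "rejected")
    if (length(keep) >= 4) {
      tt <- rr$beat_times[-1]
      out$intervals[bad] <- spline(tt[keep], x[keep], xout = tt[bad])$y
      out$flags[bad] <- "interpolated"
    }
  }
  attr(out, "cleaning") <- list(bounds = bounds, max_dev = max_dev,
                                max_reject = max_reject,
                                interpolate = interpolate)
  out
}

#' Split an RR series into annotated epochs
#'
#' Each interval is assigned to the epoch containing its *later* beat,
#' with half-open epochs `[start, end)`; a beat exactly on an epoch
#' boundary therefore belongs to the later epoch. The per-epoch series
#' keep absolute beat times and carry the epoch bounds as attributes.
#'
#' @param rr an [rr_series()].
#' @param annotations an [epoch_table()].
#' @param tol tolerance, s, allowed between the last annotation end and the
#'   last beat.
#' @return A named list of [rr_series()], names `kind` (plus `.domain` for
#'   stimulus epochs), suffixed by position when duplicated.
#' @export
segment_epochs <- function(rr, annotations, tol = 5) {
  stopifnot(inherits(rr, "rr_series"))
  validate_epochs(annotations,
                  record_end = rr$beat_times[length(rr$beat_times)],
                  tol = tol)
  later <- rr$beat_times[-1]
  out <- vector("list", nrow(annotations))
  nm <- character(nrow(annotations))
  for (k in seq_len(nrow(annotations))) {
    a <- annotations[k, ]
    idx <- which(later >= a$start_s & later < a$end_s)
    if (length(idx) < 1) {
      stop("epoch ", k, " (", a$kind, ") contains fewer than 2 beats")
    }
    beats <- rr$beat_times[min(idx):(max(idx) + 1L)]
    out[[k]] <- rr_series(beats, flags = rr$flags[idx],
                          t_start = a$start_s, t_end = a$end_s)
    nm[k] <- if (a$domain == "none") a$kind else paste(a$kind, a$domain, sep = ".")
  }
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  nm[dup] <- paste0(nm[dup], ".", seq_len(nrow(annotations))[dup])
  stats::setNames(out, nm)
}

#' Read / write ECG CSV
#'
#' One sample per line after a `# fs=<Hz>` header comment.
#'
#' @param ecg an [ecg_record()].
#' @param path file path.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", ecg$fs), con)
  writeLines("sample_mv", con)
  writeLines(format(ecg$samples, trim = TRUE, digits = 10), con)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("#\\s*fs=([0-9.]+)", hdr))[[1]]
  if (length(m) < 2) stop("missing '# fs=<Hz>' header in ", path)
  df <- read.csv(path, comment.char = "#")
  ecg_record(df[[1]], fs = as.numeric(m[2]))
}

#' Read / write an epoch annotation CSV
#'
#' Columns `start_s`, `end_s`, `kind`, `domain`.
#'
#' @param annotations an [epoch_table()].
#' @param path file path.
#' @export
write_annotations_csv <- function(annotations, path) {
  validate_epochs(annotations)
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_epochs(df)
  tibble::as_tibble(df)
}
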