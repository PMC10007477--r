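#' Specification for a synthetic RR series
#'
#' Describes a tachogram as a mean interval plus additive sinusoidal
#' modulations and Gaussian noise. Sinusoidal modulation on the interval
#' sequence (rather than an integral-pulse-frequency model) is used because
#' it places spectral power at known frequencies analytically, which is what
#' the downstream spectral tests need.
#'
#' @param mean_rr mean inter-beat interval, ms (> 0).
#' @param modulations list of modulation components, each a list or named
#'   vector with `amplitude` (ms), `frequency` (Hz, in (0, 0.5]) and
#'   optionally `phase` (rad, default 0).
#' @param noise_sd standard deviation of additive Gaussian interval noise,
#'   ms (>= 0).
#' @param duration record length, s (> 0).
#' @param seed integer RNG seed; identical specs reproduce bit-identical
#'   series.
#' @return An object of class `rr_gen_spec`.
#' @examples
#' rr_gen_spec(800, list(c(amplitude = 50, frequency = 0.25)), 0, 360, seed = 1)
#' @export
rr_gen_spec <- function(mean_rr, modulations = list(), noise_sd = 0,
                        duration = 360, seed = 1L) {
  if (!is.numeric(mean_rr) || mean_rr <= 0) stop("mean_rr must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  modulations <- lapply(modulations, function(m) {
    m <- as.list(m)
    if (is.null(m$phase)) m$phase <- 0
    if (is.null(m$amplitude) || is.null(m$frequency)) {
      stop("each modulation needs an amplitude and a frequency")
    }
    if (m$frequency <= 0 || m$frequency > 0.5) {
      stop("modulation frequencies must lie in (0, 0.5] Hz")
    }
    m[c("amplitude", "frequency", "phase")]
  })
  structure(
    list(mean_rr = mean_rr, modulations = modulations, noise_sd = noise_sd,
         duration = duration, seed = as.integer(seed)),
    class = "rr_gen_spec"
  )
}

#' Generate a synthetic RR-interval series
#'
#' Beats are laid down sequentially from time 0: the interval starting at
#' beat time `t` is `mean_rr + sum(A_k sin(2 pi f_k t + phi_k)) + e`,
#' `e ~ N(0, noise_sd)`, and beat times are the cumulative sums of the
#' intervals. A draw producing a non-positive interval is redrawn up to 10
#' times, after which (or immediately, when the deterministic part itself is
#' non-positive) the spec is rejected as degenerate rather than clipped.
#'
#' @param spec an [rr_gen_spec()].
#' @return An [rr_series()] spanning `[0, duration]`, with the generating
#'   spec attached as attribute `"spec"`.
#' @examples
#' rr <- generate_rr_series(rr_gen_spec(800, duration = 60, seed = 7))
#' length(rr$intervals)  # ~75 beats of 800 ms in 60 s
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "rr_gen_spec"))
  set.seed(spec$seed)
  n_guess <- ceiling(spec$duration * 1000 / spec$mean_rr) + 16L
  bt <- numeric(n_guess)
  n <- 1L
  t <- 0
  # intervals below 1 ms are treated as degenerate along with non-positive
  # ones: they are physiologically meaningless and a decaying deterministic
  # part would otherwise let beat times stall short of the duration
  while (t < spec$duration) {
    if (n > 20L * n_guess) {
      stop("degenerate RR spec: beat times stall before reaching the duration")
    }
    det <- spec$mean_rr
    for (m in spec$modulations) {
      det <- det + m$amplitude * sin(2 * pi * m$frequency * t + m$phase)
    }
    iv <- NA_real_
    for (try in seq_len(11L)) {
      cand <- det + if (spec$noise_sd > 0) rnorm(1, 0, spec$noise_sd) else 0
      if (cand >= 1) { iv <- cand; break }
      if (spec$noise_sd == 0) break
    }
    if (is.na(iv)) {
      stop("degenerate RR spec: non-positive interval at t = ",
           signif(t, 4), " s after bounded retries")
    }
    t <- t + iv / 1000
    n <- n + 1L
    if (n > length(bt)) bt <- c(bt, numeric(n_guess))
    bt[n] <- t
  }
  out <- rr_series(bt[seq_len(n)], t_start = 0, t_end = spec$duration)
  attr(out, "spec") <- spec
  out
}

#' Synthesize an ECG record from beat times
#'
#' Places one QRS-like template (a narrow unit-amplitude Gaussian spike,
#' total width ~`template_width`) at each beat time on a zero baseline.
#' Morphology is deliberately minimal: the record exists so that R-peak
#' detection can be validated against known ground-truth beat times, not to
#' mimic P/T-wave shape.
#'
#' @param rr an [rr_series()] (or a numeric vector of beat times, s).
#' @param fs sampling rate, Hz (>= 100).
#' @param template_width approximate spike width, ms; beats spaced closer
#'   than this are an error (overlapping templates).
#' @return An [ecg_record()] with `fs` metadata and the ground-truth beat
#'   times attached as attribute `"beat_times"`.
#' @export
synthesize_ecg <- function(rr, fs = 500, template_width = 80) {
  beats <- if (inherits(rr, "rr_series")) rr$beat_times else as.numeric(rr)
  if (length(beats) == 0) stop("cannot synthesize ECG from an empty RR series")
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (length(beats) > 1 && min(diff(beats)) * 1000 < template_width) {
    stop("beat spacing smaller than the template width: templates overlap")
  }
  dur <- beats[length(beats)] + 0.5
  n <- floor(dur * fs) + 1L
  x <- numeric(n)
  sd_s <- (template_width / 1000) / 6  # +/- 3 sd spans the template width
  half <- ceiling(4 * sd_s * fs)
  for (b in beats) {
    ctr <- round(b * fs) + 1L
    idx <- max(1L, ctr - half):min(n, ctr + half)
    tt <- (idx - 1L) / fs
    x[idx] <- x[idx] + exp(-(tt - b)^2 / (2 * sd_s^2))
  }
  out <- ecg_record(x, fs)
  attr(out, "beat_times") <- beats
  out
}

#' Specification for a synthetic two-group cohort
#'
#' Describes a participant-by-feature table with injected standardized group
#' differences and an aligned evaluation-score vector. Group sizes default
#' to 22 low / 26 high with the cut at 820 of 1200 points, matching the
#' study design this pipeline reproduces; effects are expressed as Cohen's
#' d so statistical power is analytically known.
#'
#' @param n_low,n_high participants below / at-or-above the score cut.
#' @param score_cut evaluation-score cut, points (multiple of 10 in
#'   (0, 1200]).
#' @param effect_map named numeric vector of standardized mean differences
#'   (high minus low, in units of `index_sd`); names must be features of
#'   the cohort.
#' @param index_sd per-feature scale: scalar or vector named like
#'   `features`.
#' @param features feature names; default the 21 indices of
#'   [hrv_index_names()]. Dynamics-derived names
#'   (see [dynamics_feature_names()]) are also accepted.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 22, n_high = 26, score_cut = 820,
                        effect_map = numeric(0), index_sd = 1,
                        features = NULL, seed = 1L) {
  if (n_low + n_high < 2) stop("need at least 2 participants")
  if (score_cut <= 0 || score_cut > 1200 || score_cut %% 10 != 0) {
    stop("score_cut must be a multiple of 10 in (0, 1200]")
  }
  if (is.null(features)) features <- hrv_index_names()
  known <- c(hrv_index_names(), dynamics_feature_names())
  if (!all(features %in% known)) {
    # custom feature panels (e.g. pure-noise calibration runs) are allowed,
    # but effects must still point at features the cohort actually has
    features <- as.character(features)
  }
  if (length(effect_map) && (is.null(names(effect_map)) ||
                             !all(names(effect_map) %in% features))) {
    stop("effect_map names must be cohort features")
  }
  if (length(index_sd) > 1 && is.null(names(index_sd))) {
    stop("a vector index_sd must be named by feature")
  }
  if (any(index_sd <= 0)) stop("index_sd must be > 0")
  structure(
    list(n_low = as.integer(n_low), n_high = as.integer(n_high),
         score_cut = score_cut, effect_map = effect_map,
         index_sd = index_sd, features = features, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with known group effects
#'
#' Low-group feature values are drawn `N(0, sd_f)` and high-group values
#' `N(d_f * sd_f, sd_f)` per feature; evaluation scores are drawn on a
#' 10-point grid, strictly below `score_cut` for the low group and at or
#' above it for the high group, so the score-defined groups coincide with
#' the ground-truth effect groups.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `features` (tibble: `participant_id`, `group`, one
#'   column per feature), `scores` (tibble: `participant_id`, `group`,
#'   `score`) and the `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(effect_map = c(RSA = 0.6), seed = 2))
#' table(coh$scores$group, coh$scores$score >= 820)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_low + spec$n_high
  feats <- spec$features
  sds <- if (length(spec$index_sd) == 1) {
    stats::setNames(rep(spec$index_sd, length(feats)), feats)
  } else {
    miss <- setdiff(feats, names(spec$index_sd))
    if (length(miss)) stop("index_sd missing features: ", paste(miss, collapse = ", "))
    spec$index_sd[feats]
  }
  group <- rep(c("low", "high"), c(spec$n_low, spec$n_high))
  X <- sapply(feats, function(f) {
    mu <- ifelse(group == "high",
                 sds[[f]] * if (f %in% names(spec$effect_map)) spec$effect_map[[f]] else 0,
                 0)
    rnorm(n, mu, sds[[f]])
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, feats))
  low_grid <- seq(0, spec$score_cut - 10, by = 10)
  high_grid <- seq(spec$score_cut, 1200, by = 10)
  score <- c(sample(low_grid, spec$n_low, replace = TRUE),
             sample(high_grid, spec$n_high, replace = TRUE))
  pid <- sprintf("P%02d", seq_len(n))
  list(
    features = tibble::as_tibble(cbind(
      tibble::tibble(participant_id = pid, group = group),
      tibble::as_tibble(X)
    )),
    scores = tibble::tibble(participant_id = pid, group = group, score = score),
    spec = spec
  )
}

#' Generate questionnaire responses with a controlled accuracy
#'
#' Emulates the item-level output of an emotion-recognition questionnaire:
#' exactly `round(n_items * accuracy)` items have arousal, valence and
#' keyword all consistent with the target domain (and `recognized = TRUE`);
#' the remaining items mismatch on the keyword (and are marked
#' unrecognized), so they fail scoring for every evaluation kind.
#'
#' @param n_items number of items.
#' @param accuracy target fraction correct in `[0, 1]`.
#' @param domain target emotional domain: `"HAHV"`, `"HALV"`, `"LALV"` or
#'   `"LAHV"` (high/low arousal x high/low valence quadrants).
#' @param seed integer RNG seed.
#' @param evaluation evaluation kind stamped on the items.
#' @return A tibble with columns `evaluation`, `stimulus_id`,
#'   `domain_target`, `arousal`, `valence`, `keyword`, `recognized`.
#' @examples
#' resp <- generate_responses(100, 0.92, "HAHV", seed = 1)
#' domain_accuracy(resp, "HAHV")
#' @export
generate_responses <- function(n_items, accuracy, domain, seed = 1L,
                               evaluation = "self_awareness") {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must lie in [0, 1]")
  domain <- match.arg(domain, c("HAHV", "HALV", "LALV", "LAHV"))
  set.seed(as.integer(seed))
  k <- round(n_items * accuracy)
  correct <- rep(FALSE, n_items)
  if (k > 0) correct[sample.int(n_items, k)] <- TRUE
  quad <- domain_quadrant(domain)
  hi <- function(m) sample(5:7, m, replace = TRUE)
  lo <- function(m) sample(1:3, m, replace = TRUE)
  draw_half <- function(side, m) if (side == "high") hi(m) else lo(m)
  arousal <- integer(n_items); valence <- integer(n_items)
  arousal[correct] <- draw_half(quad["arousal"], k)
  valence[correct] <- draw_half(quad["valence"], k)
  arousal[!correct] <- sample(1:7, n_items - k, replace = TRUE)
  valence[!correct] <- sample(1:7, n_items - k, replace = TRUE)
  keyword <- character(n_items)
  keyword[correct] <- domain
  others <- setdiff(c("HAHV", "HALV", "LALV", "LAHV", "neutral"), domain)
  keyword[!correct] <- sample(others, n_items - k, replace = TRUE)
  tibble::tibble(
    evaluation = evaluation,
    stimulus_id = seq_len(n_items),
    domain_target = domain,
    arousal = arousal,
    valence = valence,
    keyword = keyword,
    recognized = correct
  )
}

#' Write a sidecar YAML describing a generating spec
#'
#' @param spec an `rr_gen_spec` or `cohort_spec` (any list-like spec).
#' @param path file path.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(c(list(class = class(spec)[1]), unclass(spec)), path)
  invisible(path)
}

#' Write a synthetic cohort to CSV
#'
#' Feature table and score table as two CSVs plus a YAML sidecar of the
#' generating spec.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The three paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pf <- file.path(dir, paste0(prefix, "_features.csv"))
  ps <- file.path(dir, paste0(prefix, "_scores.csv"))
  py <- file.path(dir, paste0(prefix, "_spec.yaml"))
  write.csv(cohort$features, pf, row.names = FALSE)
  write.csv(cohort$scores, ps, row.names = FALSE)
  write_spec_yaml(cohort$spec, py)
  invisible(c(features = pf, scores = ps, spec = py))
}
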