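# closed-form two-sample t-test used by both the scalar interface and the
# sweep; Welch/Satterthwaite by default, pooled-variance optional
.two_sample_t <- function(low, high, pooled = FALSE) {
  nl <- length(low)
  nh <- length(high)
  ml <- mean(low)
  mh <- mean(high)
  vl <- var(low)
  vh <- var(high)
  if (vl + vh == 0) {
    # degenerate: both groups constant
    if (ml == mh) return(list(t = 0, df = nl + nh - 2, p = 1))
    return(list(t = sign(mh - ml) * Inf, df = nl + nh - 2, p = 0))
  }
  if (pooled) {
    sp2 <- ((nl - 1) * vl + (nh - 1) * vh) / (nl + nh - 2)
    se <- sqrt(sp2 * (1 / nl + 1 / nh))
    df <- nl + nh - 2
  } else {
    se2 <- vl / nl + vh / nh
    se <- sqrt(se2)
    df <- se2^2 / ((vl / nl)^2 / (nl - 1) + (vh / nh)^2 / (nh - 1))
  }
  t <- (mh - ml) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sample t-test between low and high scorers
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom (two-sided) by default; group summary statistics are returned
#' alongside. The unequal-variance form is the default because observed
#' group spreads of HRV features routinely differ severalfold; a
#' pooled-variance variant is available.
#'
#' @param low,high numeric feature values per group, each of length >= 2.
#' @param pooled use the pooled-variance (Student) form.
#' @param feature optional feature name carried into the result.
#' @return A one-row tibble: `feature`, `t_stat`, `df`, `p_value`,
#'   `low_mean`, `low_sd`, `high_mean`, `high_sd`, `n_low`, `n_high`.
#'   When both groups are constant and equal, `p_value = 1` by convention.
#' @examples
#' welch_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_ttest <- function(low, high, pooled = FALSE, feature = NA_character_) {
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (length(low) < 2 || length(high) < 2) {
    stop("each group needs at least 2 values")
  }
  ts <- .two_sample_t(low, high, pooled)
  tibble::tibble(
    feature = feature, t_stat = ts$t, df = ts$df, p_value = ts$p,
    low_mean = mean(low), low_sd = sd(low),
    high_mean = mean(high), high_sd = sd(high),
    n_low = length(low), n_high = length(high)
  )
}

#' Sweep evaluation-score cut-points, counting discriminating features
#'
#' Sorts participants by evaluation score and tests, at every admissible
#' cut between distinct score values (tied scores are never split and both
#' groups must reach `min_group`), how many features significantly separate
#' the resulting low/high groups. The best split maximizes the count at
#' the first significance tier; ties are broken by the count at the next
#' tier(s), then toward the most balanced split, then toward the lower cut
#' score. The reported `cut_score` is the lowest score of the high group.
#'
#' No multiple-testing correction is applied by default — the count of raw
#' p < 0.05 features is itself the selection statistic, and because the cut
#' maximizing it is chosen post hoc, null data inflate the best-split count
#' above any fixed split's count; calibrate against synthetic null cohorts
#' (see [generate_cohort()]) before interpreting the maximum.
#' `adjust = "BH"` applies Benjamini-Hochberg within each candidate split.
#'
#' @param scores numeric evaluation scores, aligned with `features` rows.
#' @param features data frame or matrix of numeric feature columns.
#' @param min_group minimal group size on either side of a cut.
#' @param alpha significance tiers, decreasing; counts use strict `<`.
#' @param pooled use the pooled-variance t-test.
#' @param adjust `"none"` or `"BH"`.
#' @return An object of class `sweep_result`: list with `curve` (tibble of
#'   per-cut records: `cut_score`, `n_low`, `n_high`, `sig_05`, `sig_01`,
#'   ... one count column per tier), `best` (the selected record), `tests`
#'   (per-feature [welch_ttest()] rows at the best split) and `markers`
#'   (see [marker_table()]).
#' @export
sweep_splits <- function(scores, features, min_group = 5,
                         alpha = c(0.05, 0.01), pooled = FALSE,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  alpha <- sort(alpha, decreasing = TRUE)
  X <- as.matrix(as.data.frame(features)[
    , vapply(as.data.frame(features), is.numeric, TRUE), drop = FALSE
  ])
  if (nrow(X) != length(scores)) {
    stop("scores and feature rows must align")
  }
  if (length(scores) < 2 * min_group) {
    stop("need at least 2 * min_group participants")
  }
  cuts <- sort(unique(scores))[-1]
  cuts <- cuts[vapply(cuts, function(cc) {
    sum(scores < cc) >= min_group && sum(scores >= cc) >= min_group
  }, TRUE)]
  if (!length(cuts)) {
    stop("no valid split: scores are too tied or groups too small")
  }
  tier_counts <- matrix(0L, length(cuts), length(alpha))
  p_by_cut <- vector("list", length(cuts))
  for (j in seq_along(cuts)) {
    lo <- scores < cuts[j]
    p <- apply(X, 2, function(v) .two_sample_t(v[lo], v[!lo], pooled)$p)
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    p_by_cut[[j]] <- p
    tier_counts[j, ] <- vapply(alpha, function(a) sum(p < a), 0L)
  }
  n_low <- vapply(cuts, function(cc) sum(scores < cc), 0L)
  n_high <- length(scores) - n_low
  # best split: tier counts in order, then balance, then lower cut
  cand <- seq_along(cuts)
  for (t in seq_along(alpha)) {
    cand <- cand[tier_counts[cand, t] == max(tier_counts[cand, t])]
    if (length(cand) == 1) break
  }
  if (length(cand) > 1) {
    bal <- abs(n_low[cand] - n_high[cand])
    cand <- cand[bal == min(bal)]
  }
  best_j <- cand[1]
  lo <- scores < cuts[best_j]
  tests <- do.call(rbind, lapply(colnames(X), function(f) {
    welch_ttest(X[lo, f], X[!lo, f], pooled = pooled, feature = f)
  }))
  if (adjust == "BH") tests$p_value <- stats::p.adjust(tests$p_value, "BH")
  count_cols <- stats::setNames(
    as.data.frame(tier_counts),
    paste0("sig_", sub("^0\\.", "", format(alpha, trim = TRUE)))
  )
  curve <- tibble::as_tibble(cbind(
    data.frame(cut_score = cuts, n_low = n_low, n_high = n_high),
    count_cols
  ))
  structure(
    list(curve = curve,
         best = curve[best_j, ],
         tests = tests,
         markers = marker_table(tests, alpha = alpha),
         alpha = alpha, min_group = min_group,
         pooled = pooled, adjust = adjust),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<sweep_result> %d candidate cuts; best cut at %g points (%d low / %d high), %d features at p < %g\n",
    nrow(x$curve), b$cut_score, b$n_low, b$n_high, b[[4]], x$alpha[1]))
  invisible(x)
}

#' Marker table of discriminating features
#'
#' Features significant at the loosest tier (strict `p < 0.05` by default),
#' starred per tier (`*` for p < 0.05, `**` for p < 0.01), grouped by
#' source — the plain HRV change score or one of its dynamics expansions —
#' with group means, SDs and p-values.
#'
#' @param tests per-feature test rows, as in `sweep_splits()$tests`.
#' @param alpha significance tiers, decreasing.
#' @return A tibble (possibly empty) sorted by source and p-value.
#' @export
marker_table <- function(tests, alpha = c(0.05, 0.01)) {
  alpha <- sort(alpha, decreasing = TRUE)
  sig <- tests[tests$p_value < alpha[1], , drop = FALSE]
  src <- sub("_.*$", "", sig$feature)
  src <- ifelse(src %in% c("variability", "instability", "inertia"), src, "HRV")
  stars <- vapply(sig$p_value, function(p) {
    strrep("*", sum(p < alpha))
  }, character(1))
  out <- tibble::tibble(
    feature = sig$feature, source = src, stars = stars,
    low_mean = sig$low_mean, low_sd = sig$low_sd,
    high_mean = sig$high_mean, high_sd = sig$high_sd,
    t_stat = sig$t_stat, p_value = sig$p_value
  )
  out[order(factor(out$source, c("HRV", "variability", "instability", "inertia")),
            out$p_value), ]
}

#' Normality check of evaluation scores
#'
#' Shapiro-Wilk test plus the quantile-quantile coordinates for a normal
#' Q-Q plot of the score distribution.
#'
#' @param scores numeric scores, n >= 8, not all equal.
#' @return List with `p_value`, `statistic` and `qq` (tibble with
#'   `theoretical` and `sample` quantiles).
#' @export
check_normality <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 8) stop("normality check needs n >= 8")
  if (sd(scores) == 0) stop("normality is undefined for constant scores")
  sw <- shapiro.test(scores)
  qq <- qqnorm(scores, plot.it = FALSE)
  list(p_value = sw$p.value, statistic = unname(sw$statistic),
       qq = tibble::tibble(theoretical = qq$x, sample = qq$y))
}

#' Write sweep outputs as CSV
#'
#' The sweep curve (count of significant features per candidate cut), the
#' marker table, the per-feature group summaries at the best split, and a
#' YAML of the run settings.
#'
#' @param sweep a `sweep_result` from [sweep_splits()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The written paths, invisibly.
#' @export
write_sweep_csv <- function(sweep, dir, prefix = "sweep") {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- file.path(dir, paste0(prefix, "_curve.csv"))
  pm <- file.path(dir, paste0(prefix, "_markers.csv"))
  pg <- file.path(dir, paste0(prefix, "_group_summary.csv"))
  py <- file.path(dir, paste0(prefix, "_run.yaml"))
  write.csv(sweep$curve, pc, row.names = FALSE)
  write.csv(sweep$markers, pm, row.names = FALSE)
  write.csv(sweep$tests, pg, row.names = FALSE)
  yaml::write_yaml(list(
    alpha = sweep$alpha, min_group = sweep$min_group,
    pooled = sweep$pooled, adjust = sweep$adjust,
    best = as.list(sweep$best)
  ), py)
  invisible(c(curve = pc, markers = pm, group_summary = pg, run = py))
}
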