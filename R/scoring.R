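#' Likert quadrant mapping
#'
#' Maps a 7-point Likert rating to a half of the valence/arousal axis:
#' 5-7 is "high", 1-3 "low", and the midpoint 4 belongs to neither half
#' (it cannot match any target quadrant). The midpoint-exclusion rule is a
#' documented convention; pass `midpoint = "high"` or `"low"` to assign it.
#'
#' @param x integer ratings in 1..7.
#' @param midpoint how to treat a rating of 4: `"none"` (excluded),
#'   `"high"` or `"low"`.
#' @return Character vector `"high"`/`"low"`/`NA`.
#' @export
likert_half <- function(x, midpoint = c("none", "high", "low")) {
  midpoint <- match.arg(midpoint)
  if (any(!x %in% 1:7)) stop("Likert ratings must lie in 1..7")
  out <- ifelse(x >= 5, "high", ifelse(x <= 3, "low", NA_character_))
  if (midpoint != "none") out[x == 4] <- midpoint
  out
}

# target quadrant of a domain: (arousal half, valence half)
domain_quadrant <- function(domain) {
  switch(domain,
    HAHV = c(arousal = "high", valence = "high"),
    HALV = c(arousal = "high", valence = "low"),
    LALV = c(arousal = "low", valence = "low"),
    LAHV = c(arousal = "low", valence = "high"),
    stop("unknown emotional domain: ", domain)
  )
}

#' Score one questionnaire item
#'
#' All-or-nothing 10-point scoring: an item earns 10 points only when every
#' required field matches the target emotion, else 0.
#'
#' * `self_awareness` (photo items): the arousal rating's half, the valence
#'   rating's half, and the chosen keyword must all match the target
#'   quadrant/domain.
#' * `others_awareness` (avatar items): the expression must be recognized
#'   (`recognized = TRUE`) *and* the chosen keyword must equal the target
#'   domain.
#' * `discrimination`: all placements must be correct, encoded as
#'   `recognized = TRUE`.
#'
#' @param item a list or one-row data frame with fields `evaluation`,
#'   `domain_target`, `arousal`, `valence`, `keyword`, `recognized`.
#' @param midpoint Likert midpoint rule, see [likert_half()].
#' @return 0 or 10.
#' @export
score_item <- function(item, midpoint = "none") {
  as.integer(score_items(tibble::as_tibble(as.list(item)), midpoint))
}

#' @rdname score_item
#' @param items data frame of items (one per row).
#' @return `score_items` returns an integer vector of per-item points.
#' @export
score_items <- function(items, midpoint = "none") {
  ev <- items$evaluation
  bad <- setdiff(unique(ev),
                 c("self_awareness", "others_awareness", "discrimination"))
  if (length(bad)) stop("unknown evaluation kind: ", paste(bad, collapse = ", "))
  n <- nrow(items)
  pts <- integer(n)
  photo <- ev == "self_awareness"
  if (any(photo)) {
    tq <- t(vapply(items$domain_target[photo], domain_quadrant, character(2)))
    ah <- likert_half(items$arousal[photo], midpoint)
    vh <- likert_half(items$valence[photo], midpoint)
    ok <- !is.na(ah) & !is.na(vh) & ah == tq[, "arousal"] & vh == tq[, "valence"] &
      items$keyword[photo] == items$domain_target[photo]
    pts[photo] <- 10L * ok
  }
  avatar <- ev == "others_awareness"
  if (any(avatar)) {
    ok <- items$recognized[avatar] &
      items$keyword[avatar] == items$domain_target[avatar]
    pts[avatar] <- 10L * ok
  }
  disc <- ev == "discrimination"
  if (any(disc)) {
    pts[disc] <- 10L * items$recognized[disc]
  }
  pts
}

#' Total evaluation score
#'
#' Sums item points per evaluation kind and overall. The full design is 3
#' evaluations x 4 emotional domains x 10 stimuli at 10 points per item,
#' for a 1200-point maximum.
#'
#' @param items data frame of response items; the identity
#'   (`evaluation`, `domain_target`, `stimulus_id`) must be unique.
#' @param midpoint Likert midpoint rule, see [likert_half()].
#' @return An object of class `evaluation_score`: list with `total`,
#'   `by_evaluation` (named vector) and `items` (the input with an
#'   `item_points` column).
#' @export
total_score <- function(items, midpoint = "none") {
  key <- paste(items$evaluation, items$domain_target, items$stimulus_id)
  if (anyDuplicated(key)) stop("duplicate item identity in response set")
  pts <- score_items(items, midpoint)
  items <- tibble::as_tibble(items)
  items$item_points <- pts
  structure(
    list(total = sum(pts),
         by_evaluation = tapply(pts, items$evaluation, sum),
         items = items),
    class = "evaluation_score"
  )
}

#' @export
print.evaluation_score <- function(x, ...) {
  cat(sprintf("<evaluation_score> total %d points over %d items\n",
              x$total, nrow(x$items)))
  for (e in names(x$by_evaluation)) {
    cat(sprintf("  %-18s %d\n", e, x$by_evaluation[[e]]))
  }
  invisible(x)
}

#' Recognition accuracy for one emotional domain
#'
#' Percentage of the domain's items scored correct (item points > 0).
#'
#' @param responses data frame of response items.
#' @param domain target domain.
#' @param midpoint Likert midpoint rule.
#' @return Accuracy in percent.
#' @export
domain_accuracy <- function(responses, domain, midpoint = "none") {
  sub <- responses[responses$domain_target == domain, , drop = FALSE]
  if (!nrow(sub)) stop("no responses for domain ", domain)
  100 * mean(score_items(sub, midpoint) > 0)
}

#' Select photo stimuli by recognition accuracy
#'
#' Keeps stimuli whose accuracy is at or above the threshold (inclusive:
#' "81% or above" keeps an exact 81%).
#'
#' @param accuracies numeric accuracies in percent, optionally named.
#' @param threshold inclusion threshold, percent.
#' @return The kept subset (names or indices), with a warning when nothing
#'   survives.
#' @export
select_photo_stimuli <- function(accuracies, threshold = 81) {
  if (any(accuracies < 0 | accuracies > 100)) {
    stop("accuracies must lie in [0, 100]")
  }
  keep <- which(accuracies >= threshold)
  if (!length(keep)) warning("no stimulus reaches the accuracy threshold")
  if (!is.null(names(accuracies))) names(accuracies)[keep] else keep
}

#' Select the peak-accuracy expression intensity
#'
#' Returns the intensity level at which recognition accuracy peaks; ties go
#' to the lower intensity (the weakest expression that is recognized best).
#'
#' @param accuracies accuracy, percent, per intensity level.
#' @param intensities intensity levels aligned with `accuracies`.
#' @return List with `intensity` and `accuracy`.
#' @examples
#' select_peak_intensity(c(60, 80, 100, 95), 1:4)
#' @export
select_peak_intensity <- function(accuracies, intensities = seq_along(accuracies)) {
  if (!length(accuracies)) stop("need at least one intensity level")
  o <- order(intensities)
  accuracies <- accuracies[o]
  intensities <- intensities[o]
  best <- which.max(accuracies)  # first maximum = lowest intensity on ties
  list(intensity = intensities[best], accuracy = accuracies[best])
}

#' Read / write response items as CSV
#'
#' Columns `participant`, `evaluation`, `stimulus_id`, `domain_target`,
#' `arousal`, `valence`, `keyword`, `recognized`.
#'
#' @param responses response data frame.
#' @param path file path.
#' @export
write_responses_csv <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$recognized <- as.logical(df$recognized)
  tibble::as_tibble(df)
}
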