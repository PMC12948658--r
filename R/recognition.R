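#' Point-light-face trial accuracy
#'
#' Accuracy on one recognition trial is the rating given to the displayed
#' (correct) emotion minus the mean of the two incorrect-emotion ratings.
#' With 0-10 rating scales the score ranges from -10 to 10; 0 means the
#' correct emotion was rated no higher than the average distractor.
#'
#' @param trials Data frame with columns `emotion` (the displayed emotion)
#'   and rating columns `rating_angry`, `rating_happy`, `rating_sad`.
#' @return Numeric vector of per-trial accuracy scores.
#' @export
trial_accuracy <- function(trials) {
  rating_cols <- c(angry = "rating_angry", happy = "rating_happy",
                   sad = "rating_sad")
  stopifnot(all(rating_cols %in% names(trials)), "emotion" %in% names(trials))
  r <- as.matrix(trials[rating_cols])
  if (anyNA(r)) stop("missing rating(s) in recognition trials")
  if (any(r < 0 | r > 10)) stop("ratings must lie in [0, 10]")
  correct_idx <- match(trials$emotion, names(rating_cols))
  if (anyNA(correct_idx))
    stop("unknown displayed emotion: ",
         paste(unique(trials$emotion[is.na(correct_idx)]), collapse = ", "))
  correct <- r[cbind(seq_len(nrow(r)), correct_idx)]
  correct - (rowSums(r) - correct) / 2
}

#' Mean recognition accuracy, overall and by condition
#'
#' Grand mean accuracy over all trials, plus cell means over any requested
#' grouping of emotion, spatial and kinematic levels. With the complete
#' balanced 108-trial design the grand mean equals the mean of the cell
#' means; with missing trials the grand mean is computed over available
#' trials and a warning is raised.
#'
#' @param trials Recognition trial table (see [trial_accuracy()]); may also
#'   carry `spatial`, `kinematic`, `actor`.
#' @param by Character vector of grouping columns (subset of `emotion`,
#'   `spatial`, `kinematic`, `actor`) or `NULL` for the grand mean only.
#' @param expected_n Expected trial count for the completeness audit
#'   (default 108; use `NA` to skip).
#' @return List with `grand_mean` and, when `by` is given, `cells` (a tibble
#'   of group means with counts).
#' @export
mean_accuracy <- function(trials, by = NULL, expected_n = 108) {
  acc <- trial_accuracy(trials)
  if (length(acc) == 0) stop("no trials")
  if (!is.na(expected_n) && length(acc) != expected_n)
    warning("expected ", expected_n, " trials, got ", length(acc),
            "; grand mean computed over available trials")
  out <- list(grand_mean = mean(acc))
  if (!is.null(by)) {
    stopifnot(all(by %in% names(trials)))
    groups <- trials[by]
    cells <- stats::aggregate(acc, by = as.list(groups), FUN = mean)
    counts <- stats::aggregate(acc, by = as.list(groups), FUN = length)
    if (any(counts$x == 0)) stop("empty accuracy cell")
    names(cells)[ncol(cells)] <- "mean_accuracy"
    cells$n_trials <- counts$x
    out$cells <- tibble::as_tibble(cells)
  }
  out
}

#' Per-participant recognition scores
#'
#' @param trials Recognition trial table with a `participant` column.
#' @param expected_n Expected trials per participant (default 108).
#' @return Tibble with columns `participant`, `recognition_accuracy`.
#' @export
score_recognition <- function(trials, expected_n = 108) {
  ids <- unique(trials$participant)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$participant == id, , drop = FALSE]
    tibble::tibble(participant = id,
                   recognition_accuracy =
                     mean_accuracy(sub, expected_n = expected_n)$grand_mean)
  })
  do.call(rbind, rows)
}
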