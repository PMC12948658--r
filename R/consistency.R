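#' Reduce a raw choice table to final valid choices
#'
#' Raw choice data may contain redo chains: trap selections and too-fast
#' responses are flagged (`redo = TRUE`), force a penalty, and the trial is
#' repeated until a valid choice is made. Scoring uses only the final
#' non-redo event of each planned trial; all flagged events are dropped.
#'
#' @param choices Data frame with at least `condition`, `trial`, `chosen` and
#'   a logical `redo` column; multiple rows per (condition, trial) when the
#'   trial was redone.
#' @return The filtered table, one row per planned trial, ordered by
#'   condition and trial.
#' @export
filter_final_choices <- function(choices) {
  stopifnot(is.data.frame(choices),
            all(c("condition", "trial", "redo") %in% names(choices)))
  valid <- choices[!choices$redo, , drop = FALSE]
  key <- paste(valid$condition, valid$trial)
  # keep the last valid event per trial (input is in presentation order)
  keep <- !duplicated(key, fromLast = TRUE)
  out <- valid[keep, , drop = FALSE]
  planned <- unique(paste(choices$condition, choices$trial))
  missing <- setdiff(planned, paste(out$condition, out$trial))
  if (length(missing) > 0)
    stop("incomplete data: no valid final choice for trial(s) ",
         paste(missing, collapse = ", "))
  out <- out[order(out$condition, out$trial), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Times-chosen rank scores for one choice condition
#'
#' Counts, for each target image, the number of trials in which it was chosen.
#' In a complete 11-image round robin each image appears in 10 trials, so a
#' perfectly consistent chooser produces the rank scores 10, 9, ..., 1, 0 and
#' the counts always sum to 55 (one choice per trial). Images never chosen
#' score 0.
#'
#' @param choices Filtered choice table (see [filter_final_choices()]) for a
#'   single condition, with columns `stimulus_a`, `stimulus_b`, `chosen`.
#' @return Named integer vector, one entry per target image.
#' @export
rank_scores <- function(choices) {
  stopifnot(all(c("stimulus_a", "stimulus_b", "chosen") %in% names(choices)))
  if (length(unique(choices$condition)) > 1)
    stop("rank_scores expects a single condition")
  targets <- sort(unique(c(choices$stimulus_a, choices$stimulus_b)))
  n <- length(targets)
  if (nrow(choices) != choose(n, 2))
    stop("incomplete round robin: expected ", choose(n, 2), " trials for ",
         n, " targets, got ", nrow(choices))
  pair_key <- paste(pmin(choices$stimulus_a, choices$stimulus_b),
                    pmax(choices$stimulus_a, choices$stimulus_b))
  if (anyDuplicated(pair_key) > 0)
    stop("incomplete round robin: duplicated target pair(s)")
  if (!all(choices$chosen == choices$stimulus_a |
             choices$chosen == choices$stimulus_b))
    stop("chosen image not among the displayed targets")
  counts <- table(factor(choices$chosen, levels = targets))
  stats::setNames(as.integer(counts), targets)
}

#' Total consistency score from a choice round robin
#'
#' For each trial the rank score (times-chosen count) of the unchosen target
#' is subtracted from that of the chosen target; these item differences are
#' summed over the 55 trials of the condition. A strictly transitive chooser
#' over 11 images attains the maximum of 220; a decision with item difference
#' less than or equal to zero is counted as inconsistent. For a complete
#' n = 11 round robin the total equals `2 * sum(w^2) - 550` where `w` are the
#' rank scores.
#'
#' @param choices Filtered single-condition choice table.
#' @param ranks Optional rank scores from [rank_scores()] on these same
#'   choices (recomputed when omitted).
#' @return A list of class `consistency_result`: `total`, `item_differences`,
#'   `n_inconsistent`, `ranks`, `condition`.
#' @export
consistency_total <- function(choices, ranks = NULL) {
  if (is.null(ranks)) ranks <- rank_scores(choices)
  targets <- sort(unique(c(choices$stimulus_a, choices$stimulus_b)))
  if (!setequal(names(ranks), targets))
    stop("rank/choice mismatch: rank scores do not cover the shown targets")
  unchosen <- ifelse(choices$chosen == choices$stimulus_a,
                     choices$stimulus_b, choices$stimulus_a)
  diffs <- as.numeric(ranks[choices$chosen]) - as.numeric(ranks[unchosen])
  structure(
    list(total = sum(diffs),
         item_differences = diffs,
         n_inconsistent = sum(diffs <= 0),
         ranks = ranks,
         condition = if ("condition" %in% names(choices))
           unique(choices$condition) else NA_character_),
    class = "consistency_result"
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("Choice-consistency result (condition: ", x$condition, ")\n", sep = "")
  cat("  total consistency:    ", x$total, "\n", sep = "")
  cat("  inconsistent choices: ", x$n_inconsistent, " of ",
      length(x$item_differences), "\n", sep = "")
  invisible(x)
}

#' Per-participant, per-condition consistency scores for a cohort
#'
#' Applies [filter_final_choices()], [rank_scores()] and
#' [consistency_total()] to every participant x condition cell of a raw
#' choice table.
#'
#' @param choices Raw choice table with a `participant` column.
#' @return Tibble with columns `participant`, `condition`, `consistency`,
#'   `n_inconsistent`.
#' @export
score_consistency <- function(choices) {
  stopifnot("participant" %in% names(choices))
  cells <- unique(choices[c("participant", "condition")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- choices[choices$participant == cells$participant[i] &
                     choices$condition == cells$condition[i], , drop = FALSE]
    r <- consistency_total(filter_final_choices(sub))
    tibble::tibble(participant = cells$participant[i],
                   condition = cells$condition[i],
                   consistency = r$total,
                   n_inconsistent = r$n_inconsistent)
  })
  do.call(rbind, res)
}
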