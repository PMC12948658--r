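#' Score every task of a simulated (or real) cohort
#'
#' Runs the four scoring pipelines over raw trial data and assembles the
#' per-participant analysis frame used by the inference layer.
#'
#' @param cohort An `emomap_cohort` from [simulate_cohort()], or a list with
#'   the same elements.
#' @param mds_args List of arguments passed to [score_differentiation()]
#'   (e.g. `n_init`, `max_iter`) to trade accuracy for speed.
#' @return List with `scores` (wide per-participant tibble),
#'   `consistency_long`, `between_long`, `within_long` (long frames with
#'   covariates attached, ready for [compare_groups()]).
#' @export
score_cohort <- function(cohort, mds_args = list()) {
  cons <- score_consistency(cohort$choices)
  diff <- do.call(score_differentiation,
                  c(list(ratings = cohort$similarity), mds_args))
  conc <- score_concepts(cohort$definitions, cohort$embeddings)
  reco <- score_recognition(cohort$plf)

  cons_emotional <- cons[cons$condition != "control", , drop = FALSE]
  cons_wide <- stats::aggregate(consistency ~ participant,
                                data = cons_emotional, FUN = mean)
  names(cons_wide)[2] <- "consistency_mean"

  scores <- Reduce(function(a, b) merge(a, b, by = "participant"),
                   list(cohort$participants, cons_wide, diff, conc, reco))
  scores <- tibble::as_tibble(scores[order(scores$participant), ])

  covs <- merge(cohort$participants, conc, by = "participant")
  long_with_cov <- function(long) {
    tibble::as_tibble(merge(long, covs, by = "participant"))
  }
  bl <- diff[c("participant", grep("^dist_between_", names(diff), value = TRUE))]
  bl <- bl[setdiff(names(bl), "dist_between_mean")]
  between_long <- stats::reshape(
    as.data.frame(bl), direction = "long",
    varying = setdiff(names(bl), "participant"),
    v.names = "distance", timevar = "emotion_pair",
    times = sub("^dist_between_", "", setdiff(names(bl), "participant")),
    idvar = "participant")
  wl <- diff[c("participant", grep("^dist_within_", names(diff), value = TRUE))]
  wl <- wl[setdiff(names(wl), "dist_within_mean")]
  within_long <- stats::reshape(
    as.data.frame(wl), direction = "long",
    varying = setdiff(names(wl), "participant"),
    v.names = "distance", timevar = "emotion",
    times = sub("^dist_within_", "", setdiff(names(wl), "participant")),
    idvar = "participant")

  list(scores = scores,
       consistency_long = long_with_cov(cons_emotional),
       between_long = long_with_cov(between_long),
       within_long = long_with_cov(within_long),
       consistency_all = cons)
}

#' The 19 predictors entered into the variable-selection analysis
#' @return Character vector of column names in the wide score table.
#' @export
selection_predictors <- function() {
  c("consistency_mean", "dist_between_mean", "dist_within_mean",
    "vocab_total", "within_valence_distance", "between_valence_distance",
    "aq", "tas", "aq_social", "aq_attention_switch", "aq_attention_detail",
    "aq_communication", "aq_imagination", "tas_ddf", "tas_dif", "tas_eot",
    "nvr", "education", "age")
}

concept_covariates <- function() {
  c("age", "sex", "nvr", "education", "tas", "vocab_total",
    "within_valence_distance", "between_valence_distance",
    "mean_word_count")
}

#' Run the complete analysis pipeline on a cohort
#'
#' Scores every task, then (1) fits the repeated-measures group comparisons
#' for the five outcome families (emotional consistency, between- and
#' within-cluster distances, emotional vocabulary, valence conceptual
#' distances), (2) runs shadow-feature variable selection on mean emotion
#' recognition per group with the 19 candidate predictors, followed by the
#' two reduced follow-up regressions (between- and within-cluster distance
#' entered separately, which are strongly correlated), and (3) fits the two
#' conceptual-distance mediation models plus their reversed-direction
#' counterparts.
#'
#' @param cohort An `emomap_cohort`.
#' @param seed Seed for selection and bootstrap stages.
#' @param boruta_iter Iterations of the selection wrapper.
#' @param B Bootstrap replications for mediation.
#' @param mds_args Passed to [score_cohort()].
#' @return Structured list of class `emomap_report`: `scored`,
#'   `group_comparisons`, `selection`, `followup`, `mediation`.
#' @export
run_full_analysis <- function(cohort, seed = 1L, boruta_iter = 100,
                              B = 2000, mds_args = list()) {
  scored <- score_cohort(cohort, mds_args = mds_args)
  sc <- scored$scores

  covs_full <- c("age", "sex", "nvr", "education", "tas", "vocab_total",
                 "between_valence_distance", "within_valence_distance",
                 "mean_word_count")
  gc <- list(
    consistency = compare_groups(scored$consistency_long, "consistency",
                                 within_factor = "condition",
                                 covariates = covs_full),
    dist_between = compare_groups(scored$between_long, "distance",
                                  within_factor = "emotion_pair",
                                  covariates = covs_full),
    dist_within = compare_groups(scored$within_long, "distance",
                                 within_factor = "emotion",
                                 covariates = covs_full),
    vocab = rank_regression(sc, "vocab_total",
                            c("group", "age", "sex", "nvr", "education",
                              "tas", "mean_word_count")),
    between_valence = compare_groups(sc, "between_valence_distance",
                                     covariates = c("age", "sex", "nvr",
                                                    "education", "tas",
                                                    "mean_word_count")),
    within_valence = compare_groups(sc, "within_valence_distance",
                                    covariates = c("age", "sex", "nvr",
                                                   "education", "tas",
                                                   "mean_word_count")))

  preds <- selection_predictors()
  sel <- list(); follow <- list()
  for (g in unique(sc$group)) {
    sub <- sc[sc$group == g, , drop = FALSE]
    rep_g <- boruta_select(sub[preds], sub$recognition_accuracy,
                           n_iter = boruta_iter, seed = seed)
    sel[[g]] <- rep_g
    kept <- rep_g$decisions$feature[rep_g$decisions$decision != "rejected"]
    if (length(kept) == 0) kept <- preds[1:2]
    drop_between <- setdiff(unique(c(kept, "dist_within_mean")), "dist_between_mean")
    drop_within <- setdiff(unique(c(kept, "dist_between_mean")), "dist_within_mean")
    follow[[g]] <- list(
      excl_between = summary(stats::lm(
        stats::reformulate(drop_between, "recognition_accuracy"), data = sub)),
      excl_within = summary(stats::lm(
        stats::reformulate(drop_within, "recognition_accuracy"), data = sub)))
  }

  med_cov <- c("nvr", "aq", "tas", "education", "vocab_total",
               "mean_word_count")
  non_aut <- sc[sc$group == "non-autistic", , drop = FALSE]
  mediation <- list(
    via_between = mediate_bc_bootstrap(non_aut, "between_valence_distance",
                                       "dist_between_mean",
                                       "recognition_accuracy",
                                       med_cov, B = B, seed = seed),
    via_within = mediate_bc_bootstrap(non_aut, "between_valence_distance",
                                      "dist_within_mean",
                                      "recognition_accuracy",
                                      med_cov, B = B, seed = seed + 1),
    reversed_between = mediate_bc_bootstrap(non_aut, "dist_between_mean",
                                            "between_valence_distance",
                                            "recognition_accuracy",
                                            med_cov, B = B, seed = seed + 2),
    reversed_within = mediate_bc_bootstrap(non_aut, "dist_within_mean",
                                           "between_valence_distance",
                                           "recognition_accuracy",
                                           med_cov, B = B, seed = seed + 3))

  structure(list(scored = scored, group_comparisons = gc, selection = sel,
                 followup = follow, mediation = mediation, seed = seed),
            class = "emomap_report")
}

#' @export
print.emomap_report <- function(x, ...) {
  cat("Emotion-task analysis report\n")
  cat("Group comparisons (group main effect):\n")
  for (nm in names(x$group_comparisons)) {
    g <- x$group_comparisons[[nm]]
    if (inherits(g, "group_comparison")) {
      row <- g[g$term == "group", ]
      if (nrow(row) == 1)
        cat(sprintf("  %-16s F(%g, %g) = %.2f, p = %.3f\n", nm,
                    row$df1, row$df2, row$statistic, row$p_value))
    } else {
      row <- g[grepl("^group", g$term), ]
      if (nrow(row) >= 1)
        cat(sprintf("  %-16s t(%g) = %.2f, p = %.3f\n", nm,
                    row$df[1], row$statistic[1], row$p_value[1]))
    }
  }
  cat("Selected predictors of recognition accuracy:\n")
  for (g in names(x$selection)) {
    d <- x$selection[[g]]$decisions
    cat(sprintf("  %-13s confirmed: %s\n", g,
                paste(d$feature[d$decision == "confirmed"], collapse = ", ")))
  }
  cat("Mediation indirect effects (non-autistic group):\n")
  for (nm in names(x$mediation)) {
    p <- x$mediation[[nm]]$paths
    r <- p[p$quantity == "indirect", ]
    cat(sprintf("  %-17s %7.4f [%7.4f, %7.4f]%s\n", nm, r$estimate,
                r$ci_lower, r$ci_upper, if (isTRUE(r$significant)) " *" else ""))
  }
  invisible(x)
}
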