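#' Split-plot group comparison for repeated-measures scores
#'
#' Approximates the random-intercept mixed model used for this design by two
#' OLS strata. Between-subject terms (group and participant-level
#' covariates) are tested on participant mean outcomes with marginal
#' (drop-one) F tests. Within-subject terms (the condition factor and its
#' interaction with group) are tested in a model with fixed subject effects,
#' which absorb the subject-level variation exactly as the random intercept
#' does in the balanced case. Kenward-Roger degree-of-freedom corrections
#' are not applied.
#'
#' @param frame Long data frame, one row per participant x condition.
#' @param outcome Name of the outcome column.
#' @param within_factor Name of the within-subject factor column (e.g.
#'   emotion), or `NULL` for purely between-subject outcomes.
#' @param covariates Character vector of participant-level covariate columns.
#' @param group Name of the group column (default `"group"`).
#' @param subject Name of the subject-identifier column.
#' @return A tibble of class `group_comparison` with columns `term`,
#'   `stratum`, `df1`, `df2`, `statistic`, `p_value`, plus attribute
#'   `degenerate` when the outcome has zero variance.
#' @export
compare_groups <- function(frame, outcome, within_factor = NULL,
                           covariates = character(), group = "group",
                           subject = "participant") {
  stopifnot(all(c(outcome, group, subject, within_factor, covariates)
                %in% names(frame)))
  y <- frame[[outcome]]
  if (anyNA(frame[c(outcome, group, subject, within_factor, covariates)]))
    stop("missing values in analysis frame; run a completeness pass first")

  degenerate <- stats::var(y) == 0
  between_terms <- c(group, covariates)

  # between stratum: participant means
  agg <- stats::aggregate(frame[[outcome]],
                          by = lapply(c(subject, between_terms), function(v)
                            frame[[v]]),
                          FUN = mean)
  names(agg) <- c(subject, between_terms, ".y")
  fb <- stats::as.formula(paste(".y ~", paste(between_terms, collapse = " + ")))
  fit_b <- stats::lm(fb, data = agg)
  if (any(is.na(stats::coef(fit_b))))
    stop("rank-deficient between-subject model; aliased term(s): ",
         paste(names(stats::coef(fit_b))[is.na(stats::coef(fit_b))],
               collapse = ", "))
  rows <- if (degenerate) {
    tibble::tibble(term = between_terms, stratum = "between",
                   df1 = NA_real_, df2 = NA_real_, statistic = 0,
                   p_value = NA_real_)
  } else {
    d1 <- stats::drop1(fit_b, test = "F")
    d1 <- d1[-1, , drop = FALSE]  # drop the <none> row
    tibble::tibble(term = rownames(d1), stratum = "between",
                   df1 = d1$Df, df2 = fit_b$df.residual,
                   statistic = d1$`F value`, p_value = d1$`Pr(>F)`)
  }

  if (!is.null(within_factor)) {
    dat <- data.frame(.y = y,
                      .subj = factor(frame[[subject]]),
                      .w = factor(frame[[within_factor]]),
                      .g = factor(frame[[group]]))
    fit_w <- stats::lm(.y ~ .subj + .w + .w:.g, data = dat)
    if (degenerate) {
      rows <- rbind(rows, tibble::tibble(
        term = c(within_factor, paste0(within_factor, ":", group)),
        stratum = "within", df1 = NA_real_, df2 = NA_real_,
        statistic = 0, p_value = NA_real_))
    } else {
      aw <- stats::anova(fit_w)
      keep <- rownames(aw) %in% c(".w", ".w:.g")
      rows <- rbind(rows, tibble::tibble(
        term = c(within_factor, paste0(within_factor, ":", group)),
        stratum = "within",
        df1 = aw$Df[keep], df2 = aw$Df[rownames(aw) == "Residuals"],
        statistic = aw$`F value`[keep], p_value = aw$`Pr(>F)`[keep]))
    }
  }
  structure(rows, class = c("group_comparison", class(rows)),
            degenerate = degenerate)
}

#' Rank-transformed (non-parametric) linear regression
#'
#' Fallback used when parametric assumptions are violated: the outcome and
#' numeric predictors are rank-transformed before ordinary least squares.
#'
#' @param frame Data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns.
#' @return `summary.lm`-style coefficient tibble with `term`, `estimate`,
#'   `statistic` (t), `df`, `p_value`.
#' @export
rank_regression <- function(frame, outcome, predictors) {
  dat <- frame[c(outcome, predictors)]
  stopifnot(!anyNA(dat))
  for (v in names(dat))
    if (is.numeric(dat[[v]])) dat[[v]] <- rank(dat[[v]])
  f <- stats::as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(f, data = dat)
  cf <- summary(fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 statistic = cf[, 3], df = fit$df.residual,
                 p_value = cf[, 4])
}

scaled_importance <- function(imp) {
  z <- imp$importance
  se <- imp$importance_sd
  ifelse(se > 0, z / se, ifelse(z == 0, 0, sign(z) * Inf))
}

default_importance <- function(x, y, n_trees, mtry) {
  p <- ncol(x)
  shadows <- apply(x, 2, sample)
  # keep at least 5 shadow columns so the shadow-max reference stays a
  # maximum over several draws even when few features remain live
  if (p < 5)
    shadows <- cbind(shadows,
                     apply(x[, sample.int(p, 5 - p, replace = TRUE),
                             drop = FALSE], 2, sample))
  big <- cbind(x, shadows)
  imp <- rf_importance_cpp(big, y, n_trees = n_trees,
                           mtry = if (is.null(mtry)) max(1L, floor(ncol(big) / 3)) else mtry)
  z <- scaled_importance(imp)
  list(importance = stats::setNames(z[seq_len(p)], colnames(x)),
       shadow_max = max(z[(p + 1):ncol(big)]))
}

#' Shadow-feature all-relevant variable selection
#'
#' Re-implementation of the Boruta wrapper: at each iteration every live
#' feature is paired with an independently permuted "shadow" copy, a
#' random-forest regressor is fitted to the augmented design, and a feature
#' scores a hit when its (scaled) permutation importance exceeds the maximum
#' shadow importance of that iteration. Accumulated hits are tested against
#' a Binomial(iterations, 0.5) reference with a two-sided test at level
#' `alpha` (Bonferroni-corrected over the undecided features at each
#' decision pass): significantly many hits confirms a feature, significantly
#' few rejects it (and removes it from the live pool); features undecided
#' after `n_iter` iterations are tentative.
#'
#' @param x Data frame or matrix of candidate predictors (>= 2 columns).
#' @param y Numeric outcome.
#' @param n_iter Number of iterations (>= 20).
#' @param alpha Two-sided decision level (default 0.01).
#' @param seed Seed for permutations and forests.
#' @param n_trees Trees per forest (default 16). Deliberately small: the
#'   shadow-max comparison is calibrated by the per-iteration sampling noise
#'   of the importance estimates, and stability comes from accumulating hits
#'   over iterations; large forests make chance-correlated noise features
#'   beat their freshly permuted shadows too reliably.
#' @param mtry Features sampled per split (default p/3 of the augmented set).
#' @param importance_fn Override of the importance engine (used for exact
#'   fixture tests): `function(x_live, y)` returning
#'   `list(importance = named numeric, shadow_max = numeric)`.
#' @return Object of class `selection_report`: `decisions` tibble (`feature`,
#'   `decision`, `hits`, `n_tested`, `mean_importance`),
#'   `importance_history` (n_iter x p matrix, NA once a feature leaves the
#'   pool), `shadow_max_history`, `alpha`, `n_iter`, `seed`.
#' @export
boruta_select <- function(x, y, n_iter = 100, alpha = 0.01, seed = 1L,
                          n_trees = 16, mtry = NULL, importance_fn = NULL) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 candidate features")
  if (n_iter < 20) stop("n_iter must be at least 20")
  if (stats::var(y) == 0) stop("constant outcome")
  if (anyNA(x) || anyNA(y)) stop("missing values in predictors or outcome")
  feats <- colnames(x)
  p <- length(feats)
  xm <- as.matrix(x)

  decision <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(rep(0L, p), feats)
  tested <- stats::setNames(rep(0L, p), feats)
  hist <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, feats))
  shadow_hist <- rep(NA_real_, n_iter)

  with_local_seed(seed, {
    for (it in seq_len(n_iter)) {
      undecided <- names(decision)[decision == "tentative"]
      live <- names(decision)[decision != "rejected"]
      if (length(live) < 1) break
      res <- if (is.null(importance_fn))
        default_importance(xm[, live, drop = FALSE], y, n_trees, mtry)
      else importance_fn(xm[, live, drop = FALSE], y)
      hist[it, live] <- res$importance[live]
      shadow_hist[it] <- res$shadow_max
      hit_now <- res$importance[live] > res$shadow_max
      hits[live] <- hits[live] + as.integer(hit_now)
      tested[live] <- tested[live] + 1L

      if (it >= 5 && length(undecided) > 0) {
        n_tests <- length(undecided)
        for (f in undecided) {
          p_hi <- stats::pbinom(hits[f] - 1, tested[f], 0.5, lower.tail = FALSE)
          p_lo <- stats::pbinom(hits[f], tested[f], 0.5)
          p_two <- min(1, 2 * min(p_hi, p_lo))
          if (p_two * n_tests < alpha)
            decision[f] <- if (hits[f] > tested[f] / 2) "confirmed" else "rejected"
        }
      }
    }
  })

  structure(
    list(decisions = tibble::tibble(
           feature = feats,
           decision = unname(decision),
           hits = unname(hits),
           n_tested = unname(tested),
           mean_importance = colMeans(hist, na.rm = TRUE)),
         importance_history = hist,
         shadow_max_history = shadow_hist,
         alpha = alpha, n_iter = n_iter, seed = seed),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  d <- x$decisions
  cat("Shadow-feature selection (", x$n_iter, " iterations, alpha = ",
      x$alpha, ")\n", sep = "")
  for (lev in c("confirmed", "tentative", "rejected")) {
    f <- d$feature[d$decision == lev]
    if (length(f) > 0)
      cat(sprintf("  %-9s: %s\n", lev, paste(f, collapse = ", ")))
  }
  invisible(x)
}

bc_ci <- function(boot, point, level = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) < 10 || stats::sd(boot) == 0)
    return(c(lower = point, upper = point))
  prop <- mean(boot < point)
  prop <- min(max(prop, 1 / (length(boot) + 1)), length(boot) / (length(boot) + 1))
  z0 <- stats::qnorm(prop)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  q <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  stats::setNames(stats::quantile(boot, q, names = FALSE, type = 6),
                  c("lower", "upper"))
}

mediation_paths <- function(mm_med, mm_out, med, out, rows) {
  # mediator ~ predictor + covariates; outcome ~ mediator + predictor + covs
  # lm.fit (not .lm.fit): keeps coefficients in column order under pivoting
  fa <- stats::lm.fit(mm_med[rows, , drop = FALSE], med[rows])
  fb <- stats::lm.fit(mm_out[rows, , drop = FALSE], out[rows])
  a <- unname(fa$coefficients[2])       # predictor column
  b <- unname(fb$coefficients[2])       # mediator column
  cprime <- unname(fb$coefficients[3])  # predictor column
  c(a = a, b = b, cprime = cprime, indirect = a * b,
    total = cprime + a * b)
}

#' Mediation with bias-corrected bootstrap confidence intervals
#'
#' Regression-based product-of-coefficients mediation: path `a` from the
#' regression of the mediator on the predictor (plus covariates), path `b`
#' and the direct effect `c'` from the regression of the outcome on mediator
#' and predictor (plus covariates); the indirect effect is `a * b`.
#' Participants are resampled with replacement `B` times and each quantity
#' receives a bias-corrected percentile interval: with
#' `z0 = qnorm(P(boot < point))`, the interval endpoints are the bootstrap
#' quantiles at `pnorm(2 * z0 -/+ 1.96)`. Covariates enter both regressions.
#'
#' @param frame Data frame of complete cases.
#' @param predictor,mediator,outcome Column names.
#' @param covariates Character vector of covariate columns.
#' @param B Bootstrap replications (>= 1; >= 1000 recommended, 2000 typical).
#' @param seed Seed for resampling.
#' @param level Confidence level (default 0.95).
#' @return Object of class `mediation_report`: `paths` tibble (`quantity`,
#'   `estimate`, `boot_se`, `z`, `ci_lower`, `ci_upper`, `significant`),
#'   `B`, `seed`, `level`.
#' @export
mediate_bc_bootstrap <- function(frame, predictor, mediator, outcome,
                                 covariates = character(), B = 2000,
                                 seed = 1L, level = 0.95) {
  if (B < 1) stop("B must be a positive number of bootstrap replications")
  vars <- c(predictor, mediator, outcome, covariates)
  stopifnot(all(vars %in% names(frame)))
  dat <- frame[stats::complete.cases(frame[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  if (n < 10) stop("too few complete cases for mediation")
  if (stats::var(dat[[mediator]]) == 0) stop("zero-variance mediator")

  cov_mm <- if (length(covariates) > 0)
    stats::model.matrix(~ ., data = dat[covariates])[, -1, drop = FALSE]
  else NULL
  mm_med <- cbind(1, dat[[predictor]], cov_mm)
  mm_out <- cbind(1, dat[[mediator]], dat[[predictor]], cov_mm)
  if (qr(mm_out)$rank < ncol(mm_out))
    stop("collinear design (predictor/mediator/covariates)")

  med <- dat[[mediator]]; out <- dat[[outcome]]
  point <- mediation_paths(mm_med, mm_out, med, out, seq_len(n))

  boot <- with_local_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      mediation_paths(mm_med, mm_out, med, out, rows)
    }, numeric(5)))
  })

  qty <- names(point)
  paths <- do.call(rbind, lapply(seq_along(qty), function(j) {
    ci <- bc_ci(boot[, j], point[j], level)
    se <- stats::sd(boot[, j])
    tibble::tibble(quantity = qty[j], estimate = unname(point[j]),
                   boot_se = se,
                   z = if (se > 0) unname(point[j]) / se else NA_real_,
                   ci_lower = unname(ci["lower"]),
                   ci_upper = unname(ci["upper"]),
                   significant = ci["lower"] > 0 | ci["upper"] < 0)
  }))
  structure(list(paths = paths, B = B, seed = seed, level = level, n = n),
            class = "mediation_report")
}

#' @export
print.mediation_report <- function(x, ...) {
  cat("Mediation (bias-corrected bootstrap, B = ", x$B, ", n = ", x$n,
      ")\n", sep = "")
  p <- x$paths
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-8s %8.4f  [%7.4f, %7.4f]%s\n", p$quantity[i],
                p$estimate[i], p$ci_lower[i], p$ci_upper[i],
                if (isTRUE(p$significant[i])) " *" else ""))
  invisible(x)
}
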