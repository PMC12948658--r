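test_that("group comparison reports both strata and flags degenerate input", {
  set.seed(11)
  f <- make_null_frame(20, 20, group_shift = 2)
  res <- compare_groups(f, "y", "condition", covariates = c("age", "tas"))
  expect_setequal(res$term, c("group", "age", "tas", "condition",
                              "condition:group"))
  expect_true(res$p_value[res$term == "group"] < 0.05)

  f0 <- f; f0$y <- 1
  res0 <- compare_groups(f0, "y", "condition", covariates = "age")
  expect_true(attr(res0, "degenerate"))
  expect_true(all(res0$statistic == 0))

  f$age2 <- f$age
  expect_error(compare_groups(f, "y", "condition",
                              covariates = c("age", "age2")),
               "rank-deficient")
})

test_that("a strong within-subject-sd group shift is detected with high power", {
  set.seed(12)
  hits <- vapply(1:50, function(i) {
    f <- make_null_frame(55, 55, group_shift = 1, sd_subject = 1, sd_resid = 1)
    res <- compare_groups(f, "y", "condition", covariates = c("age", "tas"))
    res$p_value[res$term == "group"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("shadow-feature decisions match a hand-computed binomial table", {
  # injected importances: f_always beats the shadow max every iteration,
  # f_never never does, f_half alternates. With alpha = 0.01 and Bonferroni
  # over the undecided features, 2 * 0.5^t * m < 0.01 first holds at t = 10
  # (m = 3), so f_always is confirmed and f_never rejected at iteration 10;
  # f_half stays tentative throughout.
  inj <- local({
    it <- 0
    function(x, y) {
      it <<- it + 1
      imp <- c(f_always = 2, f_never = -2,
               f_half = if (it %% 2 == 0) 2 else -2)
      list(importance = imp[colnames(x)], shadow_max = 0)
    }
  })
  x <- data.frame(f_always = rnorm(30), f_never = rnorm(30),
                  f_half = rnorm(30))
  rep <- boruta_select(x, rnorm(30), n_iter = 25, seed = 1,
                       importance_fn = inj)
  d <- setNames(rep$decisions$decision, rep$decisions$feature)
  expect_equal(unname(d["f_always"]), "confirmed")
  expect_equal(unname(d["f_never"]), "rejected")
  expect_equal(unname(d["f_half"]), "tentative")
  expect_equal(rep$decisions$n_tested[rep$decisions$feature == "f_never"], 10L)
  # rejected features leave the live pool: histories go NA afterwards
  expect_true(all(is.na(rep$importance_history[11:25, "f_never"])))

  expect_error(boruta_select(x, rnorm(30), n_iter = 10), "at least 20")
  expect_error(boruta_select(x, rep(1, 30)), "constant outcome")
  expect_error(boruta_select(x[1], rnorm(30)), "at least 2")
})

test_that("selection confirms a planted predictor and rejects pure noise", {
  set.seed(13)
  n <- 120
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("f", 1:6)
  y <- 1.5 * x$f1 + rnorm(n, sd = 0.5)
  rep <- boruta_select(x, y, n_iter = 60, seed = 14)
  d <- setNames(rep$decisions$decision, rep$decisions$feature)
  expect_equal(unname(d["f1"]), "confirmed")
  expect_gte(sum(d[paste0("f", 2:6)] == "rejected"), 4)
})

test_that("mediation obeys the least-squares decomposition and is seeded", {
  set.seed(15)
  n <- 200
  p <- rnorm(n); m <- 0.6 * p + rnorm(n); o <- 0.5 * m + 0.2 * p + rnorm(n)
  d <- data.frame(p = p, m = m, o = o)
  rep <- mediate_bc_bootstrap(d, "p", "m", "o", B = 500, seed = 16)
  est <- setNames(rep$paths$estimate, rep$paths$quantity)
  # in-sample identity: total effect c equals c' + a*b exactly
  c_direct <- unname(coef(lm(o ~ p))["p"])
  expect_equal(unname(est["total"]), c_direct, tolerance = 1e-10)
  expect_equal(unname(est["indirect"]), unname(est["a"] * est["b"]))

  rep2 <- mediate_bc_bootstrap(d, "p", "m", "o", B = 500, seed = 16)
  expect_identical(rep$paths, rep2$paths)
  rep3 <- mediate_bc_bootstrap(d, "p", "m", "o", B = 500, seed = 17)
  expect_false(identical(rep$paths$ci_lower, rep3$paths$ci_lower))

  expect_error(mediate_bc_bootstrap(d, "p", "m", "o", B = 0), "positive")
  d$m0 <- 1
  expect_error(mediate_bc_bootstrap(d, "p", "m0", "o"), "zero-variance")
  d$p2 <- d$p
  expect_error(mediate_bc_bootstrap(d, "p", "m", "o", covariates = "p2"),
               "collinear")
})

test_that("covariates enter both mediation regressions", {
  set.seed(18)
  n <- 300
  z <- rnorm(n)                      # confounder of predictor and mediator
  p <- z + rnorm(n)
  m <- z + rnorm(n)                  # no true p -> m path
  o <- 0.5 * m + rnorm(n)
  d <- data.frame(p = p, m = m, o = o, z = z)
  unadj <- mediate_bc_bootstrap(d, "p", "m", "o", B = 400, seed = 19)
  adj <- mediate_bc_bootstrap(d, "p", "m", "o", covariates = "z",
                              B = 400, seed = 19)
  a_unadj <- unadj$paths$estimate[unadj$paths$quantity == "a"]
  a_adj <- adj$paths$estimate[adj$paths$quantity == "a"]
  expect_gt(a_unadj, 0.3)
  expect_lt(abs(a_adj), 0.2)
})

test_that("the full pipeline runs end to end and is reproducible", {
  coh <- simulate_cohort(cohort_config(n_autistic = 12, n_non_autistic = 12,
                                       seed = 101))
  rep1 <- run_full_analysis(coh, seed = 5, boruta_iter = 20, B = 200,
                            mds_args = list(n_init = 2, max_iter = 100))
  rep2 <- run_full_analysis(coh, seed = 5, boruta_iter = 20, B = 200,
                            mds_args = list(n_init = 2, max_iter = 100))
  expect_identical(rep1$mediation$via_between$paths,
                   rep2$mediation$via_between$paths)
  expect_identical(rep1$selection[["autistic"]]$decisions,
                   rep2$selection[["autistic"]]$decisions)
  expect_named(rep1$group_comparisons,
               c("consistency", "dist_between", "dist_within", "vocab",
                 "between_valence", "within_valence"))
  expect_equal(nrow(rep1$scored$scores), 24)
  gm <- rep1$group_comparisons$consistency
  expect_true(all(c("group", "condition", "condition:group") %in% gm$term))
  expect_named(rep1$mediation, c("via_between", "via_within",
                                 "reversed_between", "reversed_within"))
})
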