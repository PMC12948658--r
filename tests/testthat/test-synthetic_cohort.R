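test_that("similarity generator maps latent geometry onto the rating scale", {
  plan <- build_similarity_pairs(image_set())
  coincident <- participant_profile(id = "p0", cluster_separation = 0,
                                    within_spread = 0, sim_noise_sd = 0,
                                    seed = 1)
  r0 <- simulate_similarity_ratings(coincident, plan, seed = 2)
  expect_true(all(r0$rating == 10))

  spread <- participant_profile(id = "p1", cluster_separation = 5,
                                within_spread = 0.8, sim_noise_sd = 0,
                                seed = 3)
  r1 <- simulate_similarity_ratings(spread, plan, seed = 4)
  expect_true(all(r1$rating >= 0 & r1$rating <= 10))
  # gain maps the farthest pair exactly to rating 0
  expect_equal(min(r1$rating), 0)
  # clustered geometry: within-emotion pairs more similar than between
  expect_gt(mean(r1$rating[r1$pair_type == "within"]),
            mean(r1$rating[r1$pair_type == "between"]))
})

test_that("choice generator matches an independent Thurstone oracle", {
  ints <- setNames(seq(3, -3, length.out = 11), targets11())
  plan <- build_choice_trials(targets11(), "trap1", seed = 5)
  noise_sd <- 3
  prof <- participant_profile(id = "p1", intensities = list(angry = ints),
                              choice_noise_sd = noise_sd, seed = 1)
  reps <- 400
  set.seed(21)
  pkg_mean <- mean(vapply(seq_len(reps), function(i) {
    ch <- simulate_choices(prof, plan)
    consistency_total(filter_final_choices(ch))$total
  }, numeric(1)))
  oracle <- vapply(seq_len(reps), function(i)
    oracle_simulate_total(unname(ints), noise_sd), numeric(1))
  expect_lt(pkg_mean, 220)
  expect_gt(pkg_mean, 0)
  expect_lt(abs(pkg_mean - mean(oracle)), 4 * sd(oracle) / sqrt(reps) + 2)
})

test_that("trap lapses are emitted as redo events followed by re-choices", {
  ints <- setNames(11:1, targets11())
  prof <- participant_profile(id = "p1", intensities = list(angry = ints),
                              choice_noise_sd = 0, p_lapse = 0.5, seed = 1)
  plan <- build_choice_trials(targets11(), "trapX", seed = 2)
  ev <- simulate_choices(prof, plan, seed = 3)
  expect_gt(sum(ev$redo), 0)
  expect_true(all(ev$chosen[ev$redo] == ev$trap[ev$redo]))
  filtered <- filter_final_choices(ev)
  expect_equal(nrow(filtered), 55)
  expect_equal(consistency_total(filtered)$total, 220)
})

test_that("cohort simulation is deterministic with stated-world row counts", {
  cfg <- cohort_config(n_autistic = 4, n_non_autistic = 5, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$similarity, b$similarity)
  expect_identical(a$choices, b$choices)
  expect_identical(a$plf, b$plf)
  expect_identical(a$truth, b$truth)

  n <- 9
  expect_equal(nrow(a$participants), n)
  expect_equal(nrow(a$similarity), n * 105)
  expect_equal(nrow(a$plf), n * 108)
  expect_equal(nrow(a$definitions), n * 20)
  # 4 conditions x 55 trials, no lapses by default
  expect_equal(nrow(a$choices), n * 4 * 55)
  expect_true(all(a$similarity$rating >= 0 & a$similarity$rating <= 10))
  expect_true(all(a$truth$sim_noise_sd >= 0))
  expect_true(all(a$participants$aq >= 0 & a$participants$aq <= 50))
  expect_true(all(a$participants$tas >= 20 & a$participants$tas <= 100))
})

test_that("default group effects are null on the latent parameters", {
  pvals <- vapply(1:100, function(i) {
    coh <- simulate_cohort(cohort_config(n_autistic = 8, n_non_autistic = 8,
                                         seed = 9000 + i))
    tr <- coh$truth
    t.test(cluster_separation ~ group, data = tr)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("configured group effects shift the autistic latent parameters", {
  cfg <- cohort_config(n_autistic = 40, n_non_autistic = 40,
                       effects = list(cluster_separation = 3), seed = 17)
  tr <- simulate_cohort(cfg)$truth
  expect_gt(mean(tr$cluster_separation[tr$group == "autistic"]),
            mean(tr$cluster_separation[tr$group == "non-autistic"]) + 1.5)
})
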