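test_that("similarity ratings invert onto the dissimilarity scale", {
  plan <- build_similarity_pairs(image_set())
  plan$rating <- 5
  plan$rating[1] <- 10; plan$rating[2] <- 0; plan$rating[3] <- 3.25
  d <- similarity_to_dissimilarity(plan)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 15))
  expect_equal(d[plan$stimulus_a[1], plan$stimulus_b[1]], 0)
  expect_equal(d[plan$stimulus_a[2], plan$stimulus_b[2]], 10)
  expect_equal(d[plan$stimulus_a[3], plan$stimulus_b[3]], 6.75)

  expect_error(similarity_to_dissimilarity(plan[-1, ]), "missing pair")
  expect_error(similarity_to_dissimilarity(rbind(plan, plan[1, ])),
               "duplicate pair")
})

test_that("SMACOF recovers exactly embeddable configurations", {
  set.seed(42)
  x <- matrix(rnorm(30), 15, 2)
  delta <- as.matrix(dist(x))
  dimnames(delta) <- list(paste0("i", 1:15), paste0("i", 1:15))
  emb <- mds_embed(delta, k = 2, seed = 1)
  expect_lt(emb$stress, 1e-8)
  rec <- as.matrix(dist(emb$points))
  expect_lt(max(abs(rec - delta)), 1e-6)
  # stress history non-increasing
  expect_true(all(diff(emb$stress_history) <= 1e-12))

  # 3-4-5 triangle embeds exactly in the plane
  tri <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  emb3 <- mds_embed(tri, k = 2, seed = 2)
  expect_equal(sort(as.vector(dist(emb3$points))), c(3, 4, 5),
               tolerance = 1e-6)

  # degenerate all-zero input collapses to a point
  z <- mds_embed(matrix(0, 4, 4), k = 2)
  expect_equal(z$stress, 0)
  expect_true(all(z$points == 0))

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  neg <- matrix(0, 3, 3); neg[1, 2] <- neg[2, 1] <- -1
  expect_error(mds_embed(neg), "nonnegative")
})

test_that("cluster distances match a brute-force pairwise oracle", {
  labels <- rep(c("angry", "happy", "sad"), each = 5)
  set.seed(8)
  pts <- matrix(rnorm(30, sd = 3), 15, 2)
  cd <- cluster_distances(pts, labels)
  oracle <- oracle_cluster_means(pts, labels)
  expect_equal(cd$within, oracle$within)
  expect_equal(cd$between, oracle$between)
  expect_equal(cd$within_mean, mean(oracle$within))
  expect_equal(cd$between_mean, mean(oracle$between))
  expect_equal(cd$n_pairs_within, 10L)
  expect_equal(cd$n_pairs_between, 25L)

  expect_equal(cluster_distances(matrix(0, 15, 2), labels)$between_mean, 0)

  # pure centroid geometry: within 0, between = centroid separations
  cent <- rbind(c(0, 0), c(1, 0), c(0, 1))
  pure <- cent[rep(1:3, each = 5), ]
  cdp <- cluster_distances(pure, labels)
  expect_equal(unname(cdp$within), rep(0, 3))
  expect_equal(sort(unname(cdp$between)), c(1, 1, sqrt(2)))

  expect_error(cluster_distances(pts, rep(c("a", "b"), c(7, 8))), "imbalance")
})

test_that("cluster distances are invariant to rigid motions of the embedding", {
  labels <- rep(c("a", "b", "c"), each = 5)
  set.seed(3)
  pts <- matrix(rnorm(30), 15, 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  moved <- sweep(pts %*% rot, 2, c(5, -2), "+")
  a <- cluster_distances(pts, labels)
  b <- cluster_distances(moved, labels)
  expect_equal(a$within, b$within)
  expect_equal(a$between, b$between)
})

test_that("estimated between-cluster distance tracks the latent separation", {
  plan <- build_similarity_pairs(image_set())
  seps <- seq(0.5, 8, length.out = 50)
  est <- vapply(seq_along(seps), function(i) {
    prof <- participant_profile(id = sprintf("p%02d", i),
                                cluster_separation = seps[i],
                                within_spread = 0.5, sim_noise_sd = 0.75,
                                seed = 400 + i)
    ratings <- simulate_similarity_ratings(prof, plan, seed = 500 + i)
    delta <- similarity_to_dissimilarity(ratings)
    emb <- mds_embed(delta, k = 2, seed = 1, n_init = 4)
    labels <- image_set()$emotion[match(rownames(emb$points),
                                        image_set()$image)]
    cluster_distances(emb, labels)$between_mean
  }, numeric(1))
  expect_gt(cor(seps, est, method = "spearman"), 0.9)
})
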