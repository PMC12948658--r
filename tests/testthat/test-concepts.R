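test_that("vocabulary totals attain the printed bounds and sum correctly", {
  expect_equal(vocab_total(rep(2L, 20)), 40L)
  expect_equal(vocab_total(rep(0L, 20)), 0L)
  expect_equal(vocab_total(c(rep(2L, 10), rep(1L, 10))), 30L)
  expect_error(vocab_total(rep(2L, 19)), "expected 20")
  expect_error(vocab_total(c(rep(1L, 19), 3L)), "0, 1 or 2")
})

test_that("word counting and averaging follow the whitespace contract", {
  expect_equal(count_words("a sad feeling"), 3L)
  expect_equal(count_words("  the sad feeling you get when you are alone  "), 9L)
  expect_equal(count_words("word - !!"), 1L)
  expect_equal(mean_word_count(rep(5, 20)), 5)
  expect_equal(mean_word_count(0:19), 9.5)
  expect_error(mean_word_count(c(3, -1)), "nonnegative")
})

test_that("conceptual distance is negated cosine similarity", {
  emb <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0.6, 0.8))
  tab <- pairwise_conceptual_distance(emb)
  get <- function(x, y) tab$distance[tab$word_a == x & tab$word_b == y]
  expect_equal(get("a", "b"), -1)
  expect_equal(get("a", "c"), 0)
  expect_equal(get("a", "d"), -0.6)
  expect_equal(nrow(tab), 6)
  # normalization is applied internally
  expect_equal(pairwise_conceptual_distance(emb * 10)$distance, tab$distance)
  expect_error(pairwise_conceptual_distance(rbind(a = c(0, 0), b = c(1, 0))),
               "zero")
})

test_that("valence aggregation follows the 45/45/100 grouping", {
  v <- build_vocab_items()
  emb <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(v$word, NULL))
  tab <- pairwise_conceptual_distance(emb)
  expect_equal(nrow(tab), 190)

  # piecewise-constant table: pos-pos -0.2, neg-neg -0.6, cross -0.1
  va <- v$valence[match(tab$word_a, v$word)]
  vb <- v$valence[match(tab$word_b, v$word)]
  tab$distance <- ifelse(va == "positive" & vb == "positive", -0.2,
                         ifelse(va == "negative" & vb == "negative", -0.6, -0.1))
  agg <- valence_aggregates(tab, v)
  expect_equal(agg$within, -0.4)
  expect_equal(agg$between, -0.1)

  tab$distance <- -0.3
  agg_c <- valence_aggregates(tab, v)
  expect_equal(agg_c$within, -0.3)
  expect_equal(agg_c$between, -0.3)

  bad <- v; bad$valence[1] <- "negative"
  expect_error(valence_aggregates(tab, bad), "balanced")
})

test_that("valence-clustered embeddings separate between from within", {
  # noiseless orthogonal centroids: within -1, between 0
  prof0 <- participant_profile(id = "p0", concentration = Inf,
                               emotion_offset_scale = 0, seed = 1)
  prof0$emotion_offsets <- NULL
  defs0 <- simulate_definition_embeddings(prof0, seed = 2)
  agg0 <- valence_aggregates(pairwise_conceptual_distance(defs0$embeddings))
  expect_equal(agg0$within, -1)
  expect_equal(agg0$between, 0)

  # finite concentration keeps the ordering, mirroring the pipeline check
  prof <- participant_profile(id = "p1", concentration = 3, seed = 3)
  defs <- simulate_definition_embeddings(prof, seed = 4)
  agg <- valence_aggregates(pairwise_conceptual_distance(defs$embeddings))
  expect_gt(agg$between, agg$within)

  # between - within approaches 1 as concentration grows (offsets off)
  gaps <- vapply(c(1, 4, 16, 64), function(conc) {
    p <- participant_profile(id = "s", concentration = conc,
                             emotion_offset_scale = 0, seed = 5)
    p$emotion_offsets <- NULL
    d <- simulate_definition_embeddings(p, seed = 6)
    a <- valence_aggregates(pairwise_conceptual_distance(d$embeddings))
    a$between - a$within
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[4], 0.99)
})

test_that("per-participant concept scoring assembles all four measures", {
  items <- build_vocab_items()
  profs <- lapply(1:3, function(i)
    participant_profile(id = paste0("p", i), vocab_ability = 0.9, seed = i))
  sims <- lapply(profs, simulate_definition_embeddings, seed = 9)
  defs <- do.call(rbind, lapply(sims, `[[`, "scores"))
  embs <- setNames(lapply(sims, `[[`, "embeddings"),
                   vapply(profs, `[[`, "", "id"))
  out <- score_concepts(defs, embs)
  expect_equal(nrow(out), 3)
  expect_true(all(out$vocab_total >= 0 & out$vocab_total <= 40))
  expect_true(all(out$between_valence_distance > out$within_valence_distance))
})
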