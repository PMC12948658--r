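#' Total emotional-vocabulary score
#'
#' Sums the human-assigned 0/1/2 accuracy scores over the 20 emotion-word
#' definitions, giving a total in 0-40.
#'
#' @param scores Integer vector of item scores in \{0, 1, 2\}, one per word;
#'   or a data frame with a `score` column.
#' @param n_items Expected number of items (default 20).
#' @return Integer total.
#' @export
vocab_total <- function(scores, n_items = 20) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) != n_items)
    stop("expected ", n_items, " item scores, got ", length(scores))
  if (anyNA(scores) || !all(scores %in% 0:2))
    stop("item scores must be 0, 1 or 2 with no missing items")
  as.integer(sum(scores))
}

#' Count words in a definition
#'
#' Whitespace tokenization after dropping punctuation-only tokens.
#'
#' @param text Character vector of definitions.
#' @return Integer word counts.
#' @export
count_words <- function(text) {
  vapply(strsplit(trimws(text), "\\s+"), function(tok) {
    tok <- tok[nzchar(gsub("[[:punct:]]", "", tok))]
    length(tok)
  }, integer(1))
}

#' Mean definition word count
#'
#' @param word_counts Numeric vector of per-definition word counts, or a data
#'   frame with a `word_count` column.
#' @return Arithmetic mean.
#' @export
mean_word_count <- function(word_counts) {
  if (is.data.frame(word_counts)) word_counts <- word_counts$word_count
  if (anyNA(word_counts) || any(word_counts < 0))
    stop("word counts must be nonnegative and complete")
  mean(word_counts)
}

#' Pairwise conceptual distances between definition embeddings
#'
#' Conceptual distance between two definitions is the negated cosine
#' similarity of their embedding vectors: identical meanings score -1,
#' orthogonal meanings 0. Embeddings are unit-normalized before the dot
#' product. All 190 unordered pairs of the 20 words are returned.
#'
#' @param embeddings Numeric matrix, one row per emotion word (rownames are
#'   the words), columns the embedding dimensions.
#' @return Tibble with columns `word_a`, `word_b`, `distance`.
#' @export
pairwise_conceptual_distance <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (is.null(rownames(embeddings)))
    stop("embedding matrix needs rownames (the emotion words)")
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm == 0)) stop("zero embedding vector for: ",
                          paste(rownames(embeddings)[nrm == 0], collapse = ", "))
  u <- embeddings / nrm
  cossim <- u %*% t(u)
  idx <- utils::combn(nrow(u), 2)
  tibble::tibble(
    word_a = rownames(u)[idx[1, ]],
    word_b = rownames(u)[idx[2, ]],
    distance = -cossim[cbind(idx[1, ], idx[2, ])]
  )
}

#' Within- and between-valence conceptual-distance aggregates
#'
#' The within-valence aggregate is the unweighted mean of (a) the mean over
#' the 45 positive-positive pair distances and (b) the mean over the 45
#' negative-negative pair distances (not the pooled mean of all 90). The
#' between-valence aggregate is the mean over the 100 cross-valence pairs.
#' Higher (less negative) values index more differentiated emotion concepts.
#'
#' @param distances Pair table from [pairwise_conceptual_distance()].
#' @param valence Data frame mapping `word` to `valence`
#'   (default [build_vocab_items()]); the partition must be 10/10.
#' @return List with `within`, `between`, and the three group means
#'   (`mean_pos_pos`, `mean_neg_neg`, `mean_cross`).
#' @export
valence_aggregates <- function(distances, valence = build_vocab_items()) {
  va <- valence$valence[match(distances$word_a, valence$word)]
  vb <- valence$valence[match(distances$word_b, valence$word)]
  if (anyNA(va) || anyNA(vb))
    stop("valence map does not cover all words in the distance table")
  tab <- table(valence$valence[valence$word %in%
                                 unique(c(distances$word_a, distances$word_b))])
  n_pos <- sum(valence$valence == "positive")
  n_neg <- sum(valence$valence == "negative")
  if (n_pos != n_neg)
    stop("valence partition must be balanced, got ", n_pos, "/", n_neg)
  pp <- va == "positive" & vb == "positive"
  nn <- va == "negative" & vb == "negative"
  cross <- !pp & !nn
  stopifnot(sum(pp) == choose(n_pos, 2), sum(nn) == choose(n_neg, 2),
            sum(cross) == n_pos * n_neg)
  m_pp <- mean(distances$distance[pp])
  m_nn <- mean(distances$distance[nn])
  m_x <- mean(distances$distance[cross])
  list(within = mean(c(m_pp, m_nn)), between = m_x,
       mean_pos_pos = m_pp, mean_neg_neg = m_nn, mean_cross = m_x)
}

#' Per-participant concept scores
#'
#' Computes vocabulary total, mean definition word count, and the
#' within/between-valence conceptual-distance aggregates for each participant.
#'
#' @param definitions Data frame with columns `participant`, `word`, `score`,
#'   `word_count`.
#' @param embeddings Named list (by participant) of embedding matrices, or a
#'   function `(participant) -> matrix`.
#' @param valence Valence map (default [build_vocab_items()]).
#' @return Tibble with columns `participant`, `vocab_total`,
#'   `mean_word_count`, `within_valence_distance`, `between_valence_distance`.
#' @export
score_concepts <- function(definitions, embeddings,
                           valence = build_vocab_items()) {
  ids <- unique(definitions$participant)
  rows <- lapply(ids, function(id) {
    sub <- definitions[definitions$participant == id, , drop = FALSE]
    emb <- if (is.function(embeddings)) embeddings(id) else embeddings[[as.character(id)]]
    agg <- valence_aggregates(pairwise_conceptual_distance(emb), valence)
    tibble::tibble(participant = id,
                   vocab_total = vocab_total(sub$score, n_items = nrow(valence)),
                   mean_word_count = mean_word_count(sub$word_count),
                   within_valence_distance = agg$within,
                   between_valence_distance = agg$between)
  })
  do.call(rbind, rows)
}
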