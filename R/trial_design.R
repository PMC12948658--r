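#' Construct an image set for the affect-similarity and choice tasks
#'
#' Builds the abstract stimulus set used by the EmoMap paradigm: affect-inducing
#' images grouped by the emotion they selectively evoke. Identifiers are
#' abstract (the original image database is not shipped); downstream code only
#' relies on labels and counts.
#'
#' @param n_per_emotion Images per emotion category (default 5, giving the
#'   standard 15-image similarity set).
#' @param emotions Character vector of emotion labels.
#' @return A tibble with columns `image`, `emotion`, `role` (all `"target"`).
#' @export
image_set <- function(n_per_emotion = 5,
                      emotions = c("angry", "happy", "sad")) {
  stopifnot(n_per_emotion >= 1, length(emotions) >= 1)
  tibble::tibble(
    image   = paste0(rep(substr(toupper(emotions), 1, 1), each = n_per_emotion),
                     seq_len(n_per_emotion)),
    emotion = rep(emotions, each = n_per_emotion),
    role    = "target"
  )
}

#' All unordered image pairs for the similarity-rating task
#'
#' Enumerates every unordered pair of images exactly once and tags each pair as
#' within-emotion or between-emotion. With the standard 15-image set (5 images
#' for each of 3 emotions) this yields 105 trials: 30 within-emotion pairs
#' (10 per emotion) and 75 between-emotion pairs (25 per emotion pair).
#'
#' @param images An image set as returned by [image_set()].
#' @return A tibble (one row per trial) with columns `task`, `trial`,
#'   `stimulus_a`, `stimulus_b`, `pair_type` (`"within"`/`"between"`),
#'   `emotion` (within pairs), `emotion_pair` (between pairs, labels sorted
#'   and joined by `-`).
#' @export
build_similarity_pairs <- function(images) {
  stopifnot(is.data.frame(images), all(c("image", "emotion") %in% names(images)))
  if (anyDuplicated(images$image) > 0)
    stop("image identifiers must be unique")
  tab <- table(images$emotion)
  if (length(unique(as.integer(tab))) != 1L)
    stop("design error: unbalanced emotion categories (",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  idx <- utils::combn(nrow(images), 2)
  a <- images$image[idx[1, ]]
  b <- images$image[idx[2, ]]
  ea <- images$emotion[idx[1, ]]
  eb <- images$emotion[idx[2, ]]
  within <- ea == eb
  pair_lab <- ifelse(within, NA_character_,
                     paste(pmin(ea, eb), pmax(ea, eb), sep = "-"))
  tibble::tibble(
    task = "similarity",
    trial = seq_along(a),
    stimulus_a = a, stimulus_b = b,
    pair_type = ifelse(within, "within", "between"),
    emotion = ifelse(within, ea, NA_character_),
    emotion_pair = pair_lab
  )
}

#' Round-robin forced-choice trials with trap images
#'
#' Builds the 55-trial all-pairs tournament over 11 target images for one
#' choice condition. Each trial shows two distinct targets plus one trap image
#' (an inducer of a non-target emotion, used as an attention check). Every
#' unordered target pair appears exactly once; trap assignment and trial order
#' are randomized reproducibly by `seed`.
#'
#' @param targets Character vector of exactly 11 target image ids (other
#'   lengths are allowed for testing; n targets give choose(n, 2) trials).
#' @param trap_pool Non-empty character vector of trap image ids.
#' @param seed Integer seed controlling trap draws and trial order.
#' @param condition Condition label carried through (e.g. `"angry"`).
#' @return A tibble with columns `task`, `condition`, `trial`, `stimulus_a`,
#'   `stimulus_b` (the two targets), `trap`.
#' @export
build_choice_trials <- function(targets, trap_pool, seed = 1L,
                                condition = "angry") {
  if (anyDuplicated(targets) > 0) stop("design error: duplicate target images")
  if (length(trap_pool) < 1) stop("design error: empty trap pool")
  n <- length(targets)
  if (n < 2) stop("need at least 2 targets")
  idx <- utils::combn(n, 2)
  n_tr <- ncol(idx)
  plan <- with_local_seed(seed, {
    ord <- sample.int(n_tr)
    trap <- sample(trap_pool, n_tr, replace = TRUE)
    list(ord = ord, trap = trap)
  })
  tibble::tibble(
    task = "choice",
    condition = condition,
    trial = seq_len(n_tr),
    stimulus_a = targets[idx[1, plan$ord]],
    stimulus_b = targets[idx[2, plan$ord]],
    trap = plan$trap[plan$ord]
  )
}

#' Point-light-face task trial plan
#'
#' Full crossing of emotion x actor x spatial level x kinematic level, one
#' trial each, in a seeded random order. The standard design (3 emotions, 4
#' actors, 3 spatial, 3 kinematic levels) yields 108 trials, 12 per
#' spatial x kinematic condition.
#'
#' @param emotions,actors,spatial_levels,kinematic_levels Factor levels; an
#'   integer is shorthand for that many default levels.
#' @param seed Integer seed for the trial-order permutation.
#' @return A tibble with columns `task`, `trial`, `emotion`, `actor`,
#'   `spatial`, `kinematic`.
#' @export
build_plf_trials <- function(emotions = c("angry", "happy", "sad"),
                             actors = 4,
                             spatial_levels = c(50, 100, 150),
                             kinematic_levels = c(50, 100, 150),
                             seed = 1L) {
  if (length(actors) == 1 && is.numeric(actors)) actors <- paste0("actor", seq_len(actors))
  if (length(emotions) == 1 && is.numeric(emotions)) emotions <- paste0("emotion", seq_len(emotions))
  if (length(spatial_levels) == 1 && is.numeric(spatial_levels) && spatial_levels <= 10)
    spatial_levels <- seq_len(spatial_levels)
  if (length(kinematic_levels) == 1 && is.numeric(kinematic_levels) && kinematic_levels <= 10)
    kinematic_levels <- seq_len(kinematic_levels)
  g <- expand.grid(emotion = emotions, actor = actors,
                   spatial = spatial_levels, kinematic = kinematic_levels,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ord <- with_local_seed(seed, sample.int(nrow(g)))
  g <- g[ord, , drop = FALSE]
  tibble::tibble(task = "plf", trial = seq_len(nrow(g)),
                 emotion = g$emotion, actor = g$actor,
                 spatial = g$spatial, kinematic = g$kinematic)
}

#' The 20 emotion words of the vocabulary test, with valence tags
#'
#' Ten positive and ten negative emotion words covering the basic emotions and
#' all four arousal-valence quadrants. The 10/10 valence split partitions the
#' 190 unordered word pairs into 45 positive-positive, 45 negative-negative
#' and 100 cross-valence pairs. "Surprise" is tagged positive.
#'
#' @return A tibble with columns `word` and `valence`
#'   (`"positive"`/`"negative"`).
#' @export
build_vocab_items <- function() {
  negative <- c("anger", "anxiety", "depression", "disgust", "embarrassment",
                "fear", "guilt", "irritation", "loneliness", "sadness")
  words <- c("affection", "amusement", "anger", "anxiety", "awe",
             "contentment", "depression", "desire", "disgust",
             "embarrassment", "excitement", "fear", "guilt", "happiness",
             "interest", "irritation", "loneliness", "peaceful", "sadness",
             "surprise")
  tibble::tibble(word = words,
                 valence = ifelse(words %in% negative, "negative", "positive"))
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
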