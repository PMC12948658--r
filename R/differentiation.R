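#' Similarity ratings to a dissimilarity matrix
#'
#' Inverts 0-10 similarity ratings on the instrument's own scale:
#' `dissimilarity = 10 - rating`, with a zero diagonal. Requires exactly one
#' rating per unordered image pair.
#'
#' @param ratings Data frame with columns `stimulus_a`, `stimulus_b`,
#'   `rating` (one row per unordered pair).
#' @param images Optional character vector fixing the image order of the
#'   output; defaults to the sorted union of the stimuli.
#' @param scale_max Top of the rating scale (default 10).
#' @return Symmetric numeric matrix with dimnames set to the image ids.
#' @export
similarity_to_dissimilarity <- function(ratings, images = NULL,
                                        scale_max = 10) {
  stopifnot(all(c("stimulus_a", "stimulus_b", "rating") %in% names(ratings)))
  if (is.null(images))
    images <- sort(unique(c(ratings$stimulus_a, ratings$stimulus_b)))
  n <- length(images)
  key <- paste(pmin(ratings$stimulus_a, ratings$stimulus_b),
               pmax(ratings$stimulus_a, ratings$stimulus_b))
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0)
    stop("duplicate pair rating(s): ", paste(dup, collapse = ", "))
  idx <- utils::combn(n, 2)
  expected <- paste(pmin(images[idx[1, ]], images[idx[2, ]]),
                    pmax(images[idx[1, ]], images[idx[2, ]]))
  missing <- setdiff(expected, key)
  if (length(missing) > 0)
    stop("missing pair rating(s): ", paste(missing, collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(images, images))
  ia <- match(ratings$stimulus_a, images)
  ib <- match(ratings$stimulus_b, images)
  d[cbind(ia, ib)] <- scale_max - ratings$rating
  d[cbind(ib, ia)] <- scale_max - ratings$rating
  d
}

raw_stress <- function(delta, x) {
  d <- as.matrix(stats::dist(x))
  sum(((delta - d)[upper.tri(delta)])^2)
}

# One Guttman majorization step for unweighted raw stress.
guttman_update <- function(delta, x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  ratio <- matrix(0, n, n)
  pos <- d > 0
  ratio[pos] <- delta[pos] / d[pos]
  diag(ratio) <- 0
  b <- -ratio
  diag(b) <- rowSums(ratio)
  (b %*% x) / n
}

#' Metric multidimensional scaling by stress majorization
#'
#' Embeds a symmetric dissimilarity matrix into `k` dimensions by minimizing
#' the raw stress `sum((delta_ij - ||x_i - x_j||)^2)` with SMACOF-style
#' iterative majorization (Guttman transform). Stress is guaranteed
#' non-increasing across iterations. The best of `n_init` starts is returned:
#' the first start is classical (Torgerson) scaling, the remainder are seeded
#' random configurations.
#'
#' @param delta Symmetric nonnegative matrix with zero diagonal.
#' @param k Embedding dimensionality (default 2).
#' @param seed Integer seed for the random starts.
#' @param n_init Number of starts (default 8).
#' @param max_iter Maximum majorization iterations per start (default 300).
#' @param tol Convergence threshold on the stress decrease (default 1e-6).
#' @return A list of class `mds_embedding`: `points` (n x k matrix),
#'   `stress`, `stress_history` (per-iteration stress of the winning start),
#'   `n_iter`, `k`, `seed`.
#' @export
mds_embed <- function(delta, k = 2, seed = 1L, n_init = 8,
                      max_iter = 300, tol = 1e-6) {
  delta <- as.matrix(delta)
  if (!isSymmetric(unname(delta), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (any(delta < 0)) stop("dissimilarities must be nonnegative")
  if (k < 1) stop("k must be >= 1")
  n <- nrow(delta)
  diag(delta) <- 0

  if (all(delta == 0)) {
    pts <- matrix(0, n, k, dimnames = list(rownames(delta), NULL))
    return(structure(list(points = pts, stress = 0, stress_history = 0,
                          n_iter = 0L, k = k, seed = seed),
                     class = "mds_embedding"))
  }

  starts <- vector("list", n_init)
  cs <- suppressWarnings(stats::cmdscale(delta, k = k))
  if (ncol(cs) < k) cs <- cbind(cs, matrix(0, n, k - ncol(cs)))
  starts[[1]] <- cs
  if (n_init > 1) {
    rnd <- with_local_seed(seed, lapply(seq_len(n_init - 1), function(i)
      matrix(stats::rnorm(n * k, sd = max(delta) / 2), n, k)))
    starts[2:n_init] <- rnd
  }

  best <- NULL
  for (x0 in starts) {
    x <- x0
    s <- raw_stress(delta, x)
    hist <- s
    for (it in seq_len(max_iter)) {
      x_new <- guttman_update(delta, x)
      s_new <- raw_stress(delta, x_new)
      if (s_new > s + 1e-12) break  # majorization guarantee; numerical guard
      x <- x_new
      hist <- c(hist, s_new)
      if (s - s_new < tol) { s <- s_new; break }
      s <- s_new
    }
    if (is.null(best) || s < best$stress)
      best <- list(points = x, stress = s, stress_history = hist,
                   n_iter = length(hist) - 1L)
  }
  rownames(best$points) <- rownames(delta)
  structure(c(best, list(k = k, seed = seed)), class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("Metric MDS embedding: ", nrow(x$points), " points in ", x$k,
      " dimensions\n  raw stress ", format(x$stress), " after ", x$n_iter,
      " iterations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Between- and within-cluster emotion distances from an embedding
#'
#' Averages Euclidean distances in the embedded affect space over the image
#' pairs of each emotion (within: the 10 same-label pairs per emotion) and of
#' each emotion pair (between: the 25 cross-label pairs per pair). The grand
#' within (resp. between) distance is the unweighted mean of the three
#' within (resp. between) means. Larger between-cluster distances index the
#' differentiation of distinct emotional states; larger within-cluster
#' distances the differentiation of similar states.
#'
#' @param embedding An `mds_embedding` (or a bare n x k coordinate matrix).
#' @param labels Emotion label per point; must be balanced across labels.
#' @return A list of class `cluster_distances`: `within` (named per emotion),
#'   `between` (named per emotion pair), `within_mean`, `between_mean`,
#'   `n_pairs_within`, `n_pairs_between`.
#' @export
cluster_distances <- function(embedding, labels) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points else as.matrix(embedding)
  if (length(labels) != nrow(pts))
    stop("one label per embedded point required")
  tab <- table(labels)
  if (length(unique(as.integer(tab))) != 1L)
    stop("label imbalance: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  d <- as.matrix(stats::dist(pts))
  lev <- sort(names(tab))
  within <- vapply(lev, function(e) {
    i <- which(labels == e)
    mean(d[i, i][upper.tri(d[i, i])])
  }, numeric(1))
  n_within <- choose(as.integer(tab[1]), 2)
  pairs <- utils::combn(lev, 2)
  between <- apply(pairs, 2, function(p)
    mean(d[labels == p[1], labels == p[2], drop = FALSE]))
  names(between) <- apply(pairs, 2, paste, collapse = "-")
  structure(
    list(within = within, between = between,
         within_mean = mean(within), between_mean = mean(between),
         n_pairs_within = n_within,
         n_pairs_between = as.integer(tab[1])^2),
    class = "cluster_distances"
  )
}

#' @export
print.cluster_distances <- function(x, ...) {
  cat("Emotion-cluster distances (embedded space)\n")
  cat("  within :", paste(sprintf("%s=%.3f", names(x$within), x$within),
                          collapse = "  "),
      sprintf(" | mean %.3f\n", x$within_mean))
  cat("  between:", paste(sprintf("%s=%.3f", names(x$between), x$between),
                          collapse = "  "),
      sprintf(" | mean %.3f\n", x$between_mean))
  invisible(x)
}

#' Per-participant emotion-differentiation scores from similarity ratings
#'
#' Runs the full part-1 pipeline for each participant: ratings to
#' dissimilarities, SMACOF embedding, cluster distances.
#'
#' @param ratings Similarity trial table with a `participant` column.
#' @param images Image set (see [image_set()]) giving emotion labels.
#' @param k,seed,n_init,max_iter,tol Passed to [mds_embed()]; each
#'   participant's embedding uses a seed offset by their index.
#' @return Tibble, one row per participant, with columns `participant`,
#'   `dist_between_*`, `dist_between_mean`, `dist_within_*`,
#'   `dist_within_mean`, `stress`, `k`.
#' @export
score_differentiation <- function(ratings, images = image_set(), k = 2,
                                  seed = 1L, n_init = 8, max_iter = 300,
                                  tol = 1e-6) {
  stopifnot("participant" %in% names(ratings))
  ids <- unique(ratings$participant)
  rows <- lapply(seq_along(ids), function(i) {
    sub <- ratings[ratings$participant == ids[i], , drop = FALSE]
    delta <- similarity_to_dissimilarity(sub, images = images$image)
    emb <- mds_embed(delta, k = k, seed = seed + i, n_init = n_init,
                     max_iter = max_iter, tol = tol)
    labels <- images$emotion[match(rownames(emb$points), images$image)]
    cd <- cluster_distances(emb, labels)
    out <- c(as.list(cd$between), between_mean = cd$between_mean,
             as.list(cd$within), within_mean = cd$within_mean)
    names(out) <- c(paste0("dist_between_", gsub("-", "_", names(cd$between))),
                    "dist_between_mean",
                    paste0("dist_within_", names(cd$within)),
                    "dist_within_mean")
    tibble::as_tibble(c(list(participant = ids[i]), out,
                        list(stress = emb$stress, k = k)))
  })
  do.call(rbind, rows)
}
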