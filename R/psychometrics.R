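#' Split-half reliability with Spearman-Brown correction
#'
#' Splits the item columns into two halves, sums each half per participant,
#' correlates the half-scores across participants and applies the
#' Spearman-Brown prophecy correction `2r / (1 + r)` for test length.
#'
#' @param m Numeric participants x items matrix (or data frame).
#' @param split `"odd_even"` (default) assigns alternating item indices to
#'   the halves; `"random"` draws a random half of the items using `seed`.
#' @param seed Seed for the random split.
#' @return List with `coefficient`, `r` (half-score correlation), and the
#'   item indices of each half.
#' @export
split_half_spearman_brown <- function(m, split = c("odd_even", "random"),
                                      seed = 1L) {
  split <- match.arg(split)
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 participants")
  idx <- seq_len(ncol(m))
  half1 <- if (split == "odd_even") idx[idx %% 2 == 1] else
    with_local_seed(seed, sort(sample(idx, floor(ncol(m) / 2))))
  half2 <- setdiff(idx, half1)
  s1 <- rowSums(m[, half1, drop = FALSE])
  s2 <- rowSums(m[, half2, drop = FALSE])
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0)
    stop("zero-variance half score; split-half reliability undefined")
  r <- stats::cor(s1, s2)
  list(coefficient = 2 * r / (1 + r), r = r, half1 = half1, half2 = half2)
}

#' Cronbach's alpha
#'
#' Unstandardized internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, with
#' sample (n-1) variances throughout.
#'
#' @param m Numeric participants x items matrix (or data frame).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 participants")
  item_vars <- apply(m, 2, stats::var)
  if (any(item_vars == 0))
    stop("all-constant item column(s); alpha undefined")
  total_var <- stats::var(rowSums(m))
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
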