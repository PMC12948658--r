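# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, direct counting) so it stays independent of the package's
# vectorized implementations.

targets11 <- function() sprintf("t%02d", 1:11)

# A filtered choice table realizing an arbitrary "winner function":
# win(a, b) returns the chosen image for the unordered pair {a, b}.
make_choice_table <- function(targets, win, condition = "angry") {
  idx <- t(combn(length(targets), 2))
  tibble::tibble(
    participant = "p1",
    condition = condition,
    trial = seq_len(nrow(idx)),
    stimulus_a = targets[idx[, 1]],
    stimulus_b = targets[idx[, 2]],
    trap = "trap1",
    chosen = mapply(win, targets[idx[, 1]], targets[idx[, 2]]),
    redo = FALSE,
    rt_ms = 1500
  )
}

# Strictly transitive chooser: earlier elements of `order` always win.
transitive_win <- function(order) {
  function(a, b) if (match(a, order) < match(b, order)) a else b
}

# Regular tournament on 11 images: i beats j iff (j - i) mod 11 is in 1..5.
# Every image wins exactly 5 of its 10 pairings.
rotational_win <- function(targets) {
  function(a, b) {
    i <- match(a, targets); j <- match(b, targets)
    if (((j - i) %% length(targets)) <= 5) a else b
  }
}

# Brute-force consistency total: recount ranks and item differences with
# explicit loops, no shared code with the package.
oracle_consistency_total <- function(tab) {
  imgs <- sort(unique(c(tab$stimulus_a, tab$stimulus_b)))
  w <- setNames(integer(length(imgs)), imgs)
  for (i in seq_len(nrow(tab))) w[tab$chosen[i]] <- w[tab$chosen[i]] + 1L
  total <- 0
  for (i in seq_len(nrow(tab))) {
    lose <- if (tab$chosen[i] == tab$stimulus_a[i]) tab$stimulus_b[i]
            else tab$stimulus_a[i]
    total <- total + w[tab$chosen[i]] - w[lose]
  }
  unname(total)
}

# Independent Thurstone simulation of one tournament's consistency total.
oracle_simulate_total <- function(intensities, noise_sd) {
  n <- length(intensities)
  idx <- t(combn(n, 2))
  chosen <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    u <- intensities[idx[r, ]] + rnorm(2, sd = noise_sd)
    chosen[r] <- idx[r, which.max(u)]
  }
  w <- tabulate(chosen, nbins = n)
  total <- 0
  for (r in seq_len(nrow(idx))) {
    lose <- setdiff(idx[r, ], chosen[r])
    total <- total + w[chosen[r]] - w[lose]
  }
  total
}

# Brute-force cluster distance means over an explicit double loop.
oracle_cluster_means <- function(pts, labels) {
  n <- nrow(pts)
  within <- list(); between <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    key <- paste(sort(c(labels[i], labels[j])), collapse = "-")
    if (labels[i] == labels[j]) within[[labels[i]]] <- c(within[[labels[i]]], dij)
    else between[[key]] <- c(between[[key]], dij)
  }
  list(within = vapply(within[sort(names(within))], mean, numeric(1)),
       between = vapply(between[sort(names(between))], mean, numeric(1)))
}

# Quick null analysis frame mimicking the cohort structure: subject random
# intercepts, one within-subject factor, participant-level covariates, and a
# configurable additive group shift on the outcome.
make_null_frame <- function(n1 = 58, n2 = 59, group_shift = 0,
                            sd_subject = 1, sd_resid = 1) {
  n <- n1 + n2
  subj <- sprintf("s%03d", 1:n)
  grp <- c(rep("autistic", n1), rep("non-autistic", n2))
  intercept <- rnorm(n, sd = sd_subject) +
    ifelse(grp == "autistic", group_shift, 0)
  age <- rnorm(n, 33, 12)
  tas <- rnorm(n, 55, 13)
  f <- expand.grid(participant = subj, condition = c("angry", "happy", "sad"),
                   stringsAsFactors = FALSE)
  i <- match(f$participant, subj)
  f$group <- grp[i]
  f$age <- age[i]
  f$tas <- tas[i]
  f$y <- intercept[i] + rnorm(nrow(f), sd = sd_resid)
  f
}
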