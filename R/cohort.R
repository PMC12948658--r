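clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  clamp(stats::rnorm(n, mean, sd), lo, hi)
}

# Evaluate code either on the current RNG stream (seed = NULL) or under a
# local stream seeded with `seed`.
maybe_seed <- function(seed, code) {
  if (is.null(seed)) code else with_local_seed(seed, code)
}

#' Latent generative parameters for one simulated participant
#'
#' Bundles everything the task simulators need: a clustered latent affect
#' geometry for the 15 similarity images, per-condition latent intensity
#' vectors for the choice task, embedding-generation parameters for the
#' definitions, a recognition signal model, noise scales, and covariates.
#' All parameters are explicit so downstream recovery tests can compare
#' estimates against them.
#'
#' @param id Participant identifier.
#' @param group `"autistic"` or `"non-autistic"`.
#' @param cluster_separation Distance between latent emotion-cluster
#'   centroids (equilateral triangle side) in affect space.
#' @param within_spread SD of image scatter around its cluster centroid.
#' @param sim_noise_sd Rating noise SD for the similarity task.
#' @param intensities Named list of latent intensity vectors (length 11) per
#'   choice condition; generated when `NULL`.
#' @param intensity_sd SD used to draw latent intensities when generating.
#' @param choice_noise_sd Thurstonian comparison noise SD.
#' @param p_lapse Probability of selecting the trap image on a trial
#'   (recorded as a redo event followed by a valid re-choice).
#' @param embed_dim Embedding dimensionality for simulated definitions.
#' @param concentration Inverse noise scale for definition embeddings
#'   (`Inf` gives noiseless vectors).
#' @param emotion_offset_scale Size of the per-emotion offset from the
#'   valence centroid.
#' @param vocab_ability Probability parameter of the Binomial(2, ability)
#'   item-score model, in \[0, 1\].
#' @param word_count_mean Mean definition length in words (>= 1).
#' @param recog_base,recog_signal,recog_noise_sd Recognition rating model:
#'   the displayed emotion is rated around `clamp(base + signal, 0, 10)`,
#'   distractors around `clamp(base - signal/2, 0, 10)`, with Gaussian noise.
#' @param covariates Named list of participant covariates (age, sex, nvr,
#'   education, aq, tas, subscales).
#' @param seed Seed for the generated geometry/intensities/offsets
#'   (`NULL` = current RNG stream).
#' @param k Affect-space dimensionality (default 2).
#' @param images Image set for the similarity task.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(id = "p01", group = "non-autistic",
                                cluster_separation = 5, within_spread = 1,
                                sim_noise_sd = 1.5,
                                intensities = NULL, intensity_sd = 2,
                                choice_noise_sd = 0.8, p_lapse = 0,
                                embed_dim = 16, concentration = 4,
                                emotion_offset_scale = 0.5,
                                vocab_ability = 0.75, word_count_mean = 12,
                                recog_base = 3, recog_signal = 3.5,
                                recog_noise_sd = 1.5,
                                covariates = list(), seed = NULL, k = 2,
                                images = image_set()) {
  stopifnot(sim_noise_sd >= 0, choice_noise_sd >= 0, recog_noise_sd >= 0,
            within_spread >= 0, cluster_separation >= 0,
            p_lapse >= 0, p_lapse <= 1,
            vocab_ability >= 0, vocab_ability <= 1, word_count_mean >= 1)
  if (!is.null(covariates$aq))
    stopifnot(covariates$aq >= 0, covariates$aq <= 50)
  if (!is.null(covariates$tas))
    stopifnot(covariates$tas >= 20, covariates$tas <= 100)

  emotions <- unique(images$emotion)
  conditions <- c("control", emotions)

  generated <- maybe_seed(seed, {
    # cluster centroids on a regular simplex scaled to the requested side
    ang <- 2 * pi * (seq_along(emotions) - 1) / length(emotions)
    cent <- cbind(cos(ang), sin(ang))
    if (k > 2) cent <- cbind(cent, matrix(0, length(emotions), k - 2))
    if (length(emotions) > 1) {
      side <- sqrt(sum((cent[1, ] - cent[2, ])^2))
      cent <- cent * cluster_separation / side
    }
    coords <- cent[match(images$emotion, emotions), , drop = FALSE] +
      matrix(stats::rnorm(nrow(images) * k, sd = within_spread),
             nrow(images), k)
    rownames(coords) <- images$image

    ints <- intensities
    if (is.null(ints))
      ints <- stats::setNames(lapply(conditions, function(cc)
        stats::rnorm(11, sd = intensity_sd)), conditions)

    offs <- matrix(stats::rnorm(20 * embed_dim, sd = emotion_offset_scale),
                   20, embed_dim)
    list(coords = coords, intensities = ints, emotion_offsets = offs)
  })
  structure(
    list(id = id, group = group,
         images = images, k = k,
         coords = generated$coords,
         cluster_separation = cluster_separation,
         within_spread = within_spread,
         sim_noise_sd = sim_noise_sd,
         intensities = generated$intensities,
         choice_noise_sd = choice_noise_sd, p_lapse = p_lapse,
         embed_dim = embed_dim, concentration = concentration,
         emotion_offset_scale = emotion_offset_scale,
         emotion_offsets = generated$emotion_offsets,
         vocab_ability = vocab_ability,
         word_count_mean = word_count_mean,
         recog_base = recog_base, recog_signal = recog_signal,
         recog_noise_sd = recog_noise_sd,
         covariates = covariates),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat("Simulated participant ", x$id, " (", x$group, ")\n", sep = "")
  cat("  affect geometry: separation ", x$cluster_separation,
      ", spread ", x$within_spread, ", k = ", x$k, "\n", sep = "")
  cat("  noise: similarity ", x$sim_noise_sd, ", choice ",
      x$choice_noise_sd, ", recognition ", x$recog_noise_sd, "\n", sep = "")
  invisible(x)
}

#' Simulate similarity ratings for one participant
#'
#' Each pair's rating is `clamp(10 - g * d_ij + noise, 0, 10)` where `d_ij`
#' is the latent Euclidean distance between the two images in the
#' participant's affect space and the gain `g` maps the participant's
#' maximum latent distance onto the full 0-10 scale.
#'
#' @param profile A [participant_profile()].
#' @param plan Similarity trial plan from [build_similarity_pairs()].
#' @param seed Seed (`NULL` = current stream).
#' @return The plan with added columns `participant`, `rating`, `rt_ms`,
#'   `redo` (always `FALSE`; the similarity task has no redo events here).
#' @export
simulate_similarity_ratings <- function(profile, plan, seed = NULL) {
  if (!all(c(plan$stimulus_a, plan$stimulus_b) %in% rownames(profile$coords)))
    stop("plan stimuli not covered by the profile's latent geometry")
  d <- as.matrix(stats::dist(profile$coords))
  dij <- d[cbind(plan$stimulus_a, plan$stimulus_b)]
  g <- if (max(d) > 0) 10 / max(d) else 1
  maybe_seed(seed, {
    eps <- stats::rnorm(nrow(plan), sd = profile$sim_noise_sd)
    rating <- clamp(10 - g * dij + eps, 0, 10)
    rt <- pmax(stats::rnorm(nrow(plan), 1500, 200), 200)
    tibble::tibble(participant = profile$id, plan,
                   rating = rating, rt_ms = rt, redo = FALSE)
  })
}

#' Simulate forced choices for one participant
#'
#' Two-alternative Thurstone model: on each trial both targets receive a
#' sampled utility (latent intensity plus Gaussian comparison noise) and the
#' larger one is chosen. With probability `p_lapse` the trap image is
#' selected first, which is recorded as a redo event (`redo = TRUE`) followed
#' by a valid re-choice, mirroring the attention-check procedure.
#'
#' @param profile A [participant_profile()].
#' @param plan Choice plan from [build_choice_trials()]; its condition must
#'   have an intensity vector in the profile.
#' @param seed Seed (`NULL` = current stream).
#' @return Tibble of trial events (possibly more rows than trials when
#'   lapses occur) with columns `participant`, `condition`, `trial`,
#'   `stimulus_a`, `stimulus_b`, `trap`, `chosen`, `redo`, `rt_ms`.
#' @export
simulate_choices <- function(profile, plan, seed = NULL) {
  cond <- unique(plan$condition)
  stopifnot(length(cond) == 1)
  ints <- profile$intensities[[cond]]
  if (is.null(ints)) stop("no intensity vector for condition ", cond)
  targets <- sort(unique(c(plan$stimulus_a, plan$stimulus_b)))
  if (is.null(names(ints))) {
    if (length(ints) != length(targets))
      stop("missing intensity entries: ", length(targets), " targets, ",
           length(ints), " intensities")
    names(ints) <- targets
  }
  if (!all(targets %in% names(ints)))
    stop("missing intensity entries for: ",
         paste(setdiff(targets, names(ints)), collapse = ", "))

  n <- nrow(plan)
  maybe_seed(seed, {
    u_a <- ints[plan$stimulus_a] + stats::rnorm(n, sd = profile$choice_noise_sd)
    u_b <- ints[plan$stimulus_b] + stats::rnorm(n, sd = profile$choice_noise_sd)
    lapse <- profile$p_lapse > 0 & stats::runif(n) < profile$p_lapse
    picks <- tibble::tibble(
      participant = profile$id, condition = cond, trial = plan$trial,
      stimulus_a = plan$stimulus_a, stimulus_b = plan$stimulus_b,
      trap = plan$trap,
      chosen = ifelse(u_a >= u_b, plan$stimulus_a, plan$stimulus_b),
      redo = FALSE,
      rt_ms = pmax(stats::rnorm(n, 1500, 250), 200))
    if (any(lapse)) {
      traps <- picks[lapse, , drop = FALSE]
      traps$chosen <- traps$trap
      traps$redo <- TRUE
      traps$rt_ms <- pmax(stats::rnorm(sum(lapse), 1200, 200), 200)
      out <- rbind(traps, picks)
      # presentation order: trap event precedes the re-choice of its trial
      out[order(out$trial, -out$redo), , drop = FALSE]
    } else picks
  })
}

#' Simulate definition embeddings, item scores and word counts
#'
#' Each emotion word's embedding is the unit-normalized sum of its valence
#' centroid, a participant-specific per-emotion offset, and Gaussian noise
#' scaled by `1 / concentration`. Item scores are Binomial(2, vocab_ability)
#' draws; word counts are `1 + Poisson(word_count_mean - 1)`.
#'
#' @param profile A [participant_profile()].
#' @param items Vocabulary items from [build_vocab_items()].
#' @param dim Embedding dimensionality (default the profile's `embed_dim`).
#' @param seed Seed (`NULL` = current stream).
#' @return List with `embeddings` (20 x dim unit-row matrix), `scores`
#'   (tibble word/score/word_count).
#' @export
simulate_definition_embeddings <- function(profile, items = build_vocab_items(),
                                           dim = profile$embed_dim,
                                           seed = NULL) {
  stopifnot(dim >= 2)
  n <- nrow(items)
  v_pos <- c(1, rep(0, dim - 1))
  v_neg <- c(0, 1, rep(0, dim - 2))
  centroid <- t(vapply(items$valence,
                       function(v) if (v == "positive") v_pos else v_neg,
                       numeric(dim)))
  offs <- profile$emotion_offsets
  if (is.null(offs) || ncol(offs) != dim)
    offs <- matrix(0, n, dim)
  maybe_seed(seed, {
    noise <- if (is.finite(profile$concentration))
      matrix(stats::rnorm(n * dim), n, dim) / profile$concentration
    else matrix(0, n, dim)
    raw <- centroid + offs[seq_len(n), , drop = FALSE] + noise
    emb <- raw / sqrt(rowSums(raw^2))
    rownames(emb) <- items$word
    scores <- stats::rbinom(n, 2, profile$vocab_ability)
    wc <- 1 + stats::rpois(n, max(profile$word_count_mean - 1, 0))
    list(embeddings = emb,
         scores = tibble::tibble(participant = profile$id,
                                 word = items$word, score = scores,
                                 word_count = wc))
  })
}

#' Simulate point-light-face recognition ratings
#'
#' Signal-plus-noise rating model: the displayed emotion's rating is centred
#' on `clamp(base + signal, 0, 10)`, each distractor on
#' `clamp(base - signal/2, 0, 10)`; independent Gaussian noise is added and
#' the result clamped back to the 0-10 scale.
#'
#' @param profile A [participant_profile()].
#' @param plan PLF plan from [build_plf_trials()].
#' @param seed Seed (`NULL` = current stream).
#' @return The plan with `participant`, `rating_angry`, `rating_happy`,
#'   `rating_sad`, `rt_ms` columns added.
#' @export
simulate_recognition_ratings <- function(profile, plan, seed = NULL) {
  emotions <- c("angry", "happy", "sad")
  stopifnot(all(plan$emotion %in% emotions))
  n <- nrow(plan)
  mu_correct <- clamp(profile$recog_base + profile$recog_signal, 0, 10)
  mu_wrong <- clamp(profile$recog_base - profile$recog_signal / 2, 0, 10)
  maybe_seed(seed, {
    r <- sapply(emotions, function(e) {
      mu <- ifelse(plan$emotion == e, mu_correct, mu_wrong)
      clamp(mu + stats::rnorm(n, sd = profile$recog_noise_sd), 0, 10)
    })
    r <- matrix(r, nrow = n, dimnames = list(NULL, paste0("rating_", emotions)))
    tibble::tibble(participant = profile$id, plan,
                   rating_angry = r[, "rating_angry"],
                   rating_happy = r[, "rating_happy"],
                   rating_sad = r[, "rating_sad"],
                   rt_ms = pmax(stats::rnorm(n, 2000, 300), 200))
  })
}

#' Cohort-level simulation configuration
#'
#' Defaults describe the study cohort the package emulates: 58 autistic and
#' 59 non-autistic adults matched on age, sex and non-verbal reasoning, with
#' covariate distributions taken from the sample-characteristics table, and
#' all group effects on latent task parameters set to zero (the reported
#' findings are null group effects).
#'
#' @param n_autistic,n_non_autistic Group sizes.
#' @param effects Named list of additive shifts applied to the autistic
#'   group's latent parameters; names among `cluster_separation`,
#'   `within_spread`, `sim_noise_sd`, `choice_noise_sd`, `concentration`,
#'   `vocab_ability`, `word_count_mean`, `recog_signal`, `recog_noise_sd`.
#' @param seed Master seed.
#' @param embed_dim Definition-embedding dimensionality.
#' @param k Affect-space dimensionality.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_autistic = 58, n_non_autistic = 59,
                          effects = list(), seed = 1L, embed_dim = 16, k = 2) {
  stopifnot(n_autistic >= 1, n_non_autistic >= 1,
            all(vapply(effects, is.finite, logical(1))))
  structure(list(n_autistic = n_autistic, n_non_autistic = n_non_autistic,
                 effects = effects, seed = seed, embed_dim = embed_dim, k = k),
            class = "cohort_config")
}

# Population-level covariate parameters by group (sample-characteristics
# table of the emulated study; education not tabulated there, see vignette).
covariate_params <- list(
  "non-autistic" = list(age = c(32.27, 15.30), nvr = c(59.50, 13.54),
                        aq = c(20.80, 8.54), tas = c(49.48, 14.25),
                        p_female = 33 / 59),
  "autistic" = list(age = c(33.26, 11.54), nvr = c(61.11, 18.61),
                    aq = c(35.34, 7.80), tas = c(61.79, 11.60),
                    p_female = 31 / 58)
)

draw_covariates <- function(group) {
  p <- covariate_params[[group]]
  aq <- rnorm_trunc(1, p$aq[1], p$aq[2], 0, 50)
  tas <- rnorm_trunc(1, p$tas[1], p$tas[2], 20, 100)
  # AQ: five 10-item domains; TAS-20: DIF (7 items), DDF (5), EOT (8)
  aq_w <- stats::rnorm(5, 1 / 5, 0.03); aq_w <- aq_w / sum(aq_w)
  tas_w <- stats::rnorm(3, c(7, 5, 8) / 20, 0.03); tas_w <- tas_w / sum(tas_w)
  list(age = rnorm_trunc(1, p$age[1], p$age[2], 18, 80),
       sex = if (stats::runif(1) < p$p_female) "female" else "male",
       nvr = rnorm_trunc(1, p$nvr[1], p$nvr[2], 0, 100),
       education = rnorm_trunc(1, 16, 2.5, 10, 24),
       aq = aq,
       aq_social = aq * aq_w[1], aq_attention_switch = aq * aq_w[2],
       aq_attention_detail = aq * aq_w[3], aq_communication = aq * aq_w[4],
       aq_imagination = aq * aq_w[5],
       tas = tas,
       tas_dif = tas * tas_w[1], tas_ddf = tas * tas_w[2],
       tas_eot = tas * tas_w[3])
}

#' Simulate a complete cohort across all four tasks
#'
#' Draws per-participant latent parameters from population distributions
#' (with any configured additive group effects on the autistic group),
#' builds each task's trial plan, and simulates raw trial events for every
#' participant. Deterministic given the master seed. The returned
#' ground-truth table holds the latent parameters so downstream scoring can
#' be tested for parameter recovery.
#'
#' @param config A [cohort_config()].
#' @return List of class `emomap_cohort` with elements `participants`
#'   (covariates tibble), `similarity`, `choices`, `plf` (raw trial-event
#'   tibbles), `definitions` (scores/word counts), `embeddings` (named list
#'   of matrices), `truth` (latent-parameter tibble), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- function(name) if (is.null(config$effects[[name]])) 0 else config$effects[[name]]
  images <- image_set()
  sim_plan <- build_similarity_pairs(images)
  plf_plan <- build_plf_trials(seed = config$seed)
  conditions <- c("control", "angry", "happy", "sad")

  with_local_seed(config$seed, {
    groups <- c(rep("autistic", config$n_autistic),
                rep("non-autistic", config$n_non_autistic))
    ids <- sprintf("p%03d", seq_along(groups))

    acc <- list(participants = list(), similarity = list(), choices = list(),
                plf = list(), definitions = list(), embeddings = list(),
                truth = list())
    for (i in seq_along(ids)) {
      g <- groups[i]
      shift <- function(name) if (g == "autistic") eff(name) else 0
      cov <- draw_covariates(g)
      prof <- participant_profile(
        id = ids[i], group = g,
        cluster_separation = rnorm_trunc(1, 5 + shift("cluster_separation"), 1, 0.5, Inf),
        within_spread = rnorm_trunc(1, 1 + shift("within_spread"), 0.25, 0.05, Inf),
        sim_noise_sd = rnorm_trunc(1, 1.5 + shift("sim_noise_sd"), 0.5, 0.05, Inf),
        choice_noise_sd = rnorm_trunc(1, 0.8 + shift("choice_noise_sd"), 0.3, 0.01, Inf),
        concentration = rnorm_trunc(1, 4 + shift("concentration"), 1, 0.5, Inf),
        vocab_ability = rnorm_trunc(1, 0.75 + shift("vocab_ability"), 0.12, 0.05, 1),
        word_count_mean = rnorm_trunc(1, 12 + shift("word_count_mean"), 3, 2, Inf),
        recog_signal = rnorm_trunc(1, 3.5 + shift("recog_signal"), 1, 0, 10),
        recog_noise_sd = rnorm_trunc(1, 1.5 + shift("recog_noise_sd"), 0.4, 0.1, Inf),
        covariates = cov, seed = NULL, k = config$k,
        embed_dim = config$embed_dim, images = images)

      acc$similarity[[i]] <- simulate_similarity_ratings(prof, sim_plan)
      acc$choices[[i]] <- do.call(rbind, lapply(conditions, function(cc) {
        plan <- build_choice_trials(paste0(substr(cc, 1, 2), sprintf("%02d", 1:11)),
                                    trap_pool = paste0("trap_", cc, "_", 1:3),
                                    seed = sample.int(2^30, 1), condition = cc)
        simulate_choices(prof, plan)
      }))
      acc$plf[[i]] <- simulate_recognition_ratings(prof, plf_plan)
      defs <- simulate_definition_embeddings(prof)
      acc$definitions[[i]] <- defs$scores
      acc$embeddings[[ids[i]]] <- defs$embeddings

      acc$participants[[i]] <- tibble::tibble(
        participant = ids[i], group = g, tibble::as_tibble(cov))
      acc$truth[[i]] <- tibble::tibble(
        participant = ids[i], group = g,
        cluster_separation = prof$cluster_separation,
        within_spread = prof$within_spread,
        sim_noise_sd = prof$sim_noise_sd,
        choice_noise_sd = prof$choice_noise_sd,
        concentration = prof$concentration,
        vocab_ability = prof$vocab_ability,
        word_count_mean = prof$word_count_mean,
        recog_signal = prof$recog_signal,
        recog_noise_sd = prof$recog_noise_sd)
    }
    structure(list(participants = do.call(rbind, acc$participants),
                   similarity = do.call(rbind, acc$similarity),
                   choices = do.call(rbind, acc$choices),
                   plf = do.call(rbind, acc$plf),
                   definitions = do.call(rbind, acc$definitions),
                   embeddings = acc$embeddings,
                   truth = do.call(rbind, acc$truth),
                   config = config),
              class = "emomap_cohort")
  })
}

#' @export
print.emomap_cohort <- function(x, ...) {
  cat("Simulated cohort: ", x$config$n_autistic, " autistic + ",
      x$config$n_non_autistic, " non-autistic participants (seed ",
      x$config$seed, ")\n", sep = "")
  cat("  similarity trials: ", nrow(x$similarity),
      "; choice events: ", nrow(x$choices),
      "; recognition trials: ", nrow(x$plf), "\n", sep = "")
  invisible(x)
}
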