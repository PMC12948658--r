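Package: emomapr
Title: Scoring and Inference for Emotion Differentiation, Consistency, and
    Recognition Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the measurement pipeline for a battery of
    computer-based emotion tasks: forced-choice tournament consistency
    scoring (EmoMap part 2), multidimensional-scaling emotion
    differentiation from pairwise similarity ratings (EmoMap part 1),
    point-light-face emotion recognition accuracy, emotional-vocabulary
    totals and embedding-based conceptual distances, and split-half /
    internal-consistency reliability. Includes a synthetic cohort
    generator with known latent parameters for recovery testing, and an
    inference layer providing repeated-measures group comparisons,
    shadow-feature (Boruta-style) random-forest variable selection, and
    bias-corrected bootstrap mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
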