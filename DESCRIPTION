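Package: indecision
Title: Difference-with-Indecision Modelling of Two-Interval Contrast Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-interval forced-choice contrast
    judgments with an explicit "don't know" opt-out (2-AFC-DK). Implements
    the difference-with-indecision signal-detection model (Gaussian internal
    difference signal partitioned by two decision criteria) with multinomial
    maximum-likelihood fitting, a generative simulator of balanced
    surround-suppression experiment designs, deterministic binocular-disparity
    stimulus geometry (quantized cumulative-Gaussian depth bump, disparity
    annuli, non-oriented filtered-noise textures, stereo-pair rendering), and
    within-subject group statistics (repeated-measures ANOVA and
    Bonferroni-corrected paired post-hoc tests) on the fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
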