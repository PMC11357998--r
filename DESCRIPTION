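Package: sexspan
Title: Profiling Age-Dependent Sex Differences in Phenotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how sex differences in continuous and
    binary phenotypes change across the adult age span. Implements
    penalized-spline additive models with a parametric sex term, a shared
    age smooth and a by-sex deviation smooth; Cohen's f-squared effect-size
    gating of age-by-sex interactions; sliding-window t-test localization of
    turning-point ages; a menopause leave-out analysis; cross-validated
    nested-model variance decomposition; PERMANOVA; UPGMA clustering of
    fitted sex-specific trajectories; penalization-based selection of
    lifestyle-by-age-by-sex interaction terms with bootstrap stability; and
    a longitudinal new-onset event scan. Includes a synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
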