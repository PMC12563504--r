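Package: serodyn
Title: Genotype-Informed Dynamic Modelling of the Serotonin Presynapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates presynaptic serotonin (5-HT) dynamics per individual
    from genotypes at five functional variants in TPH2, SLC6A4 and MAOA.
    Allele-specific expression fold-changes are converted into activity
    coefficients that scale a kinetic ordinary-differential-equation model of
    serotonin synthesis, vesicular packaging, release, reuptake and
    degradation. Each simulated trajectory is summarised into thirty
    time-series features (six statistics for each of five molecular species),
    and features are compared across diagnostic and suicide-attempt groups
    with Kruskal-Wallis tests and two-way aligned rank transform (ART) ANOVA
    with Tukey-adjusted post hoc contrasts. A Hardy-Weinberg synthetic-cohort
    generator with X-linked MAOA sampling makes the full analysis runnable
    without access to individual-level genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    deSolve,
    dplyr,
    emmeans,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
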