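Package: sleepsynth
Title: Physiologically Constrained Hierarchical Copula Synthesis of Sleep and
    Heart-Rate-Variability Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates physiologically plausible synthetic cohorts of seven
    sleep and heart-rate-variability parameters (total, deep and light sleep
    duration, SDNN, RMSSD, LF/HF and PNN50) by fitting constraint-preserving
    marginal transforms and a two-subsystem hierarchical Archimedean copula
    with a Gaussian cross-subsystem link, then sampling under a hard
    physiological constraint system with clinically weighted regions.
    Includes fidelity and diversity metrics (histogram KL divergence,
    two-sample Kolmogorov-Smirnov tests, a Gaussian-kernel HSIC with
    permutation p-values), endpoint sensitivity/specificity with
    Clopper-Pearson intervals, HRV profile clustering into three archetypes
    with stability diagnostics, template-based report rendering and lexicon
    parsing, profile-conditioned chain-of-thought assembly, and a toy
    profile-aided top-k mixture-of-experts router with load-balancing and
    profile-alignment losses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
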