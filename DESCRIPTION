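Package: ntopower
Title: Simulation and Prospective Power Analysis for Non-Target-Organism
    Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical simulation of count and presence/absence data as
    encountered in comparative field trials for environmental risk assessment
    of genetically modified plants: overdispersed (negative binomial,
    Poisson-lognormal, overdispersed Poisson, beta-binomial,
    binomial-logitnormal) and zero-inflated families, randomized block and
    completely randomized designs, reference-variety populations,
    multi-environment trials with genotype-by-environment interaction, and
    repeated measures with compound-symmetric or autoregressive correlation.
    Includes likelihood-ratio difference tests, profile-likelihood confidence
    intervals for the GM/comparator mean ratio, two one-sided tests (TOST)
    equivalence testing, and a Monte-Carlo engine for power curves and
    required-replication tables.
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
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
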