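Package: seedmet
Title: Seed Metabolic Rate Allometry and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the standard metabolic rate (SMR) of seeds
    from closed-system respirometry traces and analysing its allometric and
    phylogenetic structure. Converts raw oxygen partial-pressure time series
    into per-seed oxygen consumption rates with moving-window smoothing,
    hypoxia truncation, slope-based rate estimation, replicate outlier
    screening and Q10 temperature standardization; fits power-law
    mass-scaling models by ordinary and phylogenetic generalized least
    squares (Pagel's lambda estimated by restricted maximum likelihood);
    quantifies phylogenetic signal with Pagel's lambda and Blomberg's K
    (permutation test); fits three-parameter log-logistic germination time
    courses; and relates allometric residuals to domestication, germination
    traits and bioclimatic covariates with ordered climate contrasts and
    backward stepwise type-III regression. Includes a full synthetic-data
    generator (birth-death trees, Brownian traits, respirometry traces,
    germination counts, block-correlated climate covariates) so the whole
    pipeline can be exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
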