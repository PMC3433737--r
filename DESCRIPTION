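Package: agediv
Title: Clade Age, Species Richness, and Diversification Rate Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether stem clade age predicts extant species
    richness across higher taxa. Provides phylogenetic generalized least squares
    regression of log-richness on stem age with Pagel's lambda signal estimation,
    closed-form constant-rate birth-death mathematics (survival probability,
    conditioned expectations, progeny-count distributions and exact samplers),
    a stepwise AICc rate-shift model for backbone trees with tip richness that
    permits extinction above speciation, a two-state birth-death simulator of
    higher-taxon origination used to build Spearman null distributions, a
    hierarchical lognormal relaxed-rate Bayesian model with posterior-predictive
    standardized effect sizes, robustness simulations for phylogenetic signal
    and clade-age error, and synthetic data generators for all of the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
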