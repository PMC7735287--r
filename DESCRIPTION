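Package: compsig
Title: Signatures of Interspecific Competition in Continuous-Trait Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares models of continuous-trait evolution on time-calibrated
    phylogenies, including models in which lineages interact: Brownian motion,
    Ornstein-Uhlenbeck, time-dependent and diversity-dependent rate models, and the
    matching competition model in which traits are repelled from the mean of coexisting
    competitors. Interactions can be restricted to ecological guilds inferred from
    categorical diet and foraging data and reconstructed through time with stochastic
    character maps. Provides exact tip mean/covariance computation for every model,
    profiled maximum-likelihood fitting, AICc-based competition scoring, false-positive
    simulation studies, the D statistic for phylogenetic signal in binary competition
    flags, and a seeded synthetic-data generator emulating multi-clade comparative
    datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
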