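Package: connherit
Title: Twin Heritability, Transcriptional Coupling and Generative Models of Connectome Rich-Club Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying genetic influences on hub connectivity of
    brain networks. Implements group-connectome construction by consistency
    and density thresholding, rich-club statistics with rewiring and
    weight-permutation null models, network communicability, edge-wise
    ACTE/ACE/AE/CE/E twin variance-component modelling with AIC model
    selection, distance-corrected correlated gene expression with per-gene
    contribution scores and gene-score-resampling enrichment,
    microstructural profile covariance, and cost-topology-genetics
    generative models of network growth fitted by Kolmogorov-Smirnov
    energy. Includes synthetic-data generators that emulate the statistical
    structure of twin-imaging, transcriptomic and histological inputs so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
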