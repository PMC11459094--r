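Package: topoRank
Title: Degree-Based Topological Indices and Multi-Criteria Drug Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes nine degree-based topological indices (Randic,
    atom-bond connectivity, first and second Zagreb, sum-connectivity,
    forgotten, geometric-arithmetic, harmonic and hyper-Zagreb) from
    hydrogen-suppressed molecular graphs via degree-pair edge partitions,
    derives criterion weights from correlations between indices and
    physicochemical properties (ratio weighting), and ranks candidate
    drugs with the VIKOR compromise method and simple additive weighting
    (SAW). Bundles a 16-drug lung-disorder case study (decision matrix and
    boiling-point / enthalpy-of-vaporization correlation tables) that the
    package reproduces end to end, and a synthetic generator of
    chemical-like random graphs and exactly-correlated property vectors
    for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'molgraph.R'
    'indices.R'
    'qspr.R'
    'mcdm.R'
    'saw.R'
    'synthetic.R'
    'fixtures.R'
    'topoRank-package.R'
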