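Package: quartetSignal
Title: Four-Cluster Likelihood Mapping and Confounding-Signal Diagnostics
    for Phylogenomic Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quartet-based tools for dissecting phylogenetic signal in
    partitioned supermatrices. Implements Four-cluster Likelihood-Mapping
    (FcLM) with seven-region Voronoi classification on the topology
    simplex, the approximately unbiased (AU) tree test via multiscale
    RELL bootstrap, pairwise Bowker matched-pairs tests of symmetry for
    diagnosing violations of stationarity, reversibility and homogeneity
    (SRH), signal-destroying alignment permutation schemes, coverage-based
    supermatrix compilation filters (strict and group-relaxed), a
    Felsenstein-pruning likelihood engine for small fixed topologies, and
    a non-stationary sequence simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, ape, phangorn, Biostrings,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
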