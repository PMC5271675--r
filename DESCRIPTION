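Package: dyncomp
Title: Dynamic Components of Molecular Dynamics Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reduces molecular dynamics trajectories of tightly packed
    proteins (such as G protein-coupled receptors) to a network of coupled
    dynamic components. Side-chain interactions that switch between distance
    substates are detected by Gaussian-mixture modality analysis of
    inter-residue minimum-distance time series; global domain motions are
    detected as single-linkage clusters of highly cross-correlated
    C-alpha distance time series. Components are linked by the absolute
    average dynamic cross-correlation of their member series and
    partitioned into communities by edge betweenness. Includes a seeded
    synthetic-trajectory generator with planted switches and domain blocks
    for validation, and exporters to PDB (pseudobond CONECT records),
    GraphML and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Network, Clustering, TimeCourse
RoxygenNote: 7.3.3
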