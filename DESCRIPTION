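Package: ensdock
Title: Ensemble Docking Benchmarking with Trajectory Clustering and
    Rank-Order Evaluation
Version: 0.1.0
Authors@R:
    person("Ensdock", "Maintainers", email = "maintainers@ensdock.example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking ensemble docking (Relaxed Complex
    Scheme) workflows. Provides a trajectory data model with multi-model
    PDB input/output, atom selections including a binding-site selection
    by distance to docked ligand poses, Kabsch superposition with
    pairwise-RMSD and RMSF ensemble diagnostics, PCA and TICA
    dimensionality reduction with cross-validated VAMP2 feature scoring,
    trajectory discretization by k-means (with medoid frame extraction)
    and GROMOS neighbor-counting clustering with cutoff-selection
    criteria, docking-score aggregation (minimum, average,
    population-weighted average), Kendall rank-correlation evaluation
    against experimental affinities with a permutation null distribution,
    and synthetic generators (Markov-switching conformational ensembles,
    planted-affinity score matrices) so the full pipeline is testable
    without external simulation or docking engines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
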