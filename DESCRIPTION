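Package: rccppi
Title: Residue Cluster Classes for Protein-Protein Interaction Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the residue cluster class (RCC) representation of
    protein structure: maximal cliques of a residue contact graph, grouped
    by clique size (3 to 6 residues) and classified by the integer
    partition induced by runs of sequence-consecutive residues, yielding a
    26-dimensional count vector per protein chain. On top of the
    featurizer it provides a protein-protein interaction (PPI) modeling
    pipeline: pair-feature construction by sum or concatenation,
    raw/normalized/standardized scaling, class-imbalance sampling grids
    (random undersampling and SMOTE oversampling), leakage-aware
    train/test splitting by domain annotation, separability diagnostics
    (set diameter versus inter-set distance, exact linear separability),
    per-feature rank-sum screening with multiplicity correction, and a
    kernel-weighted nearest-neighbour classifier evaluated by percent
    correctly classified instances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    foreign,
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
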