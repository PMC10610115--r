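Package: ScreenFunnel
Title: Hybrid Virtual-Screening Funnel with Graph-Attention Rescoring and
    Binding-Pose Stability Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for hierarchical structure-based virtual screening of
    small-molecule libraries. Implements physicochemical descriptor
    conventions (average molecular weight, Ertl topological polar surface
    area including sulfur and phosphorus contributions, hydrogen-bond
    donor/acceptor counts, rotatable bonds), conversion of molecules to
    attributed graphs with docking-score-augmented node features, a graph
    attention network (GAT) regressor for pIC50 trained on CPU with full
    reproducibility, staged docking-score funnels with consensus ranking,
    binding-pose stability scores (PoseScore and PersScore) from replicate
    trajectories, and four-parameter logistic IC50 fitting. A synthetic-data
    module generates molecule libraries with planted structure-activity
    signal, score tables, replicate trajectories, and dose-response curves
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    jsonlite,
    minpack.lm
Suggests:
    ChemmineOB,
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, MachineLearning
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assay.R'
    'chem-parse.R'
    'chem-io.R'
    'utils.R'
    'descriptors.R'
    'synthetic.R'
    'pose.R'
    'funnel.R'
    'mol-graph.R'
    'gat.R'
    'gnn.R'
    'cli.R'
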