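Package: drgpn
Title: Apoptosis-Priming and Compositional Analysis of Human DRG in Diabetic Painful Neuropathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-nucleus RNA-seq of human dorsal root
    ganglia (DRG) across Control, Diabetic and diabetic-painful-neuropathy (DPN)
    donors. Implements per-nucleus gene-module scoring with expression-binned
    control genes and a composite apoptosis-priming (trigger) score with
    ApopHigh classification; permutation-based cell-type proportion testing
    with bootstrap confidence intervals; a minimal differential-expression
    engine (per-cell rank-sum and pseudobulk negative-binomial Wald); a
    ligand-receptor interactome filter-and-rank scheme; and a seeded synthetic
    cohort generator with planted effects so the whole pipeline is testable
    without access to donor-level data. Self-contained nonparametric statistics
    (Wilcoxon rank-sum with exact small-sample enumeration, Kruskal-Wallis,
    Benjamini-Hochberg) underpin every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
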