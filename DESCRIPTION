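Package: kturnfold
Title: Sequence Rules, Ion-Titration Fitting and Metal Coordination
    Analysis for RNA Kink-Turns
Version: 0.1.0
Authors@R:
    person("kturnfold", "developers", email = "kturnfold@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the ion-induced folding of RNA kink-turn
    (k-turn) motifs. Provides positional annotation of k-turn sequences
    using the standard b/n-strand nomenclature, an empirical rule engine
    that predicts the ability of a k-turn to fold in metal ions alone from
    the identity of its 3b.3n base pair, nonlinear fitting of two-state
    ion-titration FRET curves with a Hill dependence, cohort-level 3b.3n
    distribution statistics over sequence alignments, detection and
    geometric scoring of inner-sphere metal coordination to guanine O6
    atoms in RNA coordinate files, and seeded generators for all synthetic
    inputs (titration curves, 3b.3n variant scans, sequence cohorts and
    coordinate fixtures).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
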