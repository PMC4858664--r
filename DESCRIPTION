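Package: aggscape
Title: Structure-Corrected Protein Aggregation Propensity Profiling over
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compute per-residue intrinsic (sequence-based)
    aggregation propensity profiles, to correct them by per-conformation
    solvent exposure so that buried aggregation-prone residues are treated
    as protected, and to average the corrected scores over conformational
    ensembles supplied as multi-MODEL PDB files.  Includes ensemble
    structure analytics (Shrake-Rupley solvent accessible surface areas,
    backbone and chi1 dihedrals, Kabsch-Sander beta-bridge assignment,
    AlphaBeta and beta-content collective variables, weighted-histogram
    free-energy surfaces, Kabsch-superposition RMSF), a rational mutation
    design stage (candidate-site selection, saturation mutagenesis scans,
    protective/promoting rankings, box statistics), and a synthetic-data
    generator that builds sequences with planted hydrophobic hot spots and
    ensemble pairs with a controlled solvent-protection shift.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
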