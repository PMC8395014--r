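Package: vartraj
Title: Recessive Variant Prioritization and Comparative Protein
    Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two companion pipelines for the study of a recessive disease
    variant in a consanguineous pedigree. The genetics arm applies a
    hard-filter cascade, an autosomal-recessive co-segregation test,
    runs-of-homozygosity (ROH) intersection, and score-based ranking to a
    multi-sample VCF plus pedigree. The structural arm computes comparative
    statistics over wild-type and mutant protein trajectories: Kabsch
    superposition, RMSD and per-residue RMSF, center-of-mass residue
    contact occupancy and difference maps, geometric hydrogen-bond
    occupancy, C-alpha distance statistics, and a Shrake-Rupley
    hydrophobic-surface score. Synthetic-data generators with planted
    ground truth (family VCFs and toy-dimer trajectories) make every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
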