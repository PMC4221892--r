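Package: paralogdiv
Title: Functional Divergence Analysis Between Paralogous Protein Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects amino-acid sites under Type I and Type II functional
    divergence between two paralog clades of an aligned protein family,
    with detection thresholds calibrated as the 99th percentile of scores
    on simulated null alignments and a leave-one-out alignment jackknife.
    Includes a stability-divergence statistic built on per-position ddG
    substitution matrices (median per clade, absolute between-clade
    difference, rank-sum group comparison), molecular-clock rate
    calibration from taxon-pair divergence times with node dating,
    structural mapping of divergent sites (interface and ligand-proximal
    residues at a distance cutoff, N-glycosylation sequon scanning), and
    seeded generators for null and planted-site alignments, surrogate ddG
    matrices and toy structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
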