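Package: cofilinscreen
Title: Dual-Functionality Deep Mutational Scanning of the Cofilin N-Terminus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a pooled competitive-growth screen of
    cofilin-1 N-terminal variants (residues 2-5; 16,000 sequences) assayed
    with and without LIM-kinase induction. Converts amplicon FASTQ reads to
    variant count tables, computes per-replicate and mean log2 enrichment
    scores for the function and kinase-sensitivity contrasts, classifies
    variants by quadrant into LIMK-sensitive and LIMK-resistant sets,
    summarises positional preferences as heat maps, box statistics, exact
    binomial probability logos with Bonferroni thresholds, and pairwise
    residue covariation tests, and fits the accompanying biochemistry:
    sigmoidal dose-response curves for actin binding (K_0.5) and
    Michaelis-Menten kinase kinetics (kcat, KM) with radiolabel standard-curve
    calibration. A seedable synthetic-data generator simulates the
    serial-dilution competition, finite-depth sequencing, amplicon reads and
    noisy assay curves so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
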