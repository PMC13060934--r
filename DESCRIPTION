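Package: acylamines
Title: Discovery and Quantification of Microbial N-Acyl Amides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links bacterially produced N-acyl amides (acyl amines) to host
    phenotypes through four connected computational stages: combinatorial
    in-silico acyl-amine library construction with exact-mass (ppm) screening
    of untargeted LC-MS feature tables and MS/MS diagnostic-fragment
    confirmation; detection of the three-gene C-T-A acyl-amine-synthesis
    operon (acyl transferase, acyl carrier, fatty acyl-CoA ligase) in
    bacterial genomes by protein homology plus operon-structure rules;
    translated-read quantification of operon genes in shotgun metagenomes
    normalized to reads per million; and the supporting statistics
    (exact Mann-Whitney U, Benjamini-Hochberg FDR, hypergeometric pathway
    enrichment, Spearman correlation, trapezoidal AUC). A synthetic-data
    module generates feature tables, MS/MS spectra, genomes with planted
    operons at controlled protein identity, and metagenomic read sets with
    ground truth, so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
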