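Package: promcage
Title: Promoterome Analysis of CAGE Transcription Start Site Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of cap analysis of gene expression (CAGE) data from
    per-sample transcription start site (CTSS) count tables through to
    promoter-level biology: power-law normalization to tags per million,
    tag-cluster and consensus-cluster calling with interquantile trimming,
    promoter shape classification (sharp, peaked broad, broad) and shape
    transitions between conditions, core-promoter motif scanning and
    Fisher-exact enrichment (TATA-box, CCAAT-box, Sp1, INR, YY1, poly-W
    pentamers, WW-dinucleotide profiles), negative-binomial differential
    expression across replicates, alternative-promoter utilization classes,
    monotone temporal expression trends, tissue-specificity indices (Tau,
    entropy) and gene-set permutation and chi-square statistics.  A
    fully seeded synthetic-data generator emits genomes, annotations and
    multi-sample CTSS tables with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
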