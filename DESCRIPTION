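Package: heatmir
Title: Discovery and Differential Expression of Heat-Responsive Plant
    miRNAs from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying known and novel
    plant microRNAs from multi-library small RNA sequencing data and calling
    heat-responsive expression changes. Covers adapter trimming and tag
    collapsing, structural-RNA contaminant removal, exact genome mapping,
    precursor excision and secondary-structure folding, stem-loop (hairpin)
    criteria in the miRcheck tradition, known/novel classification against a
    reference mature-miRNA catalog, chi-square differential expression with
    fold-change and p-value thresholds, plant-style miRNA target
    complementarity scoring with cleavage-site prediction and 5' RACE clone
    tallying, plus a synthetic-data generator that plants hairpin loci with
    known expression truth so every stage can be validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    data.table,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
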