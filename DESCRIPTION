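Package: vmte
Title: Clade-Resolved Analysis of Variably Methylated Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline linking retrotransposon
    sequence clades to loss of KRAB zinc-finger protein (KZFP) and KAP1/TRIM28
    mediated silencing, CpG density, genomic context, strain polymorphism and
    variable DNA methylation. Provides readers for repeat annotations, coverage
    tracks, peak calls and per-CpG methylation calls; a desk-scale progressive
    multiple aligner with low-occupancy trimming and UPGMA clade cutting;
    projection of per-base coverage into alignment-column (consensus) space and
    onto 5'-anchor windows; CpG observed/expected window scoring with matched
    random backgrounds; proximity-based genomic context classification;
    deletion-based strain conservation; replicate-consistent and novel peak
    detection; sampling-based age enrichment of variably methylated loci; and a
    fully deterministic synthetic-data generator with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
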