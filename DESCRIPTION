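Package: exomir
Title: Exosomal Small RNA-Seq Quantification and A-to-I Editing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for profiling microRNA content
    of exosome-enriched fractions from small RNA sequencing data. Assigns
    adapter-trimmed reads to mature miRNAs on hairpin references, tallies
    per-position internal modifications, filters and normalizes expression by
    the trimmed mean of M-values (TMM), tests differential abundance, and
    calls adenosine-to-inosine (ADAR) editing sites with a binomial
    sequencing-error null model, including replication filtering, editing
    levels, differential-editing tests, seed-region classification and
    trinucleotide motif context. A bundled simulator generates libraries with
    known abundances, planted fold-changes and planted editing events so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
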