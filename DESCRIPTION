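Package: ampedit
Title: Quantification of A-to-I RNA Editing from Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantifying adenosine-to-inosine (A-to-I) RNA
    editing at focused sites from barcoded amplicon deep-sequencing reads.
    Provides inline-barcode demultiplexing, read filtering (N-containing and
    short reads), gapless assignment of reads to amplicon references with
    editing sites masked from mismatch counting, per-site pileups and
    editing frequencies, background A-to-G error-rate estimation from
    flanking control positions, site categorization against the background,
    single-nucleotide-polymorphism flagging, joint haplotype phasing of
    multi-site amplicons with codon-level collapse to protein isoforms
    (the serotonin 2C receptor A/B/E/C/D case), per-site group comparisons
    with Benjamini-Hochberg correction, and a read simulator with truth
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
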