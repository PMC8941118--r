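Package: skewfit
Title: Cumulative Nucleotide Skew Scanning and Replichore Model Fitting
Version: 0.1.0
Authors@R:
    person("skewfit", "developers", email = "skewfit@example.org", role = c("aut", "cre"))
Description: Scans prokaryotic chromosomes and plasmids for eleven cumulative
    nucleotide skews (GC, TA, per codon position, non-coding, and gene strand
    bias) at fixed 4096-nucleotide resolution, fits a four-parameter circular
    piecewise-linear replichore model (leading/lagging slopes, leading-strand
    fraction, and origin shift) by multi-start downhill-simplex optimisation,
    and serialises the results to a set of database-style CSV schemas. Ships a
    synthetic-genome simulator with planted replichore structure, strand-biased
    genes and codon bias so that every pipeline stage can be validated against
    known ground truth without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    optparse,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
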