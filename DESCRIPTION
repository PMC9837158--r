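Package: ReadContext
Title: Read-Structure Segmentation and Service-Sequence Diagnostics for NGS Reads
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments each FastQ read (or read pair) into an ordered,
    strand-annotated sequence of exact pattern matches, length-labelled
    short unknown segments (K-mers), and longer unrecognized stretches,
    then aggregates the resulting "read structure" strings into a ranked
    frequency table. Patterns (adapters, primers, barcodes and other
    service sequences) are supplied as an ordered JSON dictionary and are
    diagnosed before the run: sort-order checks, pairwise Levenshtein
    confusability, nesting, and reverse-complement palindrome detection.
    Includes a synthetic-read generator with exact truth labels, an HTML
    summary writer, a gzip NDJSON per-read detail writer, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    parallel,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, QualityControl, Preprocessing
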