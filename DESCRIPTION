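Package: seqvalid
Title: Validation and Integrity Checking of Bioinformatics File Formats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: File validation for sequencing-pipeline inputs and outputs.
    Every file gets three universal checks (existence, compression
    integrity, checksum verification against md5/sha512 sidecars), then a
    format-specific validator dispatched from an extensible registry.
    Grammar and container validators cover FASTQ, SAM, BAM, CRAM, VCF and
    ZIP, with quick and thorough depth levels, BGZF-aware gzip walking,
    checksum sidecar generation, parallel multi-file validation with
    deterministic reports, a deterministic corrupted-fixture generator for
    testing validators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    utils,
    parallel,
    jsonlite,
    digest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
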