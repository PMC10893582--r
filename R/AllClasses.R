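## S4 classes for the validation domain: categories, check results, per-file
## reports, run summaries, sidecar checksums and fixture recipes.

.FORMATS      <- c("FASTQ", "SAM", "BAM", "CRAM", "VCF", "ZIP", "UNKNOWN")
.COMPRESSIONS <- c("NONE", "GZIP", "BGZF", "ZIP_CONTAINER")
.CHECK_IDS    <- c("EXISTS", "READABLE", "NONEMPTY", "COMPRESSION_OK",
                   "CHECKSUM_OK", "FORMAT_OK", "INDEX_PRESENT")
.ALGORITHMS   <- c("md5", "sha512")

#' FileCategory: detected type and compression of a path
#'
#' The result of [detectFileType()]: the format implied by the file name, the
#' compression that name claims, and the suffix chain that matched. The
#' category drives validator dispatch; `UNKNOWN` formats still receive the
#' three universal checks.
#'
#' @slot format one of `FASTQ`, `SAM`, `BAM`, `CRAM`, `VCF`, `ZIP`, `UNKNOWN`.
#' @slot compression one of `NONE`, `GZIP`, `BGZF`, `ZIP_CONTAINER`. `BAM`
#'   always claims `BGZF`; `SAM` always claims `NONE`.
#' @slot extensionMatched the suffix that matched, e.g. `".fastq.gz"`; empty
#'   for `UNKNOWN` names with no recognized trailing `.gz`/`.zip`.
#' @exportClass FileCategory
setClass("FileCategory",
    representation(format = "character", compression = "character",
                   extensionMatched = "character"))

setValidity("FileCategory", function(object) {
    msg <- character()
    ## any registered format name is allowed: the registry is runtime-
    ## extensible, so the built-in list is not a closed enum
    if (length(object@format) != 1L || !nzchar(object@format))
        msg <- c(msg, "format must be a single non-empty string")
    if (!object@compression %in% .COMPRESSIONS)
        msg <- c(msg, sprintf("unknown compression '%s'", object@compression))
    if (identical(object@format, "BAM") &&
        !identical(object@compression, "BGZF"))
        msg <- c(msg, "BAM must claim BGZF compression")
    if (identical(object@format, "SAM") &&
        !identical(object@compression, "NONE"))
        msg <- c(msg, "SAM must claim no compression")
    if (length(msg)) msg else TRUE
})

#' CheckResult: outcome of one named check
#'
#' @slot checkId one of `EXISTS`, `READABLE`, `NONEMPTY`, `COMPRESSION_OK`,
#'   `CHECKSUM_OK`, `FORMAT_OK`, `INDEX_PRESENT`.
#' @slot passed logical; whether the check passed.
#' @slot detail human-readable reason on failure (naming the byte offset,
#'   line number or companion file where applicable), or an advisory note on
#'   a pass (e.g. "no checksum found").
#' @slot warning logical; advisory severity. A failed warning-severity check
#'   (e.g. a missing BAM index under the default policy) does not flip a
#'   file's verdict.
#' @exportClass CheckResult
setClass("CheckResult",
    representation(checkId = "character", passed = "logical",
                   detail = "character", warning = "logical"))

setValidity("CheckResult", function(object) {
    msg <- character()
    if (!object@checkId %in% .CHECK_IDS)
        msg <- c(msg, sprintf("unknown check id '%s'", object@checkId))
    if (!isTRUE(object@passed) && !nzchar(object@detail))
        msg <- c(msg, "a failed check must carry a non-empty detail")
    if (length(msg)) msg else TRUE
})

#' CompanionSet: sidecar checksums and index files found next to a path
#'
#' @slot checksumSidecars data.frame with columns `algorithm` (`md5` or
#'   `sha512`) and `path`; at most one row per algorithm, every path existed
#'   at detection time.
#' @slot indexFiles character vector of existing index companions
#'   (`.bai`/`.csi`/`.crai`/`.tbi`).
#' @exportClass CompanionSet
setClass("CompanionSet",
    representation(checksumSidecars = "data.frame", indexFiles = "character"))

setValidity("CompanionSet", function(object) {
    df <- object@checksumSidecars
    msg <- character()
    if (!all(c("algorithm", "path") %in% names(df)))
        msg <- c(msg, "checksumSidecars needs columns 'algorithm' and 'path'")
    else if (anyDuplicated(df$algorithm))
        msg <- c(msg, "at most one sidecar per algorithm")
    if (length(msg)) msg else TRUE
})

#' SidecarChecksum: a parsed checksum companion file
#'
#' @slot algorithm `md5` or `sha512`.
#' @slot digestHex lowercase hex digest (32 chars for md5, 128 for sha512).
#' @slot referencedName the file name the sidecar references, or empty for
#'   the bare-digest dialect.
#' @exportClass SidecarChecksum
setClass("SidecarChecksum",
    representation(algorithm = "character", digestHex = "character",
                   referencedName = "character"))

setValidity("SidecarChecksum", function(object) {
    want <- c(md5 = 32L, sha512 = 128L)
    if (!object@algorithm %in% .ALGORITHMS)
        return(sprintf("unknown algorithm '%s'", object@algorithm))
    if (nchar(object@digestHex) != want[[object@algorithm]])
        return(sprintf("%s digest must have %d hex characters",
                       object@algorithm, want[[object@algorithm]]))
    if (grepl("[^0-9a-f]", object@digestHex))
        return("digest must be lowercase hex")
    TRUE
})

#' FileReport: ordered check results and verdict for one file
#'
#' @slot path the validated path.
#' @slot category the [FileCategory] the path was dispatched under.
#' @slot checks list of [CheckResult], in pipeline order (universal checks
#'   before the format-specific ones).
#' @slot verdict `"PASS"` or `"FAIL"`; `PASS` iff no failed non-warning check.
#' @slot warnings number of warning-severity results.
#' @exportClass FileReport
setClass("FileReport",
    representation(path = "character", category = "FileCategory",
                   checks = "list", verdict = "character",
                   warnings = "integer"))

setValidity("FileReport", function(object) {
    if (!object@verdict %in% c("PASS", "FAIL"))
        return("verdict must be PASS or FAIL")
    if (!all(vapply(object@checks, is, logical(1), class2 = "CheckResult")))
        return("checks must all be CheckResult objects")
    hard_fail <- any(vapply(object@checks,
        function(ck) !ck@passed && !ck@warning, logical(1)))
    if (identical(object@verdict, "PASS") == hard_fail)
        return("verdict must be PASS exactly when no non-warning check failed")
    TRUE
})

#' RunSummary: aggregate outcome over a set of validated paths
#'
#' @slot reports list of [FileReport] in input order.
#' @slot nPass,nFail counts of passing and failing files;
#'   `nPass + nFail` equals the number of input paths.
#' @slot exitCode 0 when every file passed, 1 otherwise.
#' @exportClass RunSummary
setClass("RunSummary",
    representation(reports = "list", nPass = "integer", nFail = "integer",
                   exitCode = "integer"))

setValidity("RunSummary", function(object) {
    msg <- character()
    if (object@nPass + object@nFail != length(object@reports))
        msg <- c(msg, "nPass + nFail must equal the number of reports")
    if ((object@exitCode == 0L) != (object@nFail == 0L))
        msg <- c(msg, "exitCode must be 0 exactly when nFail is 0")
    if (length(msg)) msg else TRUE
})

#' FixtureSpec: recipe for a deterministic synthetic test file
#'
#' Same spec, same bytes: fixture generation is fully seeded, so a
#' `FixtureSpec` identifies its output file exactly.
#'
#' @slot format one of `FASTQ`, `SAM`, `BAM`, `CRAM`, `VCF`, `ZIP`.
#' @slot seed integer RNG seed.
#' @slot nRecords number of records (reads, variant rows, archive entries).
#' @slot corruption `"NONE"` or one named corruption operator; see
#'   [applicableCorruptions()].
#' @slot compress whether to compress the output (gzip for FASTQ, BGZF for
#'   VCF); ignored for formats whose container is fixed (BAM is always BGZF,
#'   SAM never compressed).
#' @exportClass FixtureSpec
setClass("FixtureSpec",
    representation(format = "character", seed = "integer",
                   nRecords = "integer", corruption = "character",
                   compress = "logical"))

setValidity("FixtureSpec", function(object) {
    if (!object@format %in% setdiff(.FORMATS, "UNKNOWN"))
        return(sprintf("no fixture generator for format '%s'", object@format))
    if (object@nRecords < 0L)
        return("nRecords must be non-negative")
    ok <- applicableCorruptions(object@format, object@compress)
    if (!object@corruption %in% ok)
        return(sprintf("corruption '%s' not applicable to %s%s fixtures",
                       object@corruption, object@format,
                       if (object@compress) " (compressed)" else ""))
    TRUE
})
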