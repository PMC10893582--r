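## The validator registry: two edit-only mappings (extension -> format,
## format -> validator). Supporting a new type means adding one entry to
## each; nothing else in the pipeline changes.

.registry <- new.env(parent = emptyenv())
.registry$extensions <- list()   # ".fastq.gz" -> list(format, compression)
.registry$validators <- list()   # "FASTQ" -> list(fun, needsIndex)

#' Register file extensions for a format
#'
#' Extensions are matched case-insensitively, longest suffix first. The
#' compression recorded here is what the *name* claims; [sniffContainer()]
#' later reads the actual magic bytes, and any disagreement surfaces as a
#' failed `COMPRESSION_OK` check.
#'
#' @param extensions character vector of suffixes including the leading dot,
#'   e.g. `c(".fastq", ".fastq.gz")`.
#' @param format format name the suffixes map to.
#' @param compression claimed compression per extension (recycled), each one
#'   of `NONE`, `GZIP`, `BGZF`, `ZIP_CONTAINER`.
#' @return invisibly, the previous mapping entries (for restoration).
#' @seealso [registerValidator()], [unregisterFileFormat()]
#' @export
registerFileFormat <- function(extensions, format,
                               compression = "NONE") {
    stopifnot(is.character(extensions), length(extensions) >= 1L,
              all(startsWith(extensions, ".")))
    compression <- rep_len(compression, length(extensions))
    stopifnot(all(compression %in% .COMPRESSIONS))
    old <- .registry$extensions[tolower(extensions)]
    for (i in seq_along(extensions))
        .registry$extensions[[tolower(extensions[i])]] <-
            list(format = format, compression = compression[i])
    invisible(old)
}

#' Register a validator routine for a format
#'
#' @param format format name as used in [registerFileFormat()].
#' @param fun `function(path, category, thorough, strict)` returning a list
#'   of [CheckResult] (typically a single `FORMAT_OK`).
#' @param needsIndex whether files of this format should be checked for an
#'   index companion: `FALSE`, `TRUE`, or a `function(category)` deciding per
#'   file (compressed VCF needs one, plain VCF does not).
#' @return invisibly, the previous entry.
#' @export
registerValidator <- function(format, fun, needsIndex = FALSE) {
    stopifnot(is.function(fun))
    old <- .registry$validators[[format]]
    .registry$validators[[format]] <- list(fun = fun, needsIndex = needsIndex)
    invisible(old)
}

#' @rdname registerFileFormat
#' @export
unregisterFileFormat <- function(extensions) {
    keep <- setdiff(names(.registry$extensions), tolower(extensions))
    .registry$extensions <- .registry$extensions[keep]
    invisible(NULL)
}

#' @rdname registerValidator
#' @export
unregisterValidator <- function(format) {
    .registry$validators[[format]] <- NULL
    invisible(NULL)
}

#' List registered formats and their extensions
#'
#' @return data.frame with columns `extension`, `format`, `compression`,
#'   `has_validator`.
#' @export
registeredFormats <- function() {
    exts <- .registry$extensions
    data.frame(
        extension = names(exts),
        format = vapply(exts, `[[`, character(1), "format"),
        compression = vapply(exts, `[[`, character(1), "compression"),
        has_validator = vapply(exts, function(e)
            !is.null(.registry$validators[[e$format]]), logical(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}

.lookupValidator <- function(format) .registry$validators[[format]]

.formatNeedsIndex <- function(format, category) {
    entry <- .registry$validators[[format]]
    if (is.null(entry)) return(FALSE)
    ni <- entry$needsIndex
    if (is.function(ni)) isTRUE(ni(category)) else isTRUE(ni)
}

## Built-in mappings; called from .onLoad and restorable from tests.
registerBuiltinFormats <- function() {
    registerFileFormat(c(".fastq", ".fq"), "FASTQ", "NONE")
    registerFileFormat(c(".fastq.gz", ".fq.gz"), "FASTQ", "GZIP")
    registerFileFormat(".sam", "SAM", "NONE")
    registerFileFormat(".bam", "BAM", "BGZF")
    registerFileFormat(".cram", "CRAM", "NONE")
    registerFileFormat(".vcf", "VCF", "NONE")
    registerFileFormat(".vcf.gz", "VCF", "GZIP")
    registerFileFormat(".zip", "ZIP", "ZIP_CONTAINER")

    registerValidator("FASTQ", function(path, category, thorough, strict)
        list(validateFastq(path, category, thorough)$check))
    registerValidator("SAM", function(path, category, thorough, strict)
        list(validateSam(path, thorough)$check))
    registerValidator("BAM", function(path, category, thorough, strict)
        list(validateBam(path, thorough)$check), needsIndex = TRUE)
    registerValidator("CRAM", function(path, category, thorough, strict)
        list(validateCram(path)), needsIndex = TRUE)
    registerValidator("VCF", function(path, category, thorough, strict)
        list(validateVcf(path, category, thorough, strict)$check),
        needsIndex = function(category) category@compression != "NONE")
    registerValidator("ZIP", function(path, category, thorough, strict)
        list(validateZip(path, thorough)))
    invisible(NULL)
}
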