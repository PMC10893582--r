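## Type detection: extension mapping (longest suffix wins), magic-byte
## container sniffing, and companion discovery.

#' Detect a file's category from its name
#'
#' Pure function of the path string: the longest registered suffix that
#' matches (case-insensitively) decides format and claimed compression. An
#' unmatched name maps to `UNKNOWN`, with compression inferred from a
#' trailing `.gz`/`.zip` only, so the universal checks can still run.
#'
#' @param path a file path; need not exist.
#' @return a [FileCategory].
#' @examples
#' detectFileType("sample.fastq.gz")
#' detectFileType("notes.xyz")
#' @export
detectFileType <- function(path) {
    stopifnot(is.character(path), length(path) == 1L)
    name <- tolower(basename(path))
    exts <- names(.registry$extensions)
    hit <- exts[vapply(exts, function(e) endsWith(name, e), logical(1))]
    if (length(hit)) {
        best <- hit[which.max(nchar(hit))]
        entry <- .registry$extensions[[best]]
        return(.newCategory(entry$format, entry$compression, best))
    }
    comp <- if (endsWith(name, ".gz")) "GZIP"
            else if (endsWith(name, ".zip")) "ZIP_CONTAINER"
            else "NONE"
    .newCategory("UNKNOWN", comp, "")
}

#' Classify a file's container by magic bytes
#'
#' @param path an existing, readable file.
#' @return one of `"PLAIN"`, `"GZIP"`, `"BGZF"`, `"ZIP"`, `"EMPTY"`. BGZF is
#'   reported when the gzip header's extra field contains the `BC` subfield
#'   of the blocked-gzip format.
#' @export
sniffContainer <- function(path) {
    size <- file.size(path)
    if (is.na(size)) stop("cannot stat file: ", path)
    if (size == 0) return("EMPTY")
    con <- file(path, "rb")
    on.exit(close(con))
    head <- readBin(con, "raw", n = 18L)
    if (length(head) >= 4L && head[1] == as.raw(0x50) && head[2] == as.raw(0x4b) &&
        (head[3] == as.raw(0x03) || head[3] == as.raw(0x05)) &&
        (head[4] == as.raw(0x04) || head[4] == as.raw(0x06)))
        return("ZIP")
    if (length(head) >= 2L && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)) {
        if (.hasBgzfExtra(head, con)) return("BGZF")
        return("GZIP")
    }
    "PLAIN"
}

## TRUE when the first gzip member's FEXTRA field contains the 'BC' subfield.
## `head` holds the first 18 bytes; `con` is positioned right after them.
.hasBgzfExtra <- function(head, con) {
    if (length(head) < 12L) return(FALSE)
    flg <- as.integer(head[4])
    if (!bitwAnd(flg, 4L)) return(FALSE)                 # no FEXTRA
    xlen <- as.integer(head[11]) + 256L * as.integer(head[12])
    extra <- head[13:min(length(head), 12L + xlen)]
    if (length(extra) < xlen)
        extra <- c(extra, readBin(con, "raw", n = xlen - length(extra)))
    i <- 1L
    while (i + 3L <= length(extra)) {
        slen <- as.integer(extra[i + 2L]) + 256L * as.integer(extra[i + 3L])
        if (extra[i] == as.raw(0x42) && extra[i + 1L] == as.raw(0x43) &&
            slen == 2L)
            return(TRUE)
        i <- i + 4L + slen
    }
    FALSE
}

#' Locate checksum sidecars and index companions of a file
#'
#' Looks for `<path>.md5` and `<path>.sha512` checksum sidecars and, by
#' format, for index companions: `<path>.bai` / `<stem>.bai` / `<path>.csi`
#' for BAM, `<path>.crai` for CRAM, `<path>.tbi` / `<path>.csi` for
#' BGZF-compressed VCF. Only companions that exist are returned; absence is
#' a valid empty result.
#'
#' @param path an existing file.
#' @param category its [FileCategory]; defaults to [detectFileType()].
#' @return a [CompanionSet].
#' @export
locateCompanions <- function(path, category = detectFileType(path)) {
    algs <- c("md5", "sha512")
    side <- paste0(path, ".", algs)
    keep <- file.exists(side)
    sidecars <- data.frame(algorithm = algs[keep], path = side[keep],
                           stringsAsFactors = FALSE)

    candidates <- character()
    fmt <- category@format
    if (identical(fmt, "BAM"))
        candidates <- c(paste0(path, ".bai"),
                        paste0(sub("\\.bam$", "", path, ignore.case = TRUE),
                               ".bai"),
                        paste0(path, ".csi"))
    else if (identical(fmt, "CRAM"))
        candidates <- paste0(path, ".crai")
    else if (identical(fmt, "VCF") && category@compression != "NONE")
        candidates <- c(paste0(path, ".tbi"), paste0(path, ".csi"))
    indices <- unique(candidates[file.exists(candidates)])
    .newCompanionSet(sidecars, indices)
}
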