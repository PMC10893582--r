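## FASTQ grammar validation (plain or gzip), per the de-facto 4-line record
## standard:
##   line 1  "@" + non-empty identifier
##   line 2  non-empty sequence over IUPAC nucleotide codes
##   line 3  "+", optionally repeating the identifier exactly
##   line 4  quality, same length as line 2, characters in ASCII 33-126

.IUPAC_RE <- "^[ACGTURYSWKMBDHVNacgturyswkmbdhvn]+$"
.QUAL_RE  <- "^[\x21-\x7e]+$"

#' Validate a FASTQ file
#'
#' Streams the (possibly gzip-compressed) content and enforces the 4-line
#' record grammar. The total line count must be a multiple of 4 and at least
#' one record is required. Quick mode validates only the first 4 records
#' plus the line-count rule; thorough mode validates every record. The "+"
#' separator, when longer than a bare "+", must repeat the identifier — the
#' strict reading, which catches shuffled-record corruption the lenient one
#' misses. CRLF endings are tolerated and the final newline is optional.
#'
#' @param path an existing FASTQ file (plain or gzip).
#' @param category its [FileCategory]; defaults to [detectFileType()].
#' @param thorough validate every record instead of the first 4.
#' @return list with `check` (a `FORMAT_OK` [CheckResult]) and `stats`
#'   (`recordCount`, `firstBadLine` — `NA` when the file passes). Failures
#'   cite the 1-based line number.
#' @export
validateFastq <- function(path, category = detectFileType(path),
                          thorough = FALSE) {
    fail <- function(line, why) list(
        check = CheckResult("FORMAT_OK", FALSE,
                            sprintf("%s at line %d", why, line)),
        stats = list(recordCount = 0L, firstBadLine = line))

    got <- .readLogicalLines(path, category)
    if (!got$ok)
        return(list(check = CheckResult("FORMAT_OK", FALSE, sprintf(
                        "decompression failed mid-stream: %s at byte offset %.0f",
                        got$error, got$error_offset)),
                    stats = list(recordCount = 0L, firstBadLine = NA_integer_)))
    lines <- got$lines
    n <- length(lines)
    n_complete <- n %/% 4L
    if (n == 0L || n_complete == 0L)
        return(fail(1L, "no complete FASTQ record"))

    n_check <- if (thorough) n_complete else min(n_complete, 4L)
    for (k in seq_len(n_check)) {
        base <- 4L * (k - 1L)
        hdr <- lines[base + 1L]; seq <- lines[base + 2L]
        sep <- lines[base + 3L]; qual <- lines[base + 4L]
        if (!startsWith(hdr, "@") || nchar(hdr) < 2L)
            return(fail(base + 1L,
                        "record header must start with '@' and an identifier"))
        if (!grepl(.IUPAC_RE, seq))
            return(fail(base + 2L,
                        if (nzchar(seq)) "sequence contains non-IUPAC characters"
                        else "empty sequence line"))
        if (!startsWith(sep, "+"))
            return(fail(base + 3L, "separator line must start with '+'"))
        if (nchar(sep) > 1L && !identical(substring(sep, 2L),
                                          substring(hdr, 2L)))
            return(fail(base + 3L,
                        "separator text does not repeat the identifier"))
        if (nchar(qual) != nchar(seq))
            return(fail(base + 4L, sprintf(
                "quality length %d != sequence length %d",
                nchar(qual), nchar(seq))))
        if (nzchar(qual) && !grepl(.QUAL_RE, qual))
            return(fail(base + 4L,
                        "quality contains characters outside ASCII 33-126"))
    }
    if (n %% 4L != 0L)
        return(fail(4L * n_complete + 1L, sprintf(
            "line count %d not a multiple of 4; incomplete record", n)))

    list(check = CheckResult("FORMAT_OK", TRUE),
         stats = list(recordCount = n_complete, firstBadLine = NA_integer_))
}
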