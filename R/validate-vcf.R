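## VCF grammar validation (plain or BGZF-compressed): header structure and
## per-record field syntax. Deliberately grammar-only — no semantic
## cross-checks (contig declarations, ALT != REF), no INFO/FORMAT typing.

.VCF_COLS <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
.REF_RE  <- "^[ACGTNacgtn]+$"
.QUAL_NUM_RE <- "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"

.checkVcfAlt <- function(alt) {
    if (alt == ".") return(TRUE)
    parts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    if (!length(parts)) return(FALSE)
    all(vapply(parts, function(a) {
        nzchar(a) && (grepl(.REF_RE, a) || grepl("^<[^<>]+>$", a) ||
                      grepl("\\[|\\]", a) || identical(a, "*"))
    }, logical(1)))
}

.checkVcfRecord <- function(fields, column_count, n_samples) {
    if (length(fields) != column_count)
        return(sprintf("%d fields where the header declares %d columns",
                       length(fields), column_count))
    if (!nzchar(fields[1]) || grepl("[ \t]", fields[1]))
        return("CHROM empty or contains whitespace")
    if (!grepl("^[0-9]+$", fields[2]) || as.numeric(fields[2]) < 1)
        return(sprintf("POS '%s' not a positive integer", fields[2]))
    if (!grepl(.REF_RE, fields[4]))
        return(sprintf("REF '%s' not a sequence over A,C,G,T,N", fields[4]))
    if (!.checkVcfAlt(fields[5]))
        return(sprintf("malformed ALT '%s'", fields[5]))
    if (fields[6] != "." && !grepl(.QUAL_NUM_RE, fields[6]))
        return(sprintf("QUAL '%s' not '.' or a non-negative number",
                       fields[6]))
    if (!nzchar(fields[7]))
        return("FILTER is empty")
    if (fields[8] != ".") {
        toks <- strsplit(fields[8], ";", fixed = TRUE)[[1]]
        if (!length(toks) ||
            !all(grepl("^[^;=[:space:]]+(=[^;]*)?$", toks)))
            return(sprintf("malformed INFO '%s'", fields[8]))
    }
    if (n_samples > 0L) {
        fmt_keys <- strsplit(fields[9], ":", fixed = TRUE)[[1]]
        if (!length(fmt_keys) || !all(nzchar(fmt_keys)))
            return("malformed FORMAT field")
        if ("GT" %in% fmt_keys && fmt_keys[1] != "GT")
            return("GT present in FORMAT but not first")
        for (s in seq_len(n_samples)) {
            sv <- fields[9L + s]
            if (length(strsplit(sv, ":", fixed = TRUE)[[1]]) >
                length(fmt_keys))
                return(sprintf("sample %d carries more fields than FORMAT",
                               s))
        }
    }
    NULL
}

#' Validate a VCF file
#'
#' Line 1 must be `##fileformat=VCFv<number>` (any 4.x accepted; other
#' versions pass with a note), all `##` meta lines must contain `=`, and
#' exactly one `#CHROM` line — after all meta lines — must carry the eight
#' fixed columns, optionally followed by `FORMAT` and at least one unique
#' sample name. Records must match the header's column count with a
#' positive-integer `POS`, `REF` over `A,C,G,T,N`, well-formed `ALT`
#' alleles (sequence, symbolic `<ID>`, breakend, or `*`), numeric-or-`.`
#' `QUAL`, non-empty `FILTER`, well-formed `INFO` tokens and sample fields
#' no longer than `FORMAT` (with `GT`, if present, first). A header-only
#' file passes with a note by default and fails under `strict`. Quick mode
#' checks the header plus the first 4 records. Failures cite line numbers.
#'
#' @param path an existing VCF file (plain or BGZF).
#' @param category its [FileCategory]; defaults to [detectFileType()].
#' @param thorough validate every record.
#' @param strict require at least one record.
#' @return list with `check` (a `FORMAT_OK` [CheckResult]) and `info`
#'   (`fileformat`, `columnCount`, `sampleNames`, `recordCount`).
#' @export
validateVcf <- function(path, category = detectFileType(path),
                        thorough = FALSE, strict = FALSE) {
    info <- list(fileformat = NA_character_, columnCount = NA_integer_,
                 sampleNames = character(), recordCount = 0L)
    fail <- function(line, why) list(
        check = CheckResult("FORMAT_OK", FALSE,
                            sprintf("%s at line %d", why, line)),
        info = info)

    got <- .readLogicalLines(path, category)
    if (!got$ok)
        return(list(check = CheckResult("FORMAT_OK", FALSE, sprintf(
                        "decompression failed mid-stream: %s at byte offset %.0f",
                        got$error, got$error_offset)),
                    info = info))
    lines <- got$lines
    if (!length(lines)) return(fail(1L, "empty file"))

    if (!grepl("^##fileformat=VCFv[0-9]", lines[1]))
        return(fail(1L, "missing fileformat declaration"))
    info$fileformat <- sub("^##fileformat=", "", lines[1])
    version_note <- if (!grepl("^##fileformat=VCFv4\\.", lines[1]))
        sprintf("unusual VCF version '%s'", info$fileformat) else ""

    chrom_line <- NA_integer_
    i <- 2L
    n <- length(lines)
    while (i <= n) {
        ln <- lines[[i]]
        if (startsWith(ln, "##")) {
            if (!is.na(chrom_line))
                return(fail(i, "meta line after the #CHROM header"))
            if (!grepl("=", ln, fixed = TRUE))
                return(fail(i, "meta line lacks '='"))
        } else if (startsWith(ln, "#CHROM")) {
            if (!is.na(chrom_line))
                return(fail(i, "duplicate #CHROM line"))
            chrom_line <- i
        } else if (startsWith(ln, "#")) {
            return(fail(i, "malformed header line"))
        } else if (is.na(chrom_line)) {
            return(fail(i, "data line before the #CHROM header"))
        }
        i <- i + 1L
    }
    if (is.na(chrom_line))
        return(fail(n, "no #CHROM header line"))

    cols <- strsplit(lines[[chrom_line]], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 8L || !identical(cols[1:8], .VCF_COLS))
        return(fail(chrom_line,
                    "#CHROM line does not start with the 8 fixed columns"))
    if (length(cols) == 9L)
        return(fail(chrom_line, "FORMAT column without sample columns"))
    if (length(cols) > 9L) {
        if (!identical(cols[9], "FORMAT"))
            return(fail(chrom_line, "column 9 must be FORMAT"))
        samples <- cols[-(1:9)]
        if (anyDuplicated(samples))
            return(fail(chrom_line, "duplicate sample names"))
        info$sampleNames <- samples
    }
    info$columnCount <- length(cols)

    rec_idx <- which(seq_len(n) > chrom_line & nzchar(lines))
    info$recordCount <- length(rec_idx)
    if (!length(rec_idx)) {
        if (strict) return(fail(n, "no variant records"))
        return(list(check = CheckResult("FORMAT_OK", TRUE,
                        trimws(paste("header-only VCF (no records)",
                                     version_note))),
                    info = info))
    }
    take <- if (thorough) rec_idx else head(rec_idx, 4L)
    for (ri in take) {
        fields <- strsplit(lines[[ri]], "\t", fixed = TRUE)[[1]]
        why <- .checkVcfRecord(fields, length(cols),
                               length(info$sampleNames))
        if (!is.null(why)) return(fail(ri, why))
    }
    list(check = CheckResult("FORMAT_OK", TRUE, version_note), info = info)
}
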