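## Alignment-format validators: SAM text grammar, BAM binary container,
## CRAM container signature/EOF, and index companionship.

## 38-byte CRAM v3 end-of-file container (byte-exact constant, as written
## by htslib-family tools).
.CRAM_EOF <- as.raw(c(
    0x0f, 0x00, 0x00, 0x00, 0xff, 0xff, 0xff, 0xff, 0x0f, 0xe0,
    0x45, 0x4f, 0x46, 0x00, 0x00, 0x00, 0x00, 0x01, 0x00, 0x05,
    0xbd, 0xd9, 0x4f, 0x00, 0x01, 0x00, 0x06, 0x06, 0x01, 0x00,
    0x01, 0x00, 0x01, 0x00, 0xee, 0x63, 0x01, 0x4b))

## Shared SAM text-header validation. `lines` are the header lines (leading
## "@"), numbered from `first_line` for error reporting. Returns
## list(ok, line, why, info) where info = list(hasHd, hdVersion, refs).
.checkSamHeader <- function(lines, first_line = 1L) {
    info <- list(hasHd = FALSE, hdVersion = NA_character_,
                 refs = data.frame(name = character(), length = numeric(),
                                   stringsAsFactors = FALSE))
    bad <- function(i, why) list(ok = FALSE, line = first_line + i - 1L,
                                 why = why, info = info)
    seen_sn <- character()
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        tag <- substring(ln, 1L, 3L)
        if (!tag %in% c("@HD", "@SQ", "@RG", "@PG", "@CO"))
            return(bad(i, sprintf("unrecognized header record '%s'", tag)))
        if (tag == "@CO") next
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
        kv <- sub(":.*$", "", fields)
        val <- sub("^[^:]*:", "", fields)
        if (tag == "@HD") {
            if (i != 1L)
                return(bad(i, "@HD must be the first line"))
            if (!"VN" %in% kv)
                return(bad(i, "@HD lacks the VN tag"))
            info$hasHd <- TRUE
            info$hdVersion <- val[match("VN", kv)]
        } else if (tag == "@SQ") {
            if (!all(c("SN", "LN") %in% kv))
                return(bad(i, "@SQ lacks SN or LN"))
            sn <- val[match("SN", kv)]
            lnv <- suppressWarnings(as.numeric(val[match("LN", kv)]))
            if (is.na(lnv) || lnv < 1 || lnv != floor(lnv))
                return(bad(i, sprintf("@SQ LN '%s' is not a positive integer",
                                      val[match("LN", kv)])))
            if (sn %in% seen_sn)
                return(bad(i, sprintf("duplicate @SQ SN '%s'", sn)))
            seen_sn <- c(seen_sn, sn)
            info$refs <- rbind(info$refs, data.frame(
                name = sn, length = lnv, stringsAsFactors = FALSE))
        }
    }
    list(ok = TRUE, line = NA_integer_, why = "", info = info)
}

## Validate one SAM alignment line (already split into fields).
.checkSamRecord <- function(fields, ref_names, have_sq) {
    if (length(fields) < 11L)
        return(sprintf("alignment line has %d fields; 11 required",
                       length(fields)))
    flag <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(flag) || flag != floor(flag) || flag < 0 || flag > 65535)
        return(sprintf("FLAG '%s' not an integer in [0, 65535]", fields[2]))
    if (have_sq && fields[3] != "*" && !fields[3] %in% ref_names)
        return(sprintf("RNAME '%s' not declared in any @SQ", fields[3]))
    pos <- suppressWarnings(as.numeric(fields[4]))
    if (is.na(pos) || pos != floor(pos) || pos < 0 || pos > 2^31 - 1)
        return(sprintf("POS '%s' not an integer in [0, 2^31-1]", fields[4]))
    mapq <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(mapq) || mapq != floor(mapq) || mapq < 0 || mapq > 255)
        return(sprintf("MAPQ '%s' not an integer in [0, 255]", fields[5]))
    if (fields[10] != "*" && fields[11] != "*" &&
        nchar(fields[10]) != nchar(fields[11]))
        return(sprintf("SEQ length %d != QUAL length %d",
                       nchar(fields[10]), nchar(fields[11])))
    NULL
}

#' Validate a SAM file
#'
#' Header lines (leading `@`) must precede all alignment lines; `@HD`, when
#' present, must be line 1 and carry `VN`; every `@SQ` needs `SN` and a
#' positive-integer `LN`, with no duplicate `SN`. Alignment lines need at
#' least 11 tab-separated fields with `FLAG` in \[0, 65535\], `POS` in
#' \[0, 2^31-1\], `MAPQ` in \[0, 255\], matching `SEQ`/`QUAL` lengths when
#' both are given, and an `RNAME` that is `*` or declared in some `@SQ`
#' (when any exists). At least one alignment line is required. Quick mode
#' checks the header plus the first 4 alignment lines.
#'
#' @param path an existing SAM file.
#' @param thorough validate every alignment line.
#' @return list with `check` (a `FORMAT_OK` [CheckResult]) and `info`
#'   (`hasHd`, `hdVersion`, `referenceSequences`, `readSeen`,
#'   `recordCount`).
#' @export
validateSam <- function(path, thorough = FALSE) {
    lines <- .bytesToLines(readBin(path, "raw", n = file.size(path)))
    is_hdr <- startsWith(lines, "@")
    info <- list(hasHd = FALSE, hdVersion = NA_character_,
                 referenceSequences = data.frame(name = character(),
                                                 length = numeric()),
                 readSeen = FALSE, recordCount = 0L)
    fail <- function(line, why) list(
        check = CheckResult("FORMAT_OK", FALSE,
                            sprintf("%s at line %d", why, line)),
        info = info)

    first_aln <- match(FALSE, is_hdr)
    if (!is.na(first_aln) && any(is_hdr[seq_along(is_hdr) > first_aln]))
        return(fail(which(is_hdr & seq_along(is_hdr) > first_aln)[1],
                    "header line after alignment records"))

    hdr <- .checkSamHeader(lines[is_hdr], first_line = 1L)
    info$hasHd <- hdr$info$hasHd
    info$hdVersion <- hdr$info$hdVersion
    info$referenceSequences <- hdr$info$refs
    if (!hdr$ok) return(fail(hdr$line, hdr$why))

    aln <- which(!is_hdr)
    aln <- aln[nzchar(lines[aln])]
    if (!length(aln))
        return(fail(length(lines), "no reads"))
    info$readSeen <- TRUE
    info$recordCount <- length(aln)

    take <- if (thorough) aln else head(aln, 4L)
    ref_names <- hdr$info$refs$name
    for (i in take) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        why <- .checkSamRecord(fields, ref_names, length(ref_names) > 0L)
        if (!is.null(why)) return(fail(i, why))
    }
    list(check = CheckResult("FORMAT_OK", TRUE), info = info)
}

## ---- BAM ----

## Little-endian cursor over a raw vector.
.rawCursor <- function(data) {
    env <- new.env(parent = emptyenv())
    env$data <- data; env$pos <- 0
    env
}
.curRemaining <- function(cur) length(cur$data) - cur$pos
.curTake <- function(cur, n) {
    if (.curRemaining(cur) < n) stop("cursor overrun")
    out <- cur$data[(cur$pos + 1):(cur$pos + n)]
    cur$pos <- cur$pos + n
    out
}
.curI32 <- function(cur) {
    b <- as.numeric(.curTake(cur, 4L))
    v <- b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
    if (v >= 2^31) v - 2^32 else v
}
.curU32 <- function(cur) {
    b <- as.numeric(.curTake(cur, 4L))
    b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}
.curU16 <- function(cur) { b <- as.numeric(.curTake(cur, 2L)); b[1] + 256 * b[2] }
.curU8 <- function(cur) as.numeric(.curTake(cur, 1L))

#' Validate a BAM file
#'
#' The inflated BGZF stream must begin with the magic `BAM\x01`, followed by
#' the SAM text header (validated with the SAM header rules), the binary
#' reference directory (`n_ref`, NUL-terminated names, positive lengths; the
#' count must agree with the text header's `@SQ` lines when the text header
#' has any), and at least one decodable alignment record with a non-empty
#' read name — the operational meaning of "contains sequence data". Thorough
#' mode walks every record, requiring the `block_size` chain to land exactly
#' on the end of the data.
#'
#' @param path an existing BAM file (BGZF container verified separately by
#'   [checkCompression()]).
#' @param thorough walk every alignment record.
#' @return list with `check` (a `FORMAT_OK` [CheckResult]) and `info`
#'   (`hasHd`, `hdVersion`, `referenceSequences`, `readSeen`,
#'   `recordCount` — records actually walked, `structuralOk`).
#' @export
validateBam <- function(path, thorough = FALSE) {
    info <- list(hasHd = FALSE, hdVersion = NA_character_,
                 referenceSequences = data.frame(name = character(),
                                                 length = numeric()),
                 readSeen = FALSE, recordCount = 0L, structuralOk = FALSE)
    fail <- function(why) list(check = CheckResult("FORMAT_OK", FALSE, why),
                               info = info)

    got <- .readLogicalBytes(path, detectFileType(path))
    if (!got$ok)
        return(fail(sprintf("BGZF decompression failed: %s at byte offset %.0f",
                            got$error, got$error_offset)))
    cur <- .rawCursor(got$data)
    if (.curRemaining(cur) < 4L ||
        !identical(.curTake(cur, 4L), c(charToRaw("BAM"), as.raw(1L))))
        return(fail("bad BAM magic"))

    if (.curRemaining(cur) < 4L) return(fail("truncated BAM header"))
    l_text <- .curI32(cur)
    if (l_text < 0 || .curRemaining(cur) < l_text)
        return(fail("SAM header text overruns data"))
    text <- .curTake(cur, l_text)
    text <- text[text != as.raw(0L)]
    hdr_lines <- .bytesToLines(text)
    hdr_lines <- hdr_lines[nzchar(hdr_lines)]
    hdr <- .checkSamHeader(hdr_lines)
    info$hasHd <- hdr$info$hasHd
    info$hdVersion <- hdr$info$hdVersion
    if (!hdr$ok)
        return(fail(sprintf("malformed SAM header text: %s (header line %d)",
                            hdr$why, hdr$line)))

    if (.curRemaining(cur) < 4L) return(fail("truncated reference directory"))
    n_ref <- .curI32(cur)
    if (n_ref < 0) return(fail("negative n_ref"))
    refs <- data.frame(name = character(), length = numeric(),
                       stringsAsFactors = FALSE)
    for (i in seq_len(n_ref)) {
        if (.curRemaining(cur) < 4L)
            return(fail(sprintf("truncated reference record %d", i)))
        l_name <- .curI32(cur)
        if (l_name < 1L || .curRemaining(cur) < l_name + 4L)
            return(fail(sprintf("reference record %d has invalid name length",
                                i)))
        nm <- .curTake(cur, l_name)
        if (nm[l_name] != as.raw(0L))
            return(fail(sprintf("reference name %d not NUL-terminated", i)))
        l_ref <- .curI32(cur)
        if (l_ref < 1)
            return(fail(sprintf("reference %d has non-positive length", i)))
        refs <- rbind(refs, data.frame(
            name = rawToChar(nm[-l_name]), length = l_ref,
            stringsAsFactors = FALSE))
    }
    info$referenceSequences <- refs
    n_sq <- nrow(hdr$info$refs)
    if (n_sq > 0L && n_sq != n_ref)
        return(fail(sprintf(
            "reference count mismatch: %d binary references vs %d @SQ lines",
            n_ref, n_sq)))

    ## alignment records
    n_rec <- 0L
    repeat {
        if (.curRemaining(cur) == 0) break
        rec_off <- cur$pos
        if (.curRemaining(cur) < 4L)
            return(fail(sprintf("record overruns data at offset %.0f",
                                rec_off)))
        block_size <- .curI32(cur)
        if (block_size < 32L || block_size > .curRemaining(cur))
            return(fail(sprintf("record overruns data at offset %.0f",
                                rec_off)))
        body <- .rawCursor(.curTake(cur, block_size))
        refID <- .curI32(body)
        pos <- .curI32(body)
        l_read_name <- .curU8(body)
        if (refID < -1 || refID >= n_ref)
            return(fail(sprintf("record %d refID %d outside [-1, %d)",
                                n_rec + 1L, refID, n_ref)))
        if (pos < -1)
            return(fail(sprintf("record %d position %d < -1", n_rec + 1L,
                                pos)))
        if (l_read_name < 1L)
            return(fail(sprintf("record %d has empty read name", n_rec + 1L)))
        ## read name sits after mapq/bin/n_cigar/flag/l_seq/next*/tlen (28
        ## fixed bytes in all); require it to be present and non-empty
        if (block_size < 32L + l_read_name - 1L)
            return(fail(sprintf("record %d read name overruns record",
                                n_rec + 1L)))
        n_rec <- n_rec + 1L
        if (!thorough && n_rec >= 4L) { info$structuralOk <- TRUE; break }
    }
    info$recordCount <- n_rec
    info$structuralOk <- TRUE
    if (n_rec == 0L) return(fail("no reads"))
    info$readSeen <- TRUE
    list(check = CheckResult("FORMAT_OK", TRUE), info = info)
}

#' Validate a CRAM file at the container level
#'
#' Requires the 4-byte magic `CRAM`, a plausible version (major 1-3), and
#' the byte-exact 38-byte CRAM v3 EOF container terminating the file. Block
#' and codec parsing is out of scope; this is a container-level truncation
#' and identity check.
#'
#' @param path an existing CRAM file.
#' @return a `FORMAT_OK` [CheckResult].
#' @export
validateCram <- function(path) {
    size <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con))
    head <- readBin(con, "raw", n = 6L)
    if (length(head) < 6L || !identical(head[1:4], charToRaw("CRAM")))
        return(CheckResult("FORMAT_OK", FALSE, "bad CRAM magic"))
    major <- as.integer(head[5])
    if (major < 1L || major > 3L)
        return(CheckResult("FORMAT_OK", FALSE, sprintf(
            "implausible CRAM version %d.%d", major, as.integer(head[6]))))
    if (size < 6 + 38)
        return(CheckResult("FORMAT_OK", FALSE, "missing EOF container"))
    seek(con, size - 38)
    if (!identical(readBin(con, "raw", n = 38L), .CRAM_EOF))
        return(CheckResult("FORMAT_OK", FALSE, "missing EOF container"))
    CheckResult("FORMAT_OK", TRUE)
}

#' Check for an alignment/variant index companion
#'
#' A missing index is reported as a warning-severity failure by default — it
#' does not flip the file's verdict — or as a hard failure under `strict`.
#' In thorough mode the index's own magic bytes are verified (`BAI\x01`,
#' `CSI\x01`, or a gzip container for `.tbi`/`.crai`).
#'
#' @param path the indexed file.
#' @param companions its [CompanionSet]; defaults to [locateCompanions()].
#' @param thorough verify index magic bytes.
#' @param strict missing index fails the file instead of warning.
#' @return an `INDEX_PRESENT` [CheckResult].
#' @export
checkAlignmentIndex <- function(path, companions = locateCompanions(path),
                                thorough = FALSE, strict = FALSE) {
    idx <- companions@indexFiles
    if (!length(idx))
        return(CheckResult("INDEX_PRESENT", FALSE,
                           sprintf("no index found for %s", path),
                           warning = !strict))
    if (thorough) {
        for (ix in idx) {
            magic <- readBin(ix, "raw", n = 4L)
            ok <- if (grepl("\\.bai$", ix, ignore.case = TRUE))
                identical(magic, c(charToRaw("BAI"), as.raw(1L)))
            else if (grepl("\\.csi$", ix, ignore.case = TRUE))
                identical(magic, c(charToRaw("CSI"), as.raw(1L)))
            else  # .crai / .tbi are gzip containers
                length(magic) >= 2L && magic[1] == as.raw(0x1f) &&
                    magic[2] == as.raw(0x8b)
            if (!isTRUE(ok))
                return(CheckResult("INDEX_PRESENT", FALSE,
                                   sprintf("index %s has bad magic bytes",
                                           ix),
                                   warning = !strict))
        }
    }
    CheckResult("INDEX_PRESENT", TRUE, paste(idx, collapse = ", "))
}
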