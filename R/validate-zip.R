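## ZIP archives: structural validation against the PKZIP layout (local
## headers, central directory, EOCD) and a deterministic writer used by the
## fixture generator. Thorough mode inflates each entry and compares its
## CRC32 to the central-directory value.

.SIG_LOCAL <- as.raw(c(0x50, 0x4b, 0x03, 0x04))
.SIG_CDIR  <- as.raw(c(0x50, 0x4b, 0x01, 0x02))
.SIG_EOCD  <- as.raw(c(0x50, 0x4b, 0x05, 0x06))
.SIG_EOCD64 <- as.raw(c(0x50, 0x4b, 0x06, 0x06))

## Locate the EOCD record: scan the final 65 KiB + 22 bytes for its
## signature, last occurrence wins (comments may contain the bytes).
.findEocd <- function(data) {
    n <- length(data)
    lo <- max(1L, n - 65557L + 1L)
    win <- data[lo:n]
    hits <- which(win[-(length(win) - (0:2))] == .SIG_EOCD[1])
    hits <- hits[win[hits + 1L] == .SIG_EOCD[2] &
                 win[hits + 2L] == .SIG_EOCD[3] &
                 win[hits + 3L] == .SIG_EOCD[4]]
    hits <- hits[hits + 21L <= length(win)]
    if (!length(hits)) return(NA_integer_)
    lo + hits[length(hits)] - 1L            # 1-based offset in data
}

## Parse central directory entries starting at 1-based offset `at`.
## Returns list of entries or a character error message.
.readCentralDirectory <- function(data, at, n_entries) {
    entries <- vector("list", n_entries)
    for (k in seq_len(n_entries)) {
        if (at + 45L > length(data) ||
            !identical(data[at:(at + 3L)], .SIG_CDIR))
            return(sprintf("central directory entry %d missing or malformed",
                           k))
        flags  <- .rdU16(data, at + 8L)
        method <- .rdU16(data, at + 10L)
        crc    <- .rdU32(data, at + 16L)
        csize  <- .rdU32(data, at + 20L)
        usize  <- .rdU32(data, at + 24L)
        nlen   <- .rdU16(data, at + 28L)
        xlen   <- .rdU16(data, at + 30L)
        clen   <- .rdU16(data, at + 32L)
        lofs   <- .rdU32(data, at + 42L)
        if (at + 45L + nlen > length(data))
            return(sprintf("entry %d name overruns file", k))
        name <- rawToChar(data[(at + 46L):(at + 45L + nlen)])
        entries[[k]] <- list(name = name, flags = flags, method = method,
                             crc = crc, csize = csize, usize = usize,
                             local_offset = lofs)
        at <- at + 46L + nlen + xlen + clen
    }
    entries
}

#' Validate a ZIP archive
#'
#' Quick mode locates the End-Of-Central-Directory record in the final
#' 65 KiB + 22 bytes and walks the central directory, requiring the
#' enumerable entry count to match the EOCD's. Thorough mode additionally
#' decompresses every entry (stored or deflate) and compares its CRC32 to
#' the central-directory value; the first mismatch fails with the entry
#' name. ZIP64 archives are accepted in quick mode when an EOCD64 record is
#' locatable, but thorough CRC walking of ZIP64 is flagged unsupported;
#' encrypted entries fail thorough validation.
#'
#' @param path an existing ZIP file.
#' @param thorough per-entry CRC verification.
#' @return a `FORMAT_OK` [CheckResult].
#' @export
validateZip <- function(path, thorough = FALSE) {
    data <- readBin(path, "raw", n = file.size(path))
    fail <- function(why) CheckResult("FORMAT_OK", FALSE, why)

    eocd <- .findEocd(data)
    if (is.na(eocd))
        return(fail("cannot locate end of central directory"))
    n_entries <- .rdU16(data, eocd + 10L)
    cd_size   <- .rdU32(data, eocd + 12L)
    cd_offset <- .rdU32(data, eocd + 16L)

    zip64 <- n_entries == 0xFFFF || cd_offset == 0xFFFFFFFF
    if (zip64) {
        has64 <- any(vapply(seq_len(max(0L, length(data) - 3L)), function(i)
            identical(data[i:(i + 3L)], .SIG_EOCD64), logical(1)))
        if (!has64) return(fail("ZIP64 markers present but no EOCD64 record"))
        if (thorough)
            return(CheckResult("FORMAT_OK", FALSE,
                               "ZIP64 thorough validation unsupported",
                               warning = TRUE))
        return(CheckResult("FORMAT_OK", TRUE, "ZIP64 archive"))
    }

    entries <- .readCentralDirectory(data, cd_offset + 1L, n_entries)
    if (is.character(entries)) return(fail(entries))

    if (!thorough) return(CheckResult("FORMAT_OK", TRUE))

    for (e in entries) {
        if (bitwAnd(e$flags, 1L))
            return(fail(sprintf("encrypted entry unsupported: %s", e$name)))
        at <- e$local_offset + 1L
        if (at + 29L > length(data) ||
            !identical(data[at:(at + 3L)], .SIG_LOCAL))
            return(fail(sprintf("entry %s: bad local header", e$name)))
        nlen <- .rdU16(data, at + 26L)
        xlen <- .rdU16(data, at + 28L)
        dstart <- at + 30L + nlen + xlen
        if (dstart + e$csize - 1L > length(data))
            return(fail(sprintf("entry %s: data overruns file", e$name)))
        cdata <- if (e$csize > 0) data[dstart:(dstart + e$csize - 1L)]
                 else raw()
        content <- if (e$method == 0L) {
            cdata
        } else if (e$method == 8L) {
            inf <- .inflateRaw(cdata)
            if (!isTRUE(inf$ok))
                return(fail(sprintf("entry %s: %s", e$name, inf$error)))
            inf$data
        } else {
            return(fail(sprintf("entry %s: unsupported compression method %d",
                                e$name, e$method)))
        }
        if (length(content) != e$usize)
            return(fail(sprintf(
                "entry %s: inflated size %d != declared %.0f", e$name,
                length(content), e$usize)))
        if (.crc32Raw(content) != e$crc)
            return(fail(sprintf("entry %s: CRC32 mismatch", e$name)))
    }
    CheckResult("FORMAT_OK", TRUE)
}

#' Write a ZIP archive deterministically
#'
#' Deflate-compressed entries, zeroed DOS timestamps, entries in the given
#' order: identical input always yields identical bytes. Used by the fixture
#' generator; not a general-purpose archiver.
#'
#' @param entries named list of raw vectors (names become entry names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeZip <- function(entries, path) {
    stopifnot(is.list(entries), length(names(entries)) == length(entries))
    locals <- list()
    centrals <- list()
    offset <- 0
    for (nm in names(entries)) {
        content <- entries[[nm]]
        stopifnot(is.raw(content))
        cdata <- .deflateRaw(content, 6L)
        crc <- .crc32Raw(content)
        name_raw <- charToRaw(nm)
        local <- c(.SIG_LOCAL, .u16le(20L), .u16le(0L), .u16le(8L),
                   .u16le(0L), .u16le(0L), .u32le(crc),
                   .u32le(length(cdata)), .u32le(length(content)),
                   .u16le(length(name_raw)), .u16le(0L), name_raw, cdata)
        central <- c(.SIG_CDIR, .u16le(20L), .u16le(20L), .u16le(0L),
                     .u16le(8L), .u16le(0L), .u16le(0L), .u32le(crc),
                     .u32le(length(cdata)), .u32le(length(content)),
                     .u16le(length(name_raw)), .u16le(0L), .u16le(0L),
                     .u16le(0L), .u16le(0L), .u32le(0L), .u32le(offset),
                     name_raw)
        locals[[length(locals) + 1L]] <- local
        centrals[[length(centrals) + 1L]] <- central
        offset <- offset + length(local)
    }
    cd <- do.call(c, c(list(raw()), centrals))
    eocd <- c(.SIG_EOCD, .u16le(0L), .u16le(0L), .u16le(length(entries)),
              .u16le(length(entries)), .u32le(length(cd)), .u32le(offset),
              .u16le(0L))
    writeBin(c(do.call(c, c(list(raw()), locals)), cd, eocd), path)
    invisible(path)
}
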