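## gzip and BGZF containers: deterministic writers (fixed mtime/OS bytes)
## built on the zlib primitives in src/, plus BGZF block-chain walking used
## by the thorough compression check.

## 28-byte BGZF end-of-file marker: an empty block, byte-exact.
.BGZF_EOF <- as.raw(c(
    0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
    0x06, 0x00, 0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00,
    0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))

.u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256,
                               (x %/% 16777216) %% 256))

## little-endian readers over a raw vector (1-based offset of first byte)
.rdU16 <- function(x, at) as.integer(x[at]) + 256 * as.integer(x[at + 1L])
.rdU32 <- function(x, at) {
    as.numeric(x[at]) + 256 * as.numeric(x[at + 1L]) +
        65536 * as.numeric(x[at + 2L]) + 16777216 * as.numeric(x[at + 3L])
}

#' Compress bytes as a single-member gzip stream
#'
#' Deterministic: zero mtime, unknown-OS byte, fixed compression level, so
#' identical input yields identical output bytes.
#'
#' @param data raw vector.
#' @param level zlib compression level.
#' @return raw vector holding a complete gzip member.
#' @export
gzipCompress <- function(data, level = 6L) {
    stopifnot(is.raw(data))
    body <- .deflateRaw(data, as.integer(level))
    c(as.raw(c(0x1f, 0x8b, 0x08, 0x00)), .u32le(0), as.raw(c(0x00, 0xff)),
      body, .u32le(.crc32Raw(data)), .u32le(length(data) %% 2^32))
}

#' Compress bytes as a BGZF (blocked gzip) stream
#'
#' Splits `data` into blocks of at most `blockSize` uncompressed bytes, each
#' an independent gzip member carrying the `BC` extra subfield with the
#' block's compressed size, and appends the fixed 28-byte EOF marker.
#'
#' @param data raw vector.
#' @param blockSize maximum uncompressed bytes per block (BGZF caps the
#'   *compressed* block at 65536 bytes; the default leaves headroom for
#'   incompressible data).
#' @param eof append the EOF marker (disable only to emulate truncation).
#' @return raw vector holding the BGZF stream.
#' @export
bgzfCompress <- function(data, blockSize = 60000L, eof = TRUE) {
    stopifnot(is.raw(data))
    out <- list()
    n <- length(data)
    starts <- if (n == 0L) integer() else seq.int(1L, n, by = blockSize)
    for (s in starts) {
        chunk <- data[s:min(n, s + blockSize - 1L)]
        body <- .deflateRaw(chunk, 6L)
        total <- 12L + 6L + length(body) + 8L
        if (total - 1L > 65535L) stop("BGZF block overflow")
        out[[length(out) + 1L]] <- c(
            as.raw(c(0x1f, 0x8b, 0x08, 0x04)), .u32le(0),
            as.raw(c(0x00, 0xff)), .u16le(6L),
            as.raw(c(0x42, 0x43)), .u16le(2L), .u16le(total - 1L),
            body, .u32le(.crc32Raw(chunk)), .u32le(length(chunk)))
    }
    if (eof) out[[length(out) + 1L]] <- .BGZF_EOF
    do.call(c, c(list(raw()), out))
}

#' @rdname bgzfCompress
#' @param path file to test.
#' @return `bgzfHasEof()`: logical, whether the file ends with the 28-byte
#'   BGZF EOF marker.
#' @export
bgzfHasEof <- function(path) {
    size <- file.size(path)
    if (is.na(size) || size < 28) return(FALSE)
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, size - 28)
    identical(readBin(con, "raw", n = 28L), .BGZF_EOF)
}

## Walk the BGZF block chain using each block's declared BSIZE. Returns
## list(ok, n_blocks, offsets, error, error_offset). Verifies header layout
## and that the final block lands exactly on end-of-file; CRC verification
## of block contents is done separately by the zlib member walk.
.bgzfWalkBlocks <- function(path = NULL, data = NULL) {
    if (is.null(data))
        data <- readBin(path, "raw", n = file.size(path))
    n <- length(data)
    off <- 0
    blocks <- 0L
    offsets <- numeric()
    while (off < n) {
        at <- off + 1
        if (off + 18 > n)
            return(list(ok = FALSE, n_blocks = blocks,
                        offsets = offsets,
                        error = "truncated BGZF block header",
                        error_offset = off))
        if (!(data[at] == as.raw(0x1f) && data[at + 1] == as.raw(0x8b) &&
              data[at + 2] == as.raw(0x08) &&
              bitwAnd(as.integer(data[at + 3]), 4L) == 4L))
            return(list(ok = FALSE, n_blocks = blocks,
                        offsets = offsets,
                        error = "bad BGZF block magic",
                        error_offset = off))
        xlen <- .rdU16(data, at + 10)
        ## scan extra subfields for BC
        bsize <- NA
        i <- at + 12
        xend <- at + 12 + xlen - 1
        while (i + 3 <= xend) {
            slen <- .rdU16(data, i + 2)
            if (data[i] == as.raw(0x42) && data[i + 1] == as.raw(0x43) &&
                slen == 2L) {
                bsize <- .rdU16(data, i + 4)
                break
            }
            i <- i + 4 + slen
        }
        if (is.na(bsize))
            return(list(ok = FALSE, n_blocks = blocks,
                        offsets = offsets,
                        error = "missing BC subfield in BGZF block",
                        error_offset = off))
        total <- bsize + 1
        if (off + total > n)
            return(list(ok = FALSE, n_blocks = blocks,
                        offsets = offsets,
                        error = "BGZF block overruns end of file",
                        error_offset = off))
        offsets <- c(offsets, off)
        off <- off + total
        blocks <- blocks + 1L
    }
    list(ok = TRUE, n_blocks = blocks, offsets = offsets, error = "",
         error_offset = NA_real_)
}

## Read a file's logical content: plain bytes, or the inflated stream when
## the container is gzip/BGZF. Returns list(ok, data, error, error_offset).
.readLogicalBytes <- function(path, category) {
    sniff <- sniffContainer(path)
    if (sniff %in% c("GZIP", "BGZF")) {
        walk <- .gzipWalk(path, TRUE)
        return(list(ok = isTRUE(walk$ok), data = walk$data,
                    error = walk$error, error_offset = walk$error_offset))
    }
    list(ok = TRUE, data = readBin(path, "raw", n = file.size(path)),
         error = "", error_offset = NA_real_)
}

## Split logical bytes into text lines: CRLF tolerated, final newline
## optional, no trailing empty line.
.bytesToLines <- function(data) {
    if (length(data) == 0L) return(character())
    txt <- rawToChar(data)
    Encoding(txt) <- "unknown"
    ## strsplit keeps an unterminated final line and drops the empty piece
    ## after a final newline, which is exactly the framing wanted here
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    sub("\r$", "", lines)
}

## Read a file as text lines through its container.
.readLogicalLines <- function(path, category) {
    res <- .readLogicalBytes(path, category)
    if (!res$ok) return(res)
    list(ok = TRUE, lines = .bytesToLines(res$data), error = "",
         error_offset = NA_real_)
}
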