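## The three universal checks — existence, compression integrity, checksum
## verification — plus checksum sidecar generation.

#' Existence checks for a path
#'
#' Runs `EXISTS`, `READABLE`, `NONEMPTY` in that order and stops after the
#' first failure, so a nonexistent path yields exactly one failed result.
#' Symlinks are followed; a broken symlink counts as nonexistent. All
#' outcomes are expressed as check results, never conditions.
#'
#' @param path a file path.
#' @return list of [CheckResult].
#' @export
checkExistence <- function(path) {
    if (!file.exists(path))
        return(list(CheckResult("EXISTS", FALSE,
                                sprintf("no such file: %s", path))))
    out <- list(CheckResult("EXISTS", TRUE))
    if (dir.exists(path))
        return(c(out, list(CheckResult("READABLE", FALSE,
                                       sprintf("%s is a directory", path)))))
    if (file.access(path, mode = 4L) != 0L)
        return(c(out, list(CheckResult("READABLE", FALSE,
                                       sprintf("permission denied: %s",
                                               path)))))
    out <- c(out, list(CheckResult("READABLE", TRUE)))
    if (isTRUE(file.size(path) == 0))
        return(c(out, list(CheckResult("NONEMPTY", FALSE,
                                       sprintf("file is empty: %s", path)))))
    c(out, list(CheckResult("NONEMPTY", TRUE)))
}

#' Verify a file's compression container
#'
#' Quick mode checks that the magic bytes agree with the compression the
#' extension claims and, for BGZF streams, that the 28-byte EOF marker
#' terminates the file. Thorough mode additionally walks every gzip member /
#' BGZF block, inflates it and verifies each member's CRC32 and ISIZE
#' trailer; truncation or a CRC mismatch fails with the byte offset of the
#' bad block. Uncompressed categories pass with the note "not compressed".
#'
#' BGZF is a valid gzip stream, so a name claiming plain gzip accepts BGZF
#' content; the EOF-marker rule applies whenever the content is BGZF or the
#' extension claims it (BAM).
#'
#' @param path an existing, readable file.
#' @param category its [FileCategory]; defaults to [detectFileType()].
#' @param thorough full-stream CRC walk instead of magic/EOF checks only.
#' @return a single [CheckResult] with id `COMPRESSION_OK`.
#' @export
checkCompression <- function(path, category = detectFileType(path),
                             thorough = FALSE) {
    claimed <- category@compression
    if (identical(claimed, "NONE"))
        return(CheckResult("COMPRESSION_OK", TRUE, "not compressed"))

    sniff <- tryCatch(sniffContainer(path), error = function(e)
        return("IOERROR"))
    if (identical(sniff, "IOERROR"))
        return(CheckResult("COMPRESSION_OK", FALSE,
                           "I/O failure while reading magic bytes"))
    if (identical(sniff, "EMPTY"))
        return(CheckResult("COMPRESSION_OK", FALSE, "file is empty"))

    if (identical(claimed, "ZIP_CONTAINER")) {
        if (!identical(sniff, "ZIP"))
            return(CheckResult("COMPRESSION_OK", FALSE, sprintf(
                "magic bytes (%s) do not match claimed ZIP container",
                sniff)))
        return(CheckResult("COMPRESSION_OK", TRUE))
    }

    ## claimed GZIP or BGZF
    if (!sniff %in% c("GZIP", "BGZF"))
        return(CheckResult("COMPRESSION_OK", FALSE, sprintf(
            "magic bytes (%s) do not match claimed %s compression",
            sniff, tolower(claimed))))
    if (identical(claimed, "BGZF") && !identical(sniff, "BGZF"))
        return(CheckResult("COMPRESSION_OK", FALSE,
                           "gzip stream lacks the BGZF BC subfield"))

    bgzf <- identical(sniff, "BGZF") || identical(claimed, "BGZF")
    if (bgzf && !bgzfHasEof(path))
        return(CheckResult("COMPRESSION_OK", FALSE,
                           "missing BGZF EOF marker"))
    if (!thorough)
        return(CheckResult("COMPRESSION_OK", TRUE))

    walk <- .gzipWalk(path, FALSE)
    if (!isTRUE(walk$ok))
        return(CheckResult("COMPRESSION_OK", FALSE, sprintf(
            "%s at byte offset %.0f", walk$error, walk$error_offset)))
    if (bgzf) {
        bw <- .bgzfWalkBlocks(path)
        if (!isTRUE(bw$ok))
            return(CheckResult("COMPRESSION_OK", FALSE, sprintf(
                "%s at byte offset %.0f", bw$error, bw$error_offset)))
    }
    CheckResult("COMPRESSION_OK", TRUE)
}

#' Parse a checksum sidecar file
#'
#' Accepts the coreutils dialect (`<hex><space><space-or-asterisk><name>`)
#' and the bare-digest dialect (`<hex>` alone); only the first non-empty
#' line is read and the digest is lowercased.
#'
#' @param path an existing sidecar file.
#' @param algorithm `"md5"` or `"sha512"`; decides the required digest
#'   length.
#' @return a [SidecarChecksum]; malformed content raises an error of class
#'   `seqvalid_malformed_sidecar`.
#' @export
parseSidecar <- function(path, algorithm = c("md5", "sha512")) {
    algorithm <- match.arg(algorithm)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    bad <- function(why)
        stop(structure(class = c("seqvalid_malformed_sidecar", "error",
                                 "condition"),
                       list(message = sprintf("malformed sidecar %s: %s",
                                              path, why),
                            call = sys.call(-1))))
    if (!length(lines)) bad("no content")
    line <- sub("\r$", "", lines[[1]])
    m <- regmatches(line, regexec("^([0-9a-fA-F]+)(?:[ \t]+\\*?(.*))?$", line))[[1]]
    if (!length(m)) bad("not a digest line")
    hex <- tolower(m[2])
    want <- c(md5 = 32L, sha512 = 128L)[[algorithm]]
    if (nchar(hex) != want)
        bad(sprintf("expected %d hex characters for %s, found %d",
                    want, algorithm, nchar(hex)))
    new("SidecarChecksum", algorithm = algorithm, digestHex = hex,
        referencedName = if (length(m) >= 3L && nzchar(m[3])) m[3] else "")
}

#' Compute a streaming digest of a file's raw bytes
#'
#' Digests the on-disk (compressed) bytes without decompression, in constant
#' memory — matching how transfer tools like `md5sum` produce sidecars.
#'
#' @param path an existing, readable file.
#' @param algorithm `"md5"` or `"sha512"`.
#' @return lowercase hex digest.
#' @export
computeDigest <- function(path, algorithm = c("md5", "sha512")) {
    algorithm <- match.arg(algorithm)
    if (!file.exists(path) || dir.exists(path))
        stop("cannot digest: no such file: ", path)
    digest::digest(path, algo = algorithm, file = TRUE, serialize = FALSE)
}

#' Verify a file against its checksum sidecars
#'
#' Each sidecar in `companions` is parsed, the digest recomputed from the
#' file and compared case-insensitively. Absence of sidecars is not an
#' error: the single result passes with the note "no checksum found".
#'
#' @param path the file whose bytes are digested.
#' @param companions a [CompanionSet]; defaults to [locateCompanions()].
#' @return list of [CheckResult] with id `CHECKSUM_OK`, one per sidecar (or
#'   one pass-with-note when none exist).
#' @export
verifyChecksums <- function(path, companions = locateCompanions(path)) {
    side <- companions@checksumSidecars
    if (nrow(side) == 0L)
        return(list(CheckResult("CHECKSUM_OK", TRUE, "no checksum found")))
    lapply(seq_len(nrow(side)), function(i) {
        alg <- side$algorithm[i]
        sc <- tryCatch(parseSidecar(side$path[i], alg),
                       seqvalid_malformed_sidecar = function(e) e)
        if (inherits(sc, "condition"))
            return(CheckResult("CHECKSUM_OK", FALSE,
                               sprintf("malformed sidecar: %s",
                                       side$path[i])))
        got <- computeDigest(path, alg)
        if (identical(got, sc@digestHex))
            CheckResult("CHECKSUM_OK", TRUE)
        else
            CheckResult("CHECKSUM_OK", FALSE, sprintf(
                "%s mismatch: sidecar %s has %s, file digests to %s",
                alg, side$path[i], sc@digestHex, got))
    })
}

#' Write a checksum sidecar for a file
#'
#' Writes `<path>.<algorithm>` in the coreutils dialect (digest, two spaces,
#' basename, newline). Refuses to clobber an existing sidecar unless
#' `overwrite`; [verifyChecksums()] passes immediately afterwards.
#'
#' @param path an existing, readable file.
#' @param algorithm `"sha512"` (default) or `"md5"`.
#' @param overwrite replace an existing sidecar.
#' @return the sidecar path, invisibly.
#' @export
generateChecksum <- function(path, algorithm = c("sha512", "md5"),
                             overwrite = FALSE) {
    algorithm <- match.arg(algorithm)
    sidecar <- paste0(path, ".", algorithm)
    if (file.exists(sidecar) && !overwrite)
        stop(structure(class = c("seqvalid_sidecar_exists", "error",
                                 "condition"),
                       list(message = sprintf(
                           "sidecar %s exists; use overwrite = TRUE",
                           sidecar), call = sys.call(-1))))
    hex <- computeDigest(path, algorithm)
    writeLines(paste0(hex, "  ", basename(path)), sidecar)
    invisible(sidecar)
}
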