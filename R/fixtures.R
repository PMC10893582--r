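## Deterministic fixture forge: small valid files in every supported format
## plus a library of named corruption operators, each injecting exactly one
## defect. Same FixtureSpec => byte-identical output. The operator ->
## targeted-check table below is the contract the test matrix asserts.

.CORRUPTIONS <- c("NONE", "TRUNCATE_TAIL", "BYTE_FLIP", "BAD_MAGIC",
                  "STRIP_EOF_BLOCK", "ZERO_READS", "LENGTH_MISMATCH",
                  "DROP_QUALITY_LINE", "BAD_HEADER_CHAR", "DROP_FILEFORMAT",
                  "FIELD_COUNT_MISMATCH", "BAD_POS", "BAD_REF_CHAR",
                  "STALE_CHECKSUM", "DROP_INDEX")

#' Corruption operators applicable to a format
#'
#' @param format fixture format (`FASTQ`, `SAM`, `BAM`, `CRAM`, `VCF`,
#'   `ZIP`).
#' @param compress whether the fixture is compressed (gzip FASTQ, BGZF
#'   VCF); widens the applicable set with container-level operators.
#' @return character vector of operator names, always including `"NONE"`.
#' @export
applicableCorruptions <- function(format, compress = FALSE) {
    base <- switch(format,
        FASTQ = c("TRUNCATE_TAIL", "LENGTH_MISMATCH", "DROP_QUALITY_LINE",
                  "BAD_HEADER_CHAR"),
        SAM = c("TRUNCATE_TAIL", "ZERO_READS", "LENGTH_MISMATCH",
                "FIELD_COUNT_MISMATCH"),
        BAM = c("TRUNCATE_TAIL", "BYTE_FLIP", "BAD_MAGIC",
                "STRIP_EOF_BLOCK", "ZERO_READS", "DROP_INDEX"),
        CRAM = c("TRUNCATE_TAIL", "BAD_MAGIC", "STRIP_EOF_BLOCK",
                 "DROP_INDEX"),
        VCF = c("TRUNCATE_TAIL", "DROP_FILEFORMAT", "FIELD_COUNT_MISMATCH",
                "BAD_POS", "BAD_REF_CHAR"),
        ZIP = c("TRUNCATE_TAIL", "BYTE_FLIP"),
        character())
    if (compress && format == "FASTQ") base <- c(base, "BYTE_FLIP")
    if (compress && format == "VCF")
        base <- c(base, "BYTE_FLIP", "STRIP_EOF_BLOCK")
    c("NONE", base, "STALE_CHECKSUM")
}

#' The check a corruption operator is designed to trip
#'
#' The fixed operator-to-check table: for every corrupted fixture, thorough
#' validation must fail exactly this check (or, for `DROP_INDEX`, emit it as
#' a warning under the default index policy).
#'
#' @param format,compress as in [applicableCorruptions()].
#' @param corruption operator name.
#' @return list with `checkId` (`NA` for `"NONE"`) and `warning` (logical:
#'   the targeted result is advisory under default policy).
#' @export
corruptionTarget <- function(format, corruption, compress = FALSE) {
    compressed_container <- compress || format == "BAM"
    id <- switch(corruption,
        NONE = NA_character_,
        STALE_CHECKSUM = "CHECKSUM_OK",
        DROP_INDEX = "INDEX_PRESENT",
        TRUNCATE_TAIL = if (compressed_container) "COMPRESSION_OK"
                        else "FORMAT_OK",
        BYTE_FLIP = if (format == "ZIP") "FORMAT_OK" else "COMPRESSION_OK",
        STRIP_EOF_BLOCK = if (format == "CRAM") "FORMAT_OK"
                          else "COMPRESSION_OK",
        "FORMAT_OK")
    list(checkId = id, warning = identical(corruption, "DROP_INDEX"))
}

#' Construct a FixtureSpec
#'
#' @param format fixture format.
#' @param seed RNG seed; same spec, same bytes.
#' @param nRecords number of reads / variant rows / archive entries.
#' @param corruption `"NONE"` or an operator from
#'   [applicableCorruptions()].
#' @param compress compress the output (gzip for FASTQ, BGZF for VCF);
#'   ignored elsewhere (BAM is always BGZF).
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(format, seed, nRecords = 10L, corruption = "NONE",
                        compress = FALSE) {
    if (format == "BAM") compress <- TRUE
    if (format == "SAM") compress <- FALSE
    new("FixtureSpec", format = format, seed = as.integer(seed),
        nRecords = as.integer(nRecords), corruption = corruption,
        compress = isTRUE(compress))
}

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    force(expr)
}

## ---- seeded content generators ----

.randSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.genFastqLines <- function(n) {
    unlist(lapply(seq_len(n), function(i) {
        len <- sample(20:60, 1L)
        c(sprintf("@read_%04d length=%d", i, len),
          .randSeq(len, c("A", "C", "G", "T", "N")),
          "+",
          paste(intToUtf8(sample(33:73, len, replace = TRUE),
                          multiple = TRUE), collapse = ""))
    }))
}

.FIXTURE_REFS <- data.frame(name = c("chr1", "chr2"),
                            length = c(1000, 800),
                            stringsAsFactors = FALSE)

.genAlignments <- function(n) {
    if (n == 0L)
        return(data.frame(name = character(), flag = integer(),
                          ref = integer(), pos = integer(), mapq = integer(),
                          seq = character(), qual = character(),
                          stringsAsFactors = FALSE))
    len <- sample(20:50, n, replace = TRUE)
    data.frame(
        name = sprintf("read_%04d", seq_len(n)),
        flag = 0L,
        ref = sample(seq_len(nrow(.FIXTURE_REFS)), n, replace = TRUE),
        pos = sample(1:700, n, replace = TRUE),
        mapq = sample(20:60, n, replace = TRUE),
        seq = vapply(len, .randSeq, character(1)),
        qual = vapply(len, function(l)
            paste(intToUtf8(sample(33:73, l, replace = TRUE),
                            multiple = TRUE), collapse = ""),
            character(1)),
        stringsAsFactors = FALSE)
}

.samHeaderLines <- function() {
    c("@HD\tVN:1.6",
      sprintf("@SQ\tSN:%s\tLN:%d", .FIXTURE_REFS$name, .FIXTURE_REFS$length))
}

.samLines <- function(reads) {
    c(.samHeaderLines(),
      if (nrow(reads)) vapply(seq_len(nrow(reads)), function(i) {
          r <- reads[i, ]
          paste(r$name, r$flag, .FIXTURE_REFS$name[r$ref], r$pos, r$mapq,
                paste0(nchar(r$seq), "M"), "*", 0L, 0L, r$seq, r$qual,
                sep = "\t")
      }, character(1)))
}

.genVcfLines <- function(n, n_samples) {
    meta <- c("##fileformat=VCFv4.2",
              "##source=seqvalidFixture",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (n_samples > 0L)
        cols <- c(cols, "FORMAT", sprintf("sample_%d", seq_len(n_samples)))
    recs <- if (n > 0L) vapply(seq_len(n), function(i) {
        chrom <- sample(c("chr1", "chr2"), 1L)
        pos <- sample(1:1000000, 1L)
        ref <- .randSeq(sample(1:3, 1L))
        alt <- switch(sample(3L, 1L),
                      .randSeq(1L),
                      paste(.randSeq(1L), .randSeq(2L), sep = ","),
                      "<DEL>")
        qual <- sample(c(".", sprintf("%.1f", stats::runif(1, 0, 99))), 1L)
        info <- sample(c(".", sprintf("DP=%d", sample(1:200, 1L)),
                         sprintf("DP=%d;AF=%.2f", sample(1:200, 1L),
                                 stats::runif(1))), 1L)
        fields <- c(chrom, pos, ".", ref, alt, qual, "PASS", info)
        if (n_samples > 0L)
            fields <- c(fields, "GT:DP",
                        vapply(seq_len(n_samples), function(s)
                            sprintf("%s:%d", sample(c("0/0", "0/1", "1/1"),
                                                    1L),
                                    sample(1:99, 1L)), character(1)))
        paste(fields, collapse = "\t")
    }, character(1)) else character()
    c(meta, paste(cols, collapse = "\t"), recs)
}

## ---- encoders ----

## BAM reg2bin for an interval [beg, end) (0-based)
.reg2bin <- function(beg, end) {
    end <- end - 1
    shifts <- c(14, 17, 20, 23, 26)
    offs <- c(4681, 585, 73, 9, 1)
    for (i in seq_along(shifts)) {
        if (beg %/% 2^shifts[i] == end %/% 2^shifts[i])
            return(offs[i] + beg %/% 2^shifts[i])
    }
    0
}

.BAM_SEQ_CODES <- {
    codes <- integer(256)
    codes[utf8ToInt("A") + 1L] <- 1L; codes[utf8ToInt("a") + 1L] <- 1L
    codes[utf8ToInt("C") + 1L] <- 2L; codes[utf8ToInt("c") + 1L] <- 2L
    codes[utf8ToInt("G") + 1L] <- 4L; codes[utf8ToInt("g") + 1L] <- 4L
    codes[utf8ToInt("T") + 1L] <- 8L; codes[utf8ToInt("t") + 1L] <- 8L
    codes[utf8ToInt("N") + 1L] <- 15L; codes[utf8ToInt("n") + 1L] <- 15L
    codes
}

.packBamSeq <- function(seq) {
    codes <- .BAM_SEQ_CODES[utf8ToInt(seq) + 1L]
    if (length(codes) %% 2L) codes <- c(codes, 0L)
    hi <- codes[seq(1L, length(codes), by = 2L)]
    lo <- codes[seq(2L, length(codes), by = 2L)]
    as.raw(hi * 16L + lo)
}

.encodeBamRecord <- function(r) {
    l_seq <- nchar(r$seq)
    body <- c(
        .u32le((r$ref - 1L) %% 2^32),            # refID (0-based)
        .u32le((r$pos - 1L) %% 2^32),            # pos (0-based)
        as.raw(nchar(r$name) + 1L),              # l_read_name
        as.raw(r$mapq),
        .u16le(.reg2bin(r$pos - 1L, r$pos - 1L + l_seq)),
        .u16le(1L),                              # n_cigar_op
        .u16le(r$flag),
        .u32le(l_seq),
        .u32le(2^32 - 1),                        # next_refID = -1
        .u32le(2^32 - 1),                        # next_pos = -1
        .u32le(0L),                              # tlen
        charToRaw(r$name), as.raw(0L),
        .u32le(l_seq * 16L),                     # CIGAR: <l_seq>M
        .packBamSeq(r$seq),
        as.raw(utf8ToInt(r$qual) - 33L))
    c(.u32le(length(body)), body)
}

## Uncompressed BAM payload from the shared alignment fixture records.
.encodeBamPayload <- function(reads, header_lines = .samHeaderLines()) {
    text <- paste0(paste(header_lines, collapse = "\n"), "\n")
    refs <- .FIXTURE_REFS
    parts <- list(charToRaw("BAM"), as.raw(1L), .u32le(nchar(text)),
                  charToRaw(text), .u32le(nrow(refs)))
    for (i in seq_len(nrow(refs))) {
        nm <- charToRaw(refs$name[i])
        parts <- c(parts, list(.u32le(length(nm) + 1L), nm, as.raw(0L),
                               .u32le(refs$length[i])))
    }
    recs <- lapply(seq_len(nrow(reads)), function(i)
        .encodeBamRecord(reads[i, ]))
    do.call(c, c(parts, recs, list(raw())))
}

.writeBaiMinimal <- function(path, n_ref) {
    writeBin(c(charToRaw("BAI"), as.raw(1L), .u32le(n_ref),
               do.call(c, c(list(raw()), rep(list(.u32le(0L), .u32le(0L)),
                                             n_ref)))),
             path)
    invisible(path)
}

## ---- corruption helpers ----

.pickRecord <- function(n) sample(seq_len(n), 1L)

.flipByteAt <- function(bytes, offset) {
    bytes[offset] <- xor(bytes[offset], as.raw(sample(1:255, 1L)))
    bytes
}

## Cut `k` bytes off the tail of a BGZF stream, shifting by one if the cut
## would land exactly on a block boundary (which would leave a valid gzip
## stream and blur which check the operator targets).
.truncateBgzf <- function(bytes, k = 100L) {
    cut <- max(1L, length(bytes) - k)
    walk <- .bgzfWalkBlocks(data = bytes)
    if (cut %in% walk$offsets) cut <- cut - 1L
    bytes[seq_len(cut)]
}

## ---- fixture assembly ----

.fixtureFileName <- function(spec) {
    ext <- switch(spec@format,
        FASTQ = if (spec@compress) "fastq.gz" else "fastq",
        SAM = "sam", BAM = "bam", CRAM = "cram",
        VCF = if (spec@compress) "vcf.gz" else "vcf",
        ZIP = "zip")
    sprintf("%s_s%d_n%d_%s.%s", tolower(spec@format), spec@seed,
            spec@nRecords, tolower(spec@corruption), ext)
}

## Build final file bytes (content + container + byte-level corruption)
## for one spec. Returns list(bytes, defect = list(...)).
.buildFixtureBytes <- function(spec) {
    fmt <- spec@format
    op <- spec@corruption
    n <- spec@nRecords
    defect <- list()

    if (fmt == "FASTQ") {
        lines <- .genFastqLines(n)
        if (op == "LENGTH_MISMATCH") {
            k <- .pickRecord(n)
            i <- 4L * (k - 1L) + 4L
            lines[i] <- substring(lines[i], 1L, nchar(lines[i]) - 1L)
            defect <- list(record = k, lines = c(4L * (k - 1L) + 1L, i))
        } else if (op == "DROP_QUALITY_LINE") {
            k <- .pickRecord(n)
            i <- 4L * (k - 1L) + 4L
            lines <- lines[-i]
            defect <- list(record = k, lines = c(4L * (k - 1L) + 1L, i))
        } else if (op == "BAD_HEADER_CHAR") {
            k <- .pickRecord(n)
            i <- 4L * (k - 1L) + 1L
            substring(lines[i], 1L, 1L) <- "%"
            defect <- list(record = k, lines = c(i, i + 3L))
        }
        content <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
        if (op == "TRUNCATE_TAIL" && !spec@compress) {
            ## cut into the middle of the final quality line
            qlen <- nchar(lines[length(lines)])
            cut <- length(content) - 1L - qlen %/% 2L
            content <- content[seq_len(cut)]
            defect <- list(record = n,
                           lines = c(4L * (n - 1L) + 1L, 4L * n))
        }
        bytes <- if (spec@compress) gzipCompress(content) else content
        if (spec@compress && op == "TRUNCATE_TAIL") {
            cut <- max(12L, length(bytes) - 100L)
            bytes <- bytes[seq_len(cut)]
            defect <- list(cut_offset = cut)
        } else if (spec@compress && op == "BYTE_FLIP") {
            ## inside the single member's deflate body: [11, size-9]
            offset <- sample(11:(length(bytes) - 9L), 1L)
            bytes <- .flipByteAt(bytes, offset)
            defect <- list(flip_offset = offset)
        }
        return(list(bytes = bytes, defect = defect))
    }

    if (fmt == "SAM") {
        reads <- .genAlignments(if (op == "ZERO_READS") 0L else n)
        lines <- .samLines(reads)
        n_hdr <- length(.samHeaderLines())
        if (op == "LENGTH_MISMATCH") {
            k <- .pickRecord(n)
            i <- n_hdr + k
            lines[i] <- substring(lines[i], 1L, nchar(lines[i]) - 1L)
            defect <- list(record = k, lines = c(i, i))
        } else if (op == "FIELD_COUNT_MISMATCH") {
            k <- .pickRecord(n)
            i <- n_hdr + k
            lines[i] <- sub("\t[^\t]*$", "", lines[i])
            defect <- list(record = k, lines = c(i, i))
        }
        content <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
        if (op == "TRUNCATE_TAIL") {
            last_len <- nchar(lines[length(lines)])
            cut <- length(content) - 1L - (last_len - 6L)
            content <- content[seq_len(cut)]
            defect <- list(record = n, lines = rep(length(lines), 2L))
        }
        return(list(bytes = content, defect = defect))
    }

    if (fmt == "BAM") {
        reads <- .genAlignments(if (op == "ZERO_READS") 0L else n)
        payload <- .encodeBamPayload(reads)
        if (op == "BAD_MAGIC") {
            payload[1:4] <- charToRaw("XXXX")
            defect <- list(where = "BAM magic")
        }
        bytes <- bgzfCompress(payload)
        if (op == "STRIP_EOF_BLOCK") {
            bytes <- bytes[seq_len(length(bytes) - 28L)]
            defect <- list(where = "BGZF EOF marker")
        } else if (op == "TRUNCATE_TAIL") {
            bytes <- .truncateBgzf(bytes, 100L)
            defect <- list(cut_offset = length(bytes))
        } else if (op == "BYTE_FLIP") {
            ## within the first block's deflate body (after its 18-byte
            ## header, before its 8-byte trailer)
            first_total <- .rdU16(bytes, 17L) + 1L
            offset <- sample(19:(first_total - 8L), 1L)
            bytes <- .flipByteAt(bytes, offset)
            defect <- list(flip_offset = offset)
        }
        return(list(bytes = bytes, defect = defect))
    }

    if (fmt == "CRAM") {
        filler <- as.raw(sample(0:255, 32L + 8L * n, replace = TRUE))
        bytes <- c(charToRaw("CRAM"), as.raw(c(3L, 0L)), filler, .CRAM_EOF)
        if (op == "BAD_MAGIC") {
            bytes[1:4] <- charToRaw("XXXX")
            defect <- list(where = "CRAM magic")
        } else if (op == "STRIP_EOF_BLOCK") {
            bytes <- bytes[seq_len(length(bytes) - 38L)]
            defect <- list(where = "CRAM EOF container")
        } else if (op == "TRUNCATE_TAIL") {
            bytes <- bytes[seq_len(length(bytes) - 40L)]
            defect <- list(cut_offset = length(bytes))
        }
        return(list(bytes = bytes, defect = defect))
    }

    if (fmt == "VCF") {
        n_samples <- sample(0:3, 1L)
        lines <- .genVcfLines(n, n_samples)
        n_hdr <- length(lines) - n
        if (op == "DROP_FILEFORMAT") {
            lines <- lines[-1L]
            defect <- list(lines = c(1L, 1L))
        } else if (op %in% c("FIELD_COUNT_MISMATCH", "BAD_POS",
                             "BAD_REF_CHAR")) {
            k <- .pickRecord(n)
            i <- n_hdr + k
            fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
            if (op == "FIELD_COUNT_MISMATCH")
                fields <- fields[-length(fields)]
            else if (op == "BAD_POS")
                fields[2] <- paste0(fields[2], "x")
            else
                fields[4] <- "AXT"
            lines[i] <- paste(fields, collapse = "\t")
            defect <- list(record = k, lines = c(i, i))
        }
        content <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
        if (op == "TRUNCATE_TAIL" && !spec@compress) {
            last_len <- nchar(lines[length(lines)])
            cut <- length(content) - 1L - (last_len %/% 2L)
            content <- content[seq_len(cut)]
            defect <- list(record = n, lines = rep(length(lines), 2L))
        }
        bytes <- if (spec@compress) bgzfCompress(content) else content
        if (spec@compress) {
            if (op == "TRUNCATE_TAIL") {
                bytes <- .truncateBgzf(bytes, 100L)
                defect <- list(cut_offset = length(bytes))
            } else if (op == "STRIP_EOF_BLOCK") {
                bytes <- bytes[seq_len(length(bytes) - 28L)]
                defect <- list(where = "BGZF EOF marker")
            } else if (op == "BYTE_FLIP") {
                first_total <- .rdU16(bytes, 17L) + 1L
                offset <- sample(19:(first_total - 8L), 1L)
                bytes <- .flipByteAt(bytes, offset)
                defect <- list(flip_offset = offset)
            }
        }
        return(list(bytes = bytes, defect = defect))
    }

    if (fmt == "ZIP") {
        entries <- lapply(seq_len(max(n, 1L)), function(i)
            charToRaw(paste0("entry ", i, "\n",
                             paste(replicate(5, .randSeq(40L)),
                                   collapse = "\n"), "\n")))
        names(entries) <- sprintf("entry_%02d.txt", seq_len(max(n, 1L)))
        tmp <- tempfile(fileext = ".zip")
        on.exit(unlink(tmp), add = TRUE)
        writeZip(entries, tmp)
        bytes <- readBin(tmp, "raw", n = file.size(tmp))
        if (op == "TRUNCATE_TAIL") {
            bytes <- bytes[seq_len(length(bytes) - 50L)]
            defect <- list(cut_offset = length(bytes))
        } else if (op == "BYTE_FLIP") {
            nlen <- nchar(names(entries)[1])
            csize <- length(.deflateRaw(entries[[1]], 6L))
            offset <- 30L + nlen + max(1L, csize %/% 2L)
            bytes <- .flipByteAt(bytes, offset)
            defect <- list(flip_offset = offset, entry = names(entries)[1])
        }
        return(list(bytes = bytes, defect = defect))
    }

    stop("no fixture generator for format ", fmt)
}

#' Generate a fixture file (plus sidecars and indices)
#'
#' An uncorrupted spec yields a file that passes thorough validation
#' end-to-end, with a matching sha512 sidecar and, for BAM/CRAM, a
#' syntactically minimal index companion. Any other corruption value
#' injects exactly one defect after generating the valid file;
#' `STALE_CHECKSUM` writes the sidecar first and then regenerates the file
#' with different (still valid) content. A JSON manifest
#' (`<file>.manifest.json`) records the spec and the defect location.
#'
#' @param spec a [FixtureSpec] (see [fixtureSpec()]).
#' @param outDir output directory, created if needed.
#' @return the fixture path, invisibly.
#' @export
makeFixture <- function(spec, outDir) {
    validObject(spec)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outDir, .fixtureFileName(spec))
    op <- spec@corruption

    built <- .withSeed(spec@seed, .buildFixtureBytes(spec))
    defect <- built$defect

    if (op == "STALE_CHECKSUM") {
        ## sidecar digests the seed's content; the file on disk is a valid
        ## regeneration with different content
        stale_hex <- digest::digest(built$bytes, algo = "sha512",
                                    serialize = FALSE)
        writeLines(paste0(stale_hex, "  ", basename(path)),
                   paste0(path, ".sha512"))
        fresh <- fixtureSpec(spec@format, spec@seed + 499979L,
                             spec@nRecords, "NONE", spec@compress)
        built2 <- .withSeed(fresh@seed, .buildFixtureBytes(fresh))
        writeBin(built2$bytes, path)
        defect <- list(stale_digest = stale_hex)
    } else {
        writeBin(built$bytes, path)
        generateChecksum(path, "sha512", overwrite = TRUE)
    }

    if (spec@format == "BAM" && op != "DROP_INDEX")
        .writeBaiMinimal(paste0(path, ".bai"), nrow(.FIXTURE_REFS))
    if (spec@format == "CRAM" && op != "DROP_INDEX")
        writeBin(gzipCompress(charToRaw("0\t0\t0\t0\t0\t0\n")),
                 paste0(path, ".crai"))

    target <- corruptionTarget(spec@format, op, spec@compress)
    manifest <- list(format = spec@format, seed = spec@seed,
                     n_records = spec@nRecords, corruption = op,
                     compress = spec@compress, file = basename(path),
                     target_check = target$checkId,
                     target_warning = target$warning,
                     defect = defect)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, null = "null")
    invisible(path)
}

#' @rdname makeFixture
#' @param path a fixture path returned by `makeFixture()`.
#' @return `readFixtureManifest()`: the manifest as a list.
#' @export
readFixtureManifest <- function(path) {
    jsonlite::read_json(paste0(path, ".manifest.json"), simplifyVector = TRUE)
}
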