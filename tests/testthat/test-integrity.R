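test_that("existence checks stop at the first failure", {
    d <- fixtureDir()
    f <- file.path(d, "ten.bytes")
    writeBytes(as.raw(1:10), f)
    res <- checkExistence(f)
    expect_equal(vapply(res, checkId, character(1)),
                 c("EXISTS", "READABLE", "NONEMPTY"))
    expect_true(all(vapply(res, checkPassed, logical(1))))

    res2 <- checkExistence(file.path(d, "nope.bam"))
    expect_length(res2, 1L)
    expect_equal(checkId(res2[[1]]), "EXISTS")
    expect_false(checkPassed(res2[[1]]))
    expect_match(checkDetail(res2[[1]]), "no such file")

    f0 <- file.path(d, "zero.bytes")
    file.create(f0)
    res3 <- checkExistence(f0)
    expect_length(res3, 3L)
    expect_false(checkPassed(res3[[3]]))
    expect_equal(checkId(res3[[3]]), "NONEMPTY")
})

test_that("digests match an independent implementation", {
    d <- fixtureDir()
    empty <- file.path(d, "empty.txt")
    file.create(empty)
    # md5 of zero bytes / of the literal bytes "abc" (RFC 1321 test vectors,
    # reproducible with `python -c "import hashlib; ..."`)
    expect_equal(computeDigest(empty, "md5"),
                 "d41d8cd98f00b204e9800998ecf8427e")
    abc <- writeBytes(charToRaw("abc"), file.path(d, "abc.txt"))
    expect_equal(computeDigest(abc, "md5"),
                 "900150983cd24fb0d6963f7d28e17f72")
    expect_equal(computeDigest(abc, "md5"), unname(tools::md5sum(abc)))
    expect_equal(computeDigest(abc, "sha512"), paste0(
        "ddaf35a193617abacc417349ae20413112e6fa4e89a97ea20a9eeee64b55d39a",
        "2192992a274fc1a836ba3c23a3feebbd454d4423643ce80e2a9ac94fa54ca49f"))
    # determinism on a byte-identical copy
    cp <- file.path(d, "abc2.txt")
    file.copy(abc, cp)
    expect_equal(computeDigest(cp, "sha512"), computeDigest(abc, "sha512"))
})

test_that("sidecar parsing accepts both dialects and rejects junk", {
    d <- fixtureDir()
    s1 <- file.path(d, "a.md5")
    writeLines("d41d8cd98f00b204e9800998ecf8427e  empty.txt", s1)
    sc <- parseSidecar(s1, "md5")
    expect_equal(sc@digestHex, "d41d8cd98f00b204e9800998ecf8427e")
    expect_equal(sc@referencedName, "empty.txt")

    s2 <- file.path(d, "b.md5")
    writeLines("D41D8CD98F00B204E9800998ECF8427E", s2)
    sc2 <- parseSidecar(s2, "md5")
    expect_equal(sc2@digestHex, "d41d8cd98f00b204e9800998ecf8427e")
    expect_equal(sc2@referencedName, "")

    s3 <- file.path(d, "c.md5")
    writeLines("zzzz", s3)
    expect_error(parseSidecar(s3, "md5"),
                 class = "seqvalid_malformed_sidecar")
    s4 <- file.path(d, "d.md5")
    writeLines("d41d8cd98f00b2", s4)   # wrong length
    expect_error(parseSidecar(s4, "md5"),
                 class = "seqvalid_malformed_sidecar")
})

test_that("generate-then-verify round-trips and refuses to clobber", {
    d <- fixtureDir()
    f <- writeBytes(as.raw(sample(0:255, 500, TRUE)), file.path(d, "blob"))
    side <- generateChecksum(f, "sha512")
    expect_true(file.exists(side))
    expect_match(readLines(side), "^[0-9a-f]{128}  blob$")
    res <- verifyChecksums(f)
    expect_true(all(vapply(res, checkPassed, logical(1))))

    expect_error(generateChecksum(f, "sha512"),
                 class = "seqvalid_sidecar_exists")
    expect_silent(generateChecksum(f, "sha512", overwrite = TRUE))

    # absence is a pass-with-note
    g <- writeBytes(as.raw(1:3), file.path(d, "lonely"))
    res2 <- verifyChecksums(g)
    expect_length(res2, 1L)
    expect_true(checkPassed(res2[[1]]))
    expect_match(checkDetail(res2[[1]]), "no checksum found")
})

test_that("a stale sidecar fails verification naming both digests", {
    d <- fixtureDir()
    f <- writeBytes(charToRaw("version one"), file.path(d, "data.txt"))
    generateChecksum(f, "md5")
    writeBytes(charToRaw("version two"), f)
    res <- verifyChecksums(f)
    expect_false(checkPassed(res[[1]]))
    expect_match(checkDetail(res[[1]]), "mismatch")
    expect_match(checkDetail(res[[1]]), computeDigest(f, "md5"))
})

test_that("compression check agrees with claims, quick and thorough", {
    d <- fixtureDir()
    fq <- makeFx("FASTQ", 21, n = 20, compress = TRUE, dir = d)
    expect_true(checkPassed(checkCompression(fq, thorough = TRUE)))

    # plain bytes under a .gz name: claimed/actual disagreement
    fake <- writeBytes(charToRaw("not compressed"),
                       file.path(d, "fake.fastq.gz"))
    res <- checkCompression(fake)
    expect_false(checkPassed(res))
    expect_match(checkDetail(res), "magic bytes")

    # truncated gzip stream fails thorough with an offset
    bytes <- readBin(fq, "raw", n = file.size(fq))
    tr <- writeBytes(bytes[1:(length(bytes) - 100L)],
                     file.path(d, "trunc.fastq.gz"))
    res2 <- checkCompression(tr, thorough = TRUE)
    expect_false(checkPassed(res2))
    expect_match(checkDetail(res2), "byte offset")

    # BAM without its EOF marker fails even in quick mode
    bam <- makeFx("BAM", 21, dir = d)
    bb <- readBin(bam, "raw", n = file.size(bam))
    nb <- writeBytes(bb[1:(length(bb) - 28L)], file.path(d, "noeof.bam"))
    res3 <- checkCompression(nb, thorough = FALSE)
    expect_false(checkPassed(res3))
    expect_match(checkDetail(res3), "missing BGZF EOF marker")

    # uncompressed categories pass with a note
    sam <- makeFx("SAM", 21, dir = d)
    res4 <- checkCompression(sam)
    expect_true(checkPassed(res4))
    expect_match(checkDetail(res4), "not compressed")
})

test_that("multi-member gzip files are legal", {
    d <- fixtureDir()
    two <- c(gzipCompress(charToRaw("first member\n")),
             gzipCompress(charToRaw("second member\n")))
    p <- writeBytes(two, file.path(d, "two.fastq.gz"))
    expect_true(checkPassed(checkCompression(p, thorough = TRUE)))
    walk <- seqvalid:::.gzipWalk(p, TRUE)
    expect_equal(walk$n_members, 2L)
    expect_equal(rawToChar(walk$data), "first member\nsecond member\n")
})

test_that("thorough gzip walking matches a reference decompressor", {
    # oracle: Python's gzip module reading the stream to completion
    d <- fixtureDir()
    cases <- list()
    for (seed in 1:6) {
        cases[[length(cases) + 1L]] <-
            makeFx("FASTQ", seed, n = 10, compress = TRUE, dir = d)
        for (op in c("TRUNCATE_TAIL", "BYTE_FLIP"))
            cases[[length(cases) + 1L]] <-
                makeFx("FASTQ", seed, n = 10, corruption = op,
                       compress = TRUE, dir = d)
    }
    files <- unlist(cases)
    script <- file.path(d, "gzcheck.py")
    writeLines(c(
        "import gzip, sys",
        "for p in sys.argv[1:]:",
        "    try:",
        "        with gzip.open(p, 'rb') as fh:",
        "            while fh.read(65536): pass",
        "        print('OK')",
        "    except Exception:",
        "        print('BAD')"), script)
    oracle <- system2("python", c(script, files), stdout = TRUE) == "OK"
    mine <- vapply(files, function(p)
        checkPassed(checkCompression(p, detectFileType(p), thorough = TRUE)),
        logical(1))
    expect_equal(unname(mine), oracle)
})

test_that("any single byte flip in the file breaks checksum verification", {
    d <- fixtureDir()
    p <- makeFx("VCF", 31, n = 20, dir = d)
    bytes <- readBin(p, "raw", n = file.size(p))
    set.seed(31)
    for (i in 1:20) {
        at <- sample(length(bytes), 1L)
        mod <- bytes
        mod[at] <- xor(mod[at], as.raw(sample(1:255, 1L)))
        writeBytes(mod, p)
        res <- verifyChecksums(p)
        expect_false(checkPassed(res[[1]]),
                     label = sprintf("flip at byte %d detected", at))
    }
})
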