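test_that("pipeline order: early failures suppress later stages", {
    d <- fixtureDir()
    rep <- validateFile(file.path(d, "ghost.bam"))
    expect_equal(verdict(rep), "FAIL")
    expect_length(reportChecks(rep), 1L)
    expect_equal(checkId(reportChecks(rep)[[1]]), "EXISTS")

    # bad compression: no checksum, no FORMAT_OK attempted
    bad <- writeBytes(charToRaw("plain text"), file.path(d, "fake.bam"))
    generateChecksum(bad)
    rep2 <- validateFile(bad, thorough = TRUE)
    ids <- vapply(reportChecks(rep2), checkId, character(1))
    expect_true("COMPRESSION_OK" %in% ids)
    expect_false("FORMAT_OK" %in% ids)
    expect_false("CHECKSUM_OK" %in% ids)

    # bad checksum: FORMAT_OK suppressed
    fq <- makeFx("FASTQ", 70, dir = d)
    writeLines(paste0(strrep("0", 128), "  x"), paste0(fq, ".sha512"))
    rep3 <- validateFile(fq)
    ids3 <- vapply(reportChecks(rep3), checkId, character(1))
    expect_true("CHECKSUM_OK" %in% ids3)
    expect_false("FORMAT_OK" %in% ids3)

    # full pass keeps canonical ordering
    fq2 <- makeFx("FASTQ", 71, dir = d)
    ids4 <- vapply(reportChecks(validateFile(fq2)), checkId, character(1))
    expect_equal(ids4, c("EXISTS", "READABLE", "NONEMPTY", "COMPRESSION_OK",
                         "CHECKSUM_OK", "FORMAT_OK"))
})

test_that("unknown formats get universal checks and a pass-with-note", {
    d <- fixtureDir()
    p <- writeBytes(charToRaw("arbitrary bytes\n"), file.path(d, "notes.xyz"))
    rep <- validateFile(p)
    expect_equal(verdict(rep), "PASS")
    expect_equal(warningCount(rep), 1L)
    expect_match(checkDetail(reportChecks(rep)[[length(reportChecks(rep))]]),
                 "no validator")
})

test_that("multi-file runs aggregate independently with exit codes", {
    d <- fixtureDir()
    good <- makeFx("FASTQ", 80, dir = d)
    missing <- file.path(d, "missing.bam")
    s <- validatePaths(c(good, missing))
    expect_equal(nPass(s), 1L)
    expect_equal(nFail(s), 1L)
    expect_equal(exitCode(s), 1L)
    expect_length(reportChecks(runReports(s)[[2]]), 1L)

    s2 <- validatePaths(good)
    expect_equal(exitCode(s2), 0L)

    expect_error(validatePaths(character()),
                 class = "seqvalid_usage_error")
})

test_that("parallel runs are field-identical to serial runs", {
    d <- fixtureDir()
    paths <- c(
        vapply(1:4, function(s) makeFx("FASTQ", s, dir = d), character(1)),
        makeFx("BAM", 1, dir = d),
        makeFx("BAM", 2, corruption = "BAD_MAGIC", dir = d),
        makeFx("VCF", 1, corruption = "BAD_POS", dir = d),
        makeFx("ZIP", 1, dir = d),
        file.path(d, "absent.sam"))
    serial <- validatePaths(paths, threads = 1L, thorough = TRUE)
    for (th in c(2L, 4L)) {
        par <- validatePaths(paths, threads = th, thorough = TRUE)
        expect_identical(formatReport(par, "json"),
                         formatReport(serial, "json"),
                         label = sprintf("threads=%d equals serial", th))
    }
})

test_that("text and JSON reports carry the verdicts", {
    d <- fixtureDir()
    good <- makeFx("FASTQ", 81, dir = d)
    stale <- makeFx("VCF", 81, corruption = "STALE_CHECKSUM", dir = d)
    s <- validatePaths(c(good, stale))

    txt <- formatReport(s, "text")
    lines <- strsplit(txt, "\n")[[1]]
    expect_length(lines, 3L)
    expect_match(lines[1], "^PASS\t.*\tFASTQ$")
    expect_match(lines[2], "^FAIL\t.*\tCHECKSUM_OK: ")
    expect_equal(lines[3], "passed 1 of 2")

    parsed <- jsonlite::fromJSON(formatReport(s, "json"),
                                 simplifyVector = FALSE)
    expect_equal(parsed$n_pass, 1L)
    expect_equal(parsed$n_fail, 1L)
    expect_equal(parsed$exit_code, 1L)
    expect_equal(vapply(parsed$reports, `[[`, character(1), "verdict"),
                 c("PASS", "FAIL"))
    ids <- vapply(parsed$reports[[1]]$checks, `[[`, character(1),
                  "check_id")
    expect_equal(ids[1:3], c("EXISTS", "READABLE", "NONEMPTY"))
})

test_that("report and summary invariants hold under validity checking", {
    expect_error(new("RunSummary", reports = list(), nPass = 1L,
                     nFail = 0L, exitCode = 0L), "reports")
    expect_error(CheckResult("FORMAT_OK", FALSE, ""), "detail")
    cat <- detectFileType("x.bam")
    expect_error(new("FileCategory", format = "BAM", compression = "NONE",
                     extensionMatched = ".bam"), "BGZF")
    rep <- FileReport("x", cat, list(CheckResult("EXISTS", TRUE)))
    expect_equal(verdict(rep), "PASS")
    rep2 <- FileReport("x", cat, list(
        CheckResult("EXISTS", TRUE),
        CheckResult("INDEX_PRESENT", FALSE, "no index", warning = TRUE)))
    expect_equal(verdict(rep2), "PASS")
    expect_equal(warningCount(rep2), 1L)
})
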