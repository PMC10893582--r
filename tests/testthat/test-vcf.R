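vcfText <- function(...) paste0(paste(c(...), collapse = "\n"), "\n")
.hdr8 <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"

test_that("a minimal VCF passes and header defects are located", {
    d <- fixtureDir()
    ok <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", .hdr8, "chr1\t100\t.\tA\tT\t50\tPASS\t.")),
        file.path(d, "ok.vcf"))
    res <- validateVcf(ok, thorough = TRUE)
    expect_true(checkPassed(res$check))
    expect_equal(res$info$columnCount, 8L)
    expect_equal(res$info$recordCount, 1L)

    nof <- writeBytes(charToRaw(vcfText(
        .hdr8, "chr1\t100\t.\tA\tT\t50\tPASS\t.")), file.path(d, "nf.vcf"))
    res2 <- validateVcf(nof)
    expect_false(checkPassed(res2$check))
    expect_match(checkDetail(res2$check),
                 "missing fileformat declaration at line 1")

    badmeta <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", "##nometa", .hdr8,
        "chr1\t100\t.\tA\tT\t50\tPASS\t.")), file.path(d, "bm.vcf"))
    expect_match(checkDetail(validateVcf(badmeta)$check), "lacks '='")
})

test_that("record grammar failures cite their line numbers", {
    d <- fixtureDir()
    mk <- function(rec, name) writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", .hdr8, rec)), file.path(d, name))

    res <- validateVcf(mk("chr1\t12x\t.\tA\tT\t50\tPASS\t.", "pos.vcf"))
    expect_match(checkDetail(res$check),
                 "POS '12x' not a positive integer at line 3")
    expect_match(checkDetail(validateVcf(
        mk("chr1\t5\t.\tAXQ\tT\t50\tPASS\t.", "ref.vcf"))$check), "REF")
    expect_match(checkDetail(validateVcf(
        mk("chr1\t5\t.\tA\tT\t50\tPASS", "nf.vcf"))$check),
        "7 fields where the header declares 8")
    expect_match(checkDetail(validateVcf(
        mk("chr1\t5\t.\tA\tT\t-3\tPASS\t.", "q.vcf"))$check), "QUAL")
    # symbolic / breakend / multi-allelic ALT all accepted
    expect_true(checkPassed(validateVcf(
        mk("chr1\t5\t.\tA\t<DEL>,G\t.\tPASS\tDP=3", "alt.vcf"))$check))
    expect_true(checkPassed(validateVcf(
        mk("chr2\t8\t.\tT\tT[chr2:100[\t10\tq10\t.", "bnd.vcf"))$check))
})

test_that("sample columns follow FORMAT, GT first", {
    d <- fixtureDir()
    hdr <- paste(.hdr8, "FORMAT", "s1", "s2", sep = "\t")
    ok <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", hdr,
        "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:3\t1/1")),
        file.path(d, "s.vcf"))
    expect_true(checkPassed(validateVcf(ok, thorough = TRUE)$check))

    bad_gt <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", hdr,
        "chr1\t100\t.\tA\tT\t50\tPASS\t.\tDP:GT\t3:0/1\t2:1/1")),
        file.path(d, "gt.vcf"))
    expect_match(checkDetail(validateVcf(bad_gt)$check), "GT")

    over <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", hdr,
        "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1:3:9\t1/1")),
        file.path(d, "ov.vcf"))
    expect_match(checkDetail(validateVcf(over)$check),
                 "more fields than FORMAT")

    dup <- writeBytes(charToRaw(vcfText(
        "##fileformat=VCFv4.2", paste(.hdr8, "FORMAT", "s1", "s1",
                                      sep = "\t"))), file.path(d, "dup.vcf"))
    expect_match(checkDetail(validateVcf(dup)$check), "duplicate sample")
})

test_that("header-only VCF passes with a note, fails under strict", {
    d <- fixtureDir()
    p <- writeBytes(charToRaw(vcfText("##fileformat=VCFv4.2", .hdr8)),
                    file.path(d, "h.vcf"))
    res <- validateVcf(p)
    expect_true(checkPassed(res$check))
    expect_match(checkDetail(res$check), "header-only")
    expect_false(checkPassed(validateVcf(p, strict = TRUE)$check))
})

test_that("unusual versions note rather than fail", {
    d <- fixtureDir()
    p <- writeBytes(charToRaw(vcfText("##fileformat=VCFv3.3", .hdr8,
                                      "chr1\t5\t.\tA\tT\t.\tPASS\t.")),
                    file.path(d, "v3.vcf"))
    res <- validateVcf(p, thorough = TRUE)
    expect_true(checkPassed(res$check))
    expect_match(checkDetail(res$check), "unusual VCF version")
})

test_that("verdicts and record counts survive BGZF compression", {
    for (seed in c(13, 14)) {
        d <- fixtureDir()
        plain <- makeFx("VCF", seed, n = 30, dir = d)
        bgzf <- makeFx("VCF", seed, n = 30, compress = TRUE, dir = d)
        rp <- validateVcf(plain, thorough = TRUE)
        rb <- validateVcf(bgzf, thorough = TRUE)
        expect_true(checkPassed(rp$check))
        expect_equal(checkPassed(rp$check), checkPassed(rb$check))
        expect_equal(rp$info$recordCount, 30L)
        expect_equal(rb$info$recordCount, 30L)
        expect_equal(rp$info$sampleNames, rb$info$sampleNames)
    }
})

test_that("VCF corruption operators hit their declared rule", {
    for (op in c("DROP_FILEFORMAT", "FIELD_COUNT_MISMATCH", "BAD_POS",
                 "BAD_REF_CHAR")) {
        d <- fixtureDir()
        p <- makeFx("VCF", 23, n = 25, corruption = op, dir = d)
        res <- validateVcf(p, thorough = TRUE)
        expect_false(checkPassed(res$check), label = op)
        man <- readFixtureManifest(p)
        if (!is.null(man$defect$lines))
            expect_match(checkDetail(res$check),
                         sprintf("line %d", man$defect$lines[1]),
                         label = sprintf("%s cites corrupted line", op))
    }
})
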