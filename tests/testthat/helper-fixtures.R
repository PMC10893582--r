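# Shared test helpers: fixture creation in fresh temp dirs and the roster
# of (format, compressed) variants the generator supports.

fixtureDir <- function() {
    d <- file.path(tempdir(), paste0("fx_", paste(sample(letters, 8),
                                                  collapse = "")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
}

# every (format, compress) variant with its applicable operators
fixtureVariants <- function() {
    data.frame(
        format = c("FASTQ", "FASTQ", "SAM", "BAM", "CRAM", "VCF", "VCF",
                   "ZIP"),
        compress = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
        stringsAsFactors = FALSE)
}

makeFx <- function(format, seed, n = 5L, corruption = "NONE",
                   compress = FALSE, dir = fixtureDir()) {
    makeFixture(fixtureSpec(format, seed, n, corruption, compress), dir)
}

failedChecks <- function(report) {
    Filter(function(ck) !checkPassed(ck), reportChecks(report))
}

failedIds <- function(report) {
    vapply(failedChecks(report), checkId, character(1))
}

# write raw bytes, return path
writeBytes <- function(bytes, path) {
    writeBin(bytes, path)
    path
}
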