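## Orchestration: the per-file pipeline (existence -> compression ->
## checksum -> format dispatch), multi-file runs with optional per-file
## parallelism, and report rendering.

#' Validate a single file through the full pipeline
#'
#' Checks run in fixed order — existence, compression, checksums, then the
#' format-specific validator dispatched from the registry — and a failure at
#' any stage suppresses all later stages. Files of unknown (or
#' unregistered) format receive the universal checks only, with an advisory
#' `FORMAT_OK` note. Formats that expect an index companion (BAM, CRAM,
#' BGZF-compressed VCF) get an `INDEX_PRESENT` result after the format
#' check.
#'
#' @param path file to validate.
#' @param thorough full-depth validation (every gzip member CRC, every
#'   record) instead of quick structural checks.
#' @param strict missing index companions and header-only VCFs fail instead
#'   of warning.
#' @return a [FileReport].
#' @export
validateFile <- function(path, thorough = FALSE, strict = FALSE) {
    category <- detectFileType(path)
    checks <- checkExistence(path)
    if (!all(vapply(checks, checkPassed, logical(1))))
        return(FileReport(path, category, checks))

    comp <- checkCompression(path, category, thorough)
    checks <- c(checks, list(comp))
    if (!comp@passed) return(FileReport(path, category, checks))

    companions <- locateCompanions(path, category)
    cks <- verifyChecksums(path, companions)
    checks <- c(checks, cks)
    if (!all(vapply(cks, checkPassed, logical(1))))
        return(FileReport(path, category, checks))

    entry <- .lookupValidator(category@format)
    if (is.null(entry)) {
        checks <- c(checks, list(CheckResult(
            "FORMAT_OK", TRUE,
            sprintf("no validator for type '%s'", category@format),
            warning = TRUE)))
        return(FileReport(path, category, checks))
    }
    fmt_checks <- entry$fun(path, category, thorough, strict)
    checks <- c(checks, fmt_checks)
    fmt_failed <- !all(vapply(fmt_checks, checkPassed, logical(1)))

    if (!fmt_failed && .formatNeedsIndex(category@format, category))
        checks <- c(checks, list(
            checkAlignmentIndex(path, companions, thorough, strict)))
    FileReport(path, category, checks)
}

#' Validate many files, optionally in parallel
#'
#' Each path runs through the [validateFile()] pipeline independently; one
#' file's failure never aborts the others. With `threads > 1` files are
#' processed concurrently (forked workers), but reports are returned in
#' input order and are identical to a serial run.
#'
#' @param paths non-empty character vector of files.
#' @param threads number of worker processes.
#' @param thorough,strict passed to [validateFile()].
#' @return a [RunSummary].
#' @export
validatePaths <- function(paths, threads = 1L, thorough = FALSE,
                          strict = FALSE) {
    if (!is.character(paths) || length(paths) == 0L)
        stop(structure(class = c("seqvalid_usage_error", "error",
                                 "condition"),
                       list(message = "no paths given", call = sys.call())))
    stopifnot(threads >= 1L)
    one <- function(p) tryCatch(validateFile(p, thorough, strict),
        error = function(e) FileReport(p, detectFileType(p), list(
            CheckResult("EXISTS", FALSE,
                        sprintf("internal error: %s", conditionMessage(e))))))
    reports <- if (threads > 1L && .Platform$OS.type == "unix")
        parallel::mclapply(paths, one, mc.cores = threads,
                           mc.preschedule = TRUE)
    else
        lapply(paths, one)
    n_pass <- sum(vapply(reports, function(r) r@verdict == "PASS",
                         logical(1)))
    new("RunSummary", reports = reports, nPass = as.integer(n_pass),
        nFail = as.integer(length(reports) - n_pass),
        exitCode = if (n_pass == length(reports)) 0L else 1L)
}

.firstFailedCheck <- function(report) {
    for (ck in report@checks)
        if (!ck@passed && !ck@warning) return(ck)
    NULL
}

#' Render a run summary as text or JSON
#'
#' Text style prints one line per file — `PASS<TAB>path<TAB>format` or
#' `FAIL<TAB>path<TAB>first-failed-check: detail` — then a closing
#' `passed X of Y` line. JSON style serializes the whole summary with
#' stable key order; parsing it back reconstructs verdicts and check ids.
#'
#' @param summary a [RunSummary].
#' @param style `"text"` or `"json"`.
#' @return a single character string.
#' @export
formatReport <- function(summary, style = c("text", "json")) {
    style <- match.arg(style)
    stopifnot(is(summary, "RunSummary"))
    if (style == "text") {
        lines <- vapply(summary@reports, function(r) {
            if (r@verdict == "PASS")
                sprintf("PASS\t%s\t%s", r@path, r@category@format)
            else {
                ck <- .firstFailedCheck(r)
                sprintf("FAIL\t%s\t%s: %s", r@path, ck@checkId, ck@detail)
            }
        }, character(1))
        return(paste(c(lines, sprintf("passed %d of %d", summary@nPass,
                                      length(summary@reports))),
                     collapse = "\n"))
    }
    payload <- list(
        reports = lapply(summary@reports, function(r) list(
            path = r@path,
            format = r@category@format,
            compression = r@category@compression,
            verdict = r@verdict,
            n_warnings = r@warnings,
            checks = lapply(r@checks, function(ck) list(
                check_id = ck@checkId, passed = ck@passed,
                warning = ck@warning, detail = ck@detail)))),
        n_pass = summary@nPass, n_fail = summary@nFail,
        exit_code = summary@exitCode)
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE))
}
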