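## Constructors, accessors and show methods.

#' Construct a CheckResult
#'
#' @param checkId check identifier, e.g. `"COMPRESSION_OK"`.
#' @param passed logical.
#' @param detail reason on failure, or advisory note on a pass.
#' @param warning advisory severity; a failed warning does not flip a
#'   file's verdict.
#' @return a [CheckResult] object.
#' @export
CheckResult <- function(checkId, passed, detail = "", warning = FALSE) {
    new("CheckResult", checkId = checkId, passed = as.logical(passed),
        detail = detail, warning = warning)
}

.newCategory <- function(format, compression, extension = "") {
    new("FileCategory", format = format, compression = compression,
        extensionMatched = extension)
}

.newCompanionSet <- function(sidecars = NULL, indices = character()) {
    if (is.null(sidecars))
        sidecars <- data.frame(algorithm = character(), path = character(),
                               stringsAsFactors = FALSE)
    new("CompanionSet", checksumSidecars = sidecars, indexFiles = indices)
}

#' Assemble a FileReport from an ordered list of checks
#'
#' The verdict is derived, never supplied: `PASS` iff no failed non-warning
#' check is present.
#'
#' @param path validated path.
#' @param category its [FileCategory].
#' @param checks list of [CheckResult] in pipeline order.
#' @return a [FileReport].
#' @export
FileReport <- function(path, category, checks) {
    hard_fail <- any(vapply(checks, function(ck) !ck@passed && !ck@warning,
                            logical(1)))
    new("FileReport", path = path, category = category, checks = checks,
        verdict = if (hard_fail) "FAIL" else "PASS",
        warnings = sum(vapply(checks, function(ck) ck@warning, logical(1))))
}

## ---- accessors ----

#' @rdname CheckResult-class
setMethod("checkId", "CheckResult", function(object) object@checkId)
#' @rdname CheckResult-class
setMethod("checkPassed", "CheckResult", function(object) object@passed)
#' @rdname CheckResult-class
setMethod("checkDetail", "CheckResult", function(object) object@detail)
#' @rdname CheckResult-class
setMethod("isWarning", "CheckResult", function(object) object@warning)

#' @rdname FileCategory-class
setMethod("fileFormat", "FileCategory", function(object) object@format)
#' @rdname FileCategory-class
setMethod("fileCompression", "FileCategory", function(object) object@compression)
#' @rdname FileCategory-class
setMethod("extensionMatched", "FileCategory",
          function(object) object@extensionMatched)

#' @rdname CompanionSet-class
setMethod("checksumSidecars", "CompanionSet",
          function(object) object@checksumSidecars)
#' @rdname CompanionSet-class
setMethod("indexFiles", "CompanionSet", function(object) object@indexFiles)

#' @rdname FileReport-class
setMethod("reportPath", "FileReport", function(object) object@path)
#' @rdname FileReport-class
setMethod("reportChecks", "FileReport", function(object) object@checks)
#' @rdname FileReport-class
setMethod("verdict", "FileReport", function(object) object@verdict)
#' @rdname FileReport-class
setMethod("warningCount", "FileReport", function(object) object@warnings)
#' @rdname FileReport-class
setMethod("fileCategory", "FileReport", function(object) object@category)

#' @rdname RunSummary-class
setMethod("runReports", "RunSummary", function(object) object@reports)
#' @rdname RunSummary-class
setMethod("nPass", "RunSummary", function(object) object@nPass)
#' @rdname RunSummary-class
setMethod("nFail", "RunSummary", function(object) object@nFail)
#' @rdname RunSummary-class
setMethod("exitCode", "RunSummary", function(object) object@exitCode)

## ---- show methods ----

setMethod("show", "FileCategory", function(object) {
    cat(sprintf("FileCategory: %s (compression %s, matched '%s')\n",
                object@format, object@compression, object@extensionMatched))
})

setMethod("show", "CheckResult", function(object) {
    mark <- if (object@passed) "ok" else if (object@warning) "warn" else "FAIL"
    cat(sprintf("%-14s %-4s %s\n", object@checkId, mark, object@detail))
})

setMethod("show", "FileReport", function(object) {
    cat(sprintf("FileReport: %s [%s] -> %s\n", object@path,
                object@category@format, object@verdict))
    for (ck in object@checks) show(ck)
})

setMethod("show", "RunSummary", function(object) {
    cat(sprintf("RunSummary: %d file(s), %d passed, %d failed (exit %d)\n",
                length(object@reports), object@nPass, object@nFail,
                object@exitCode))
})

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf("FixtureSpec: %s seed=%d n=%d corruption=%s compress=%s\n",
                object@format, object@seed, object@nRecords,
                object@corruption, object@compress))
})

setMethod("show", "SidecarChecksum", function(object) {
    cat(sprintf("SidecarChecksum: %s %s (%s)\n", object@algorithm,
                object@digestHex,
                if (nzchar(object@referencedName)) object@referencedName
                else "bare digest"))
})
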