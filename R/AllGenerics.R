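## Accessor generics. Slot access from user code goes through these.

#' @rdname CheckResult-class
#' @param object a seqvalid S4 object
#' @export
setGeneric("checkId", function(object) standardGeneric("checkId"))
#' @rdname CheckResult-class
#' @export
setGeneric("checkPassed", function(object) standardGeneric("checkPassed"))
#' @rdname CheckResult-class
#' @export
setGeneric("checkDetail", function(object) standardGeneric("checkDetail"))
#' @rdname CheckResult-class
#' @export
setGeneric("isWarning", function(object) standardGeneric("isWarning"))

#' @rdname FileCategory-class
#' @param object a seqvalid S4 object
#' @export
setGeneric("fileFormat", function(object) standardGeneric("fileFormat"))
#' @rdname FileCategory-class
#' @export
setGeneric("fileCompression",
           function(object) standardGeneric("fileCompression"))
#' @rdname FileCategory-class
#' @export
setGeneric("extensionMatched",
           function(object) standardGeneric("extensionMatched"))

#' @rdname CompanionSet-class
#' @param object a seqvalid S4 object
#' @export
setGeneric("checksumSidecars",
           function(object) standardGeneric("checksumSidecars"))
#' @rdname CompanionSet-class
#' @export
setGeneric("indexFiles", function(object) standardGeneric("indexFiles"))

#' @rdname FileReport-class
#' @param object a seqvalid S4 object
#' @export
setGeneric("reportPath", function(object) standardGeneric("reportPath"))
#' @rdname FileReport-class
#' @export
setGeneric("reportChecks", function(object) standardGeneric("reportChecks"))
#' @rdname FileReport-class
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
#' @rdname FileReport-class
#' @export
setGeneric("warningCount", function(object) standardGeneric("warningCount"))
#' @rdname FileReport-class
#' @export
setGeneric("fileCategory", function(object) standardGeneric("fileCategory"))

#' @rdname RunSummary-class
#' @param object a seqvalid S4 object
#' @export
setGeneric("runReports", function(object) standardGeneric("runReports"))
#' @rdname RunSummary-class
#' @export
setGeneric("nPass", function(object) standardGeneric("nPass"))
#' @rdname RunSummary-class
#' @export
setGeneric("nFail", function(object) standardGeneric("nFail"))
#' @rdname RunSummary-class
#' @export
setGeneric("exitCode", function(object) standardGeneric("exitCode"))
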