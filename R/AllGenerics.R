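#' @rdname ctAccessors
#' @export
setGeneric("ctValues", function(x, ...) standardGeneric("ctValues"))

#' @rdname ctAccessors
#' @export
setGeneric("ctFlags", function(x, ...) standardGeneric("ctFlags"))

#' @rdname ctAccessors
#' @export
setGeneric("controlIds", function(x) standardGeneric("controlIds"))

#' @rdname ctAccessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' @rdname ctAccessors
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname flagEntries
#' @export
setGeneric("flagEntries", function(x, ...) standardGeneric("flagEntries"))

#' @rdname countDetectable
#' @export
setGeneric("countDetectable",
           function(x, sample = NULL, thresholdCt = 38, ...)
             standardGeneric("countDetectable"))

#' @rdname applySampleQC
#' @export
setGeneric("applySampleQC", function(x, minDetectable = 230, ...)
  standardGeneric("applySampleQC"))

#' @rdname deltaCtNormalize
#' @export
setGeneric("deltaCtNormalize", function(x, ...)
  standardGeneric("deltaCtNormalize"))

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x, ...)
  standardGeneric("quantileNormalize"))

#' @rdname controlCV
#' @export
setGeneric("controlCV", function(x, ...) standardGeneric("controlCV"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort", function(spec) standardGeneric("generateCohort"))

#' @rdname writeCohortFixtures
#' @export
setGeneric("writeCohortFixtures", function(cohort, dir)
  standardGeneric("writeCohortFixtures"))
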