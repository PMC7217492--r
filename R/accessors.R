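# Accessor generics: slot access stays behind these functions.

#' @rdname FluorTrace-class
#' @param object,x a \linkS4class{FluorTrace}.
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname FluorTrace-class
#' @export
setMethod("traceTimes", "FluorTrace", function(object) object@times)

#' @rdname FluorTrace-class
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname FluorTrace-class
#' @export
setMethod("traceValues", "FluorTrace", function(object) object@values)

#' @rdname FluorTrace-class
#' @export
setGeneric("traceMask", function(object) standardGeneric("traceMask"))
#' @rdname FluorTrace-class
#' @export
setMethod("traceMask", "FluorTrace", function(object) object@mask)

#' @rdname FluorTrace-class
#' @export
setGeneric("traceLabel", function(object) standardGeneric("traceLabel"))
#' @rdname FluorTrace-class
#' @export
setMethod("traceLabel", "FluorTrace", function(object) object@label)

#' Cohort accessors
#'
#' @param cohort a \linkS4class{TraceCohort}.
#' @return \code{cohortTimes}: the shared time grid; \code{cohortIntensity}:
#'   the cells x time intensity matrix; \code{cohortTruth}: the rowData
#'   annotation (simulation ground truth where present).
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortTimes <- function(cohort) {
  stopifnot(is(cohort, "TraceCohort"))
  cohort$time
}

#' @rdname cohort-accessors
#' @export
cohortIntensity <- function(cohort) {
  stopifnot(is(cohort, "TraceCohort"))
  SummarizedExperiment::assay(cohort, "intensity")
}

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(cohort) {
  stopifnot(is(cohort, "TraceCohort"))
  SummarizedExperiment::rowData(cohort)
}

#' Fit-result accessors
#'
#' Uniform read access to the fitted quantities of the S4 fit classes.
#'
#' @param object a fit object.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("halfLife", function(object) standardGeneric("halfLife"))
#' @rdname fit-accessors
#' @export
setMethod("halfLife", "DecayFit", function(object) object@halfLife)

#' @rdname fit-accessors
#' @export
setGeneric("decayRate", function(object) standardGeneric("decayRate"))
#' @rdname fit-accessors
#' @export
setMethod("decayRate", "DecayFit", function(object) object@k)

#' @rdname fit-accessors
#' @export
setGeneric("isExtrapolated", function(object) standardGeneric("isExtrapolated"))
#' @rdname fit-accessors
#' @export
setMethod("isExtrapolated", "DecayFit", function(object) object@extrapolated)

#' @rdname fit-accessors
#' @export
setGeneric("mobileFractions", function(object) standardGeneric("mobileFractions"))
#' @rdname fit-accessors
#' @export
setMethod("mobileFractions", "FrapFit", function(object) object@fractions)

#' @rdname fit-accessors
#' @export
setGeneric("recoveryHalfTimes", function(object) standardGeneric("recoveryHalfTimes"))
#' @rdname fit-accessors
#' @export
setMethod("recoveryHalfTimes", "FrapFit", function(object) object@tHalf)

#' @rdname fit-accessors
#' @export
setGeneric("particleNumber", function(object) standardGeneric("particleNumber"))
#' @rdname fit-accessors
#' @export
setMethod("particleNumber", "FcsFit", function(object) object@N)

#' @rdname fit-accessors
#' @export
setGeneric("diffusionTime", function(object) standardGeneric("diffusionTime"))
#' @rdname fit-accessors
#' @export
setMethod("diffusionTime", "FcsFit", function(object) object@tauD)

#' @rdname fit-accessors
#' @export
setGeneric("diffusionCoefficient",
           function(object) standardGeneric("diffusionCoefficient"))
#' @rdname fit-accessors
#' @export
setMethod("diffusionCoefficient", "FcsFit", function(object) object@D)

#' @rdname fit-accessors
#' @export
setGeneric("concentrationNM", function(object) standardGeneric("concentrationNM"))
#' @rdname fit-accessors
#' @export
setMethod("concentrationNM", "FcsFit", function(object) object@concNM)

#' @rdname fit-accessors
#' @export
setGeneric("cosinorPeriod", function(object) standardGeneric("cosinorPeriod"))
#' @rdname fit-accessors
#' @export
setMethod("cosinorPeriod", "CosineFit", function(object) object@period)

#' @rdname fit-accessors
#' @export
setGeneric("cosinorPhase", function(object) standardGeneric("cosinorPhase"))
#' @rdname fit-accessors
#' @export
setMethod("cosinorPhase", "CosineFit", function(object) object@phase)

#' @rdname fit-accessors
#' @export
setGeneric("relativeAmplitudeError",
           function(object) standardGeneric("relativeAmplitudeError"))
#' @rdname fit-accessors
#' @export
setMethod("relativeAmplitudeError", "CosineFit", function(object) object@rae)
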