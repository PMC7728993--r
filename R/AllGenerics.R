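#' Accessors
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionNames", function(object) standardGeneric("regionNames"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("nInputs", function(object) standardGeneric("nInputs"))

#' @rdname accessors
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("boldMatrix", function(object) standardGeneric("boldMatrix"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))

#' @rdname accessors
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))

#' @rdname accessors
#' @export
setGeneric("explainedVarianceOf",
           function(object) standardGeneric("explainedVarianceOf"))

#' @rdname accessors
#' @export
setGeneric("predictedResponse",
           function(object) standardGeneric("predictedResponse"))

#' @rdname accessors
#' @export
setGeneric("isFlatline", function(object) standardGeneric("isFlatline"))

#' @rdname accessors
#' @export
setGeneric("nModels", function(object) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

## ---- ModelSpec ----

#' @rdname accessors
setMethod("regionNames", "ModelSpec", function(object) object@regionNames)
#' @rdname accessors
setMethod("nRegions", "ModelSpec", function(object) length(object@regionNames))
#' @rdname accessors
setMethod("nInputs", "ModelSpec", function(object) object@nInputs)
#' @rdname accessors
setMethod("variant", "ModelSpec", function(object) object@variant)
#' @rdname accessors
setMethod("nStates", "ModelSpec",
          function(object) if (object@states == "one") 1L else 2L)

#' Structural masks of a ModelSpec
#'
#' @param spec a [ModelSpec-class].
#' @return \code{connectionMask}: l-by-l logical; \code{modulationMasks}:
#'   list of l-by-l logicals (one per input); \code{drivingMask}: l-by-m
#'   logical.
#' @export
connectionMask <- function(spec) spec@Amask

#' @rdname connectionMask
#' @export
modulationMasks <- function(spec) spec@Bmasks

#' @rdname connectionMask
#' @export
drivingMask <- function(spec) spec@Cmask

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d region(s) [%s], %d input(s)\n",
              nRegions(object), paste(object@regionNames, collapse = ", "),
              object@nInputs))
  cat(sprintf("  variant: %s, states: %s\n", object@variant, object@states))
  offd <- object@Amask & !diag(nRegions(object))
  cat(sprintf("  inter-regional connections: %d, modulated entries: %d, driven regions: %d\n",
              sum(offd), sum(vapply(object@Bmasks, sum, 0L)),
              sum(apply(object@Cmask, 1, any))))
})

## ---- BOLDSeries ----

#' @rdname accessors
setMethod("regionNames", "BOLDSeries", function(object) object@regionNames)
#' @rdname accessors
setMethod("nRegions", "BOLDSeries", function(object) ncol(object@y))
#' @rdname accessors
setMethod("boldMatrix", "BOLDSeries", function(object) object@y)
#' @rdname accessors
setMethod("repetitionTime", "BOLDSeries", function(object) object@TR)

setMethod("show", "BOLDSeries", function(object) {
  cat(sprintf("BOLDSeries: %d samples x %d region(s), TR = %g s (%.1f s)\n",
              nrow(object@y), ncol(object@y), object@TR,
              nrow(object@y) * object@TR))
  cat(sprintf("  regions: %s\n", paste(object@regionNames, collapse = ", ")))
})

setMethod("dim", "BOLDSeries", function(x) dim(x@y))

## ---- InputTimeline ----

#' @rdname accessors
setMethod("nInputs", "InputTimeline", function(object) nrow(object@u))

#' Input values and microtime step
#' @param timeline an [InputTimeline-class].
#' @export
inputMatrix <- function(timeline) timeline@u

#' @rdname inputMatrix
#' @export
microtimeStep <- function(timeline) timeline@dt

setMethod("show", "InputTimeline", function(object) {
  cat(sprintf("InputTimeline: %d input(s) x %d steps, dt = %g s (%.1f s)\n",
              nrow(object@u), ncol(object@u), object@dt,
              ncol(object@u) * object@dt))
})

## ---- DCMPosterior ----

#' @rdname accessors
setMethod("freeEnergy", "DCMPosterior", function(object) object@freeEnergy)
#' @rdname accessors
setMethod("posteriorMean", "DCMPosterior", function(object) object@mean)
#' @rdname accessors
setMethod("posteriorCov", "DCMPosterior", function(object) object@cov)
#' @rdname accessors
setMethod("explainedVarianceOf", "DCMPosterior",
          function(object) object@explainedVariance)
#' @rdname accessors
setMethod("predictedResponse", "DCMPosterior",
          function(object) object@predicted)
#' @rdname accessors
setMethod("isFlatline", "DCMPosterior", function(object) object@flatline)

setMethod("show", "DCMPosterior", function(object) {
  cat(sprintf("DCMPosterior (%s, %s-state): %d free parameter(s)\n",
              object@spec@variant, object@spec@states, length(object@mean)))
  cat(sprintf("  F = %.2f nats, explained variance = %.1f%%\n",
              object@freeEnergy, object@explainedVariance))
  cat(sprintf("  iterations = %d, converged = %s, flatline = %s\n",
              object@nIterations, object@converged, object@flatline))
})

## ---- ModelSpace ----

#' @rdname accessors
setMethod("nModels", "ModelSpace", function(object) nrow(object@codes))
#' @rdname accessors
setMethod("regionNames", "ModelSpace", function(object) object@regionNames)

setMethod("show", "ModelSpace", function(object) {
  cat(sprintf("ModelSpace: %d models over %d regions (%s)\n",
              nrow(object@codes), length(object@regionNames), object@rule))
  if (length(object@familyLabels))
    cat(sprintf("  families: %s\n",
                paste(names(table(object@familyLabels)), collapse = ", ")))
})

setMethod("length", "ModelSpace", function(x) nrow(x@codes))

## ---- RFXResult / ROCResult ----

setMethod("show", "RFXResult", function(object) {
  k <- which.max(object@protectedExceedance)
  cat(sprintf("RFXResult over %d models; BOR = %.3f\n",
              length(object@alpha), object@bor))
  cat(sprintf("  best model: %s (exceedance %.3f, protected %.3f)\n",
              object@modelNames[k], object@exceedance[k],
              object@protectedExceedance[k]))
})

#' @rdname accessors
setMethod("auc", "ROCResult", function(object) object@auc)

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.3f over %d thresholds\n",
              object@auc, length(object@thresholds)))
})
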