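#' Extract mixture components as a data.frame
#'
#' @param object a [KsMixtureFit-class].
#' @param ... unused.
#' @return data.frame with columns \code{mean}, \code{sd},
#'   \code{proportion}, one row per component, sorted by mean.
#' @export
setGeneric("components", function(object, ...) standardGeneric("components"))

#' @rdname components
#' @export
setMethod("components", "KsMixtureFit", function(object, ...) {
  data.frame(mean = object@mean, sd = object@sd,
             proportion = object@proportion)
})

#' BIC of a mixture fit
#' @param object a [KsMixtureFit-class].
#' @param ... unused.
#' @return numeric BIC value (for [selectModel()] fits, the BIC of the
#'   selected model; the per-k table is in [bicTable()]).
#' @export
setGeneric("bic", function(object, ...) standardGeneric("bic"))

#' @rdname bic
#' @export
setMethod("bic", "KsMixtureFit", function(object, ...) object@bic)

#' Per-k BIC table from model selection
#' @param object a [KsMixtureFit-class] returned by [selectModel()].
#' @param ... unused.
#' @return data.frame with one row per candidate component count.
#' @export
setGeneric("bicTable", function(object, ...) standardGeneric("bicTable"))

#' @rdname bicTable
#' @export
setMethod("bicTable", "KsMixtureFit", function(object, ...) object@bicTable)

#' Calibrated synonymous clock rate
#' @param object a [ClockCalibration-class].
#' @param ... unused.
#' @return numeric, substitutions per synonymous site per myr.
#' @export
setGeneric("clockRate", function(object, ...) standardGeneric("clockRate"))

#' @rdname clockRate
#' @export
setMethod("clockRate", "ClockCalibration", function(object, ...) object@cKs)

#' Placement results table
#' @param object a [WGDPlacementFit-class].
#' @param ... unused.
#' @return the per-hypothesis results data.frame.
#' @export
setGeneric("placementTable", function(object, ...) standardGeneric("placementTable"))

#' @rdname placementTable
#' @export
setMethod("placementTable", "WGDPlacementFit", function(object, ...) object@results)

#' Best-supported hypothesis id
#' @param object a [WGDPlacementFit-class].
#' @param ... unused.
#' @return character id of the minimum-AIC hypothesis.
#' @export
setGeneric("bestHypothesis", function(object, ...) standardGeneric("bestHypothesis"))

#' @rdname bestHypothesis
#' @export
setMethod("bestHypothesis", "WGDPlacementFit", function(object, ...) object@best)
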