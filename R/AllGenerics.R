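#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("lesionSide", function(x) standardGeneric("lesionSide"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("degreesFreedom", function(x) standardGeneric("degreesFreedom"))

#' @rdname accessors
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))

#' @rdname accessors
#' @export
setGeneric("variability", function(x) standardGeneric("variability"))

#' @rdname accessors
#' @export
setGeneric("windowLengths", function(x) standardGeneric("windowLengths"))

#' @rdname accessors
#' @export
setGeneric("subnetworkMeans", function(x) standardGeneric("subnetworkMeans"))

#' @rdname accessors
#' @export
setGeneric("suppressionScore", function(x) standardGeneric("suppressionScore"))

#' Flip hemispheres so every lesion sits on the right
#'
#' For subjects with a left-hemisphere lesion, exchanges the values of every
#' paired \code{L_}/\code{R_} region label so that all lesions end up in the
#' right hemisphere; right-lesion subjects pass through unchanged.  Applying
#' the flip twice is the identity.
#'
#' @param x a \code{RegionTimeSeries} or \code{VariabilityProfile}.
#' @param lesionSide \code{"L"} or \code{"R"}; defaults to the object's own
#'   metadata when it carries one.
#' @return an object of the same class with hemispheres exchanged when
#'   \code{lesionSide == "L"}.
#' @export
setGeneric("flipToLesionRight",
           function(x, lesionSide) standardGeneric("flipToLesionRight"))
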