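#' @name pulsegate-generics
#' @title Generics for pulsegate containers
#' @param x an object.
#' @keywords internal
NULL

#' @describeIn pulsegate-generics signal matrix (samples x segments).
#' @export
setGeneric("ecgSignals", function(x) standardGeneric("ecgSignals"))

#' @describeIn pulsegate-generics patient identifier per segment.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @describeIn pulsegate-generics PR/PEA label factor per segment.
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @describeIn pulsegate-generics sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @describeIn pulsegate-generics number of segments.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Count trainable parameters
#'
#' @param object a [PulseNet-class] model or an [S1Config-class] /
#'   [S2Config-class] configuration.
#' @param ... unused.
#' @return integer number of trainable weights and biases.
#' @seealso [countParametersClosedForm()]
#' @export
setGeneric("countParameters", function(object, ...)
  standardGeneric("countParameters"))
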