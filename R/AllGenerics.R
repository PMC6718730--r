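#' Stability coefficient of the NLARI process
#'
#' \eqn{\gamma = \beta / (4 - 2\alpha)}.  The deterministic map has a flip
#' bifurcation at \eqn{\gamma = 1}: the fixed point at the origin is
#' exponentially asymptotically stable for \eqn{\gamma \in (0, 1)} and a
#' period-2 cycle of amplitude \eqn{\sqrt{\ln\gamma}} appears beyond it.
#'
#' @param alpha resistance coefficient (scalar, != 2), or a
#'   [NlariParams-class] object.
#' @param beta restoration coefficient; ignored when \code{alpha} is a
#'   parameter object.
#' @return the stability coefficient, a numeric scalar.
#' @examples
#' stabilityCoefficient(0.71, 0.7)    # 0.2713...
#' stabilityCoefficient(NlariParams(alpha = 0.875, beta = 0.7481))
#' @export
setGeneric("stabilityCoefficient",
           function(alpha, beta) standardGeneric("stabilityCoefficient"))

#' Extract the numeric values of a trace
#'
#' @param x a [PotentialTrace-class] object.
#' @return numeric vector of membrane-potential deviations.
#' @examples
#' traceValues(PotentialTrace(c(0, 1, 2)))
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Relay index of a trace
#'
#' @param x a [PotentialTrace-class] object.
#' @return integer relay index (0 for a raw stimulus or recording).
#' @export
setGeneric("relayIndex", function(x) standardGeneric("relayIndex"))

#' Bits of a binarized spike train
#'
#' @param x a [BinarySpikeTrain-class] object.
#' @return integer 0/1 vector.
#' @examples
#' spikeBits(binarize(c(1, 0), c3 = 0.5))
#' @export
setGeneric("spikeBits", function(x) standardGeneric("spikeBits"))

#' Per-relay traces of a chain result
#'
#' @param x a [RelayChainResult-class] object.
#' @return list of [PotentialTrace-class] objects.
#' @export
setGeneric("chainTraces", function(x) standardGeneric("chainTraces"))

#' Decoded drives of an encoder--decoder chain
#'
#' @param x a [RelayChainResult-class] object.
#' @return list of numeric vectors (empty unless mode is "encoder_decoder").
#' @export
setGeneric("decoderOutputs", function(x) standardGeneric("decoderOutputs"))

#' Coefficient estimates as a named vector
#'
#' @param x an [EstimationResult-class] object.
#' @return named numeric vector with the trend, coefficient, standard-error
#'   and indicator estimates.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
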