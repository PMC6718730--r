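#' @describeIn NlariParams-class stability coefficient of a parameter object.
#' @export
setMethod("stabilityCoefficient", signature("NlariParams", "missing"),
  function(alpha, beta) stabilityCoefficient(alpha@alpha, alpha@beta))

#' @rdname stabilityCoefficient
#' @export
setMethod("stabilityCoefficient", signature("numeric", "numeric"),
  function(alpha, beta) {
    if (length(alpha) != 1L || length(beta) != 1L)
      stop("'alpha' and 'beta' must be scalars")
    if (!is.finite(alpha) || !is.finite(beta))
      stop("'alpha' and 'beta' must be finite")
    if (alpha == 2)
      stop("stability coefficient undefined at alpha = 2")
    beta / (4 - 2 * alpha)
  })

#' @export
setMethod("traceValues", "PotentialTrace", function(x) x@values)

#' @export
setMethod("relayIndex", "PotentialTrace", function(x) x@relayIndex)

#' @export
setMethod("length", "PotentialTrace", function(x) length(x@values))

#' @export
setMethod("spikeBits", "BinarySpikeTrain", function(x) x@bits)

#' @export
setMethod("length", "BinarySpikeTrain", function(x) length(x@bits))

#' @export
setMethod("chainTraces", "RelayChainResult", function(x) x@traces)

#' @export
setMethod("decoderOutputs", "RelayChainResult", function(x) x@decoderOutputs)

#' @export
setMethod("estimates", "EstimationResult", function(x)
  c(aHat = x@aHat, bHat = x@bHat,
    theta1Hat = x@theta1Hat, theta2Hat = x@theta2Hat,
    s11 = x@s11, s22 = x@s22, sigmaHat = x@sigmaHat,
    alphaHat = x@alphaHat, betaHat = x@betaHat,
    gammaHat = x@gammaHat, gammaSe = x@gammaSe,
    eta1 = x@eta1, eta2 = x@eta2, nUsed = x@nUsed))

setMethod("show", "NlariParams", function(object) {
  g <- if (object@alpha != 2)
    sprintf("%.4f", object@beta / (4 - 2 * object@alpha)) else "undefined"
  cat("NlariParams: alpha =", object@alpha, ", beta =", object@beta,
      ", omega =", object@omega, ", sigma =", object@sigma,
      "\n  stability coefficient gamma =", g, "\n")
})

setMethod("show", "PotentialTrace", function(object) {
  v <- object@values
  cat(sprintf(
    "PotentialTrace: %d points, dt = %g ms, relay %d, scale '%s'\n",
    length(v), object@dt, object@relayIndex, object@scaleNote))
  cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "DecoderThresholds", function(object) {
  cat(sprintf(
    "DecoderThresholds: c1 = %g > c2 = %g > c3 = %g, sigma1 = %g\n",
    object@c1, object@c2, object@c3, object@sigma1))
})

setMethod("show", "BinarySpikeTrain", function(object) {
  cat(sprintf("BinarySpikeTrain: %d points, %d spikes (threshold %g)\n",
              length(object@bits), sum(object@bits), object@thresholdUsed))
})

setMethod("show", "RelayChainResult", function(object) {
  cat(sprintf(
    "RelayChainResult: mode '%s', %d stored trace(s), n = %d\n",
    object@mode, length(object@traces), length(object@initialStimulus)))
})

setMethod("show", "EstimationResult", function(object) {
  cat("NLARI OLS fit (n used =", object@nUsed, ")\n")
  cat(sprintf("  theta1 = %.6g (se %.3g)   theta2 = %.6g (se %.3g)\n",
              object@theta1Hat, object@s11, object@theta2Hat, object@s22))
  cat(sprintf("  alpha = %.6g  beta = %.6g  gamma = %.6g (se %.3g)\n",
              object@alphaHat, object@betaHat, object@gammaHat,
              object@gammaSe))
  cat(sprintf("  sigma = %.6g  eta1 = %.6g  eta2 = %.6g\n",
              object@sigmaHat, object@eta1, object@eta2))
})
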