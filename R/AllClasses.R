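#' Encoder parameters of the NLARI process
#'
#' Coefficients of the second-order nonlinear autoregressive membrane-potential
#' process \deqn{Y_t = (2-\alpha) Y_{t-1} - (1-\alpha) Y_{t-2}
#'   - \beta Y_{t-1} e^{-Y_{t-1}^2} + \varepsilon_t.}
#' \code{alpha} is the (dimensionless) membrane electrical resistance
#' coefficient, \code{beta} the restoration coefficient, and \code{omega} /
#' \code{sigma} the mean and standard deviation of the synaptic drive, in
#' scaled-potential units per step.  The derived stability coefficient
#' \eqn{\gamma = \beta/(4-2\alpha)} is available through
#' [stabilityCoefficient()].  Lags are fixed to one step in every implemented
#' path (\code{kappa1 = kappa2 = 1}).
#'
#' @slot alpha numeric(1), resistance coefficient; finite, != 2 whenever the
#'   stability coefficient is requested.
#' @slot beta numeric(1), restoration coefficient, >= 0 (0 is the unit-root
#'   limit without a restoring force).
#' @slot omega numeric(1), drive mean.
#' @slot sigma numeric(1), drive standard deviation, >= 0.
#' @slot kappa1,kappa2 integer(1), resistance/restoration lags (always 1).
#'
#' @examples
#' p <- NlariParams(alpha = 0.71, beta = 0.7)
#' stabilityCoefficient(p)
#' @name NlariParams-class
#' @aliases NlariParams-class
#' @exportClass NlariParams
setClass("NlariParams",
  representation(alpha = "numeric", beta = "numeric",
                 omega = "numeric", sigma = "numeric",
                 kappa1 = "integer", kappa2 = "integer"),
  prototype(alpha = 0.71, beta = 0.7, omega = 0, sigma = 0,
            kappa1 = 1L, kappa2 = 1L))

setValidity("NlariParams", function(object) {
  msg <- character()
  for (s in c("alpha", "beta", "omega", "sigma"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(object@beta) == 1L && is.finite(object@beta) && object@beta < 0)
    msg <- c(msg, "'beta' must be >= 0")
  if (length(object@sigma) == 1L && is.finite(object@sigma) && object@sigma < 0)
    msg <- c(msg, "'sigma' must be >= 0")
  if (!identical(object@kappa1, 1L) || !identical(object@kappa2, 1L))
    msg <- c(msg, "only kappa1 = kappa2 = 1 is implemented")
  if (length(msg)) msg else TRUE
})

#' @param alpha,beta,omega,sigma see the class description.
#' @rdname NlariParams-class
#' @export
NlariParams <- function(alpha, beta, omega = 0, sigma = 0) {
  new("NlariParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      omega = as.numeric(omega), sigma = as.numeric(sigma))
}

#' A membrane-potential trace
#'
#' An ordered real sequence of membrane-potential deviations from rest at a
#' fixed sampling step (2 ms by default), with provenance: which relay in a
#' chain produced it and what amplitude scaling has been applied.
#'
#' @slot values numeric vector of potential deviations (scaled units), all
#'   finite, length >= 2.
#' @slot dt numeric(1), sampling step in ms.
#' @slot relayIndex integer(1) >= 0; 0 denotes a stimulus or recording that
#'   has not passed through a relay.
#' @slot scaleNote character(1), record of applied scaling (e.g. "raw/1000",
#'   "x1e5 display").
#'
#' @examples
#' tr <- PotentialTrace(c(0, 0.001, 0.002))
#' length(tr)
#' traceValues(tr)
#' @name PotentialTrace-class
#' @aliases PotentialTrace-class
#' @exportClass PotentialTrace
setClass("PotentialTrace",
  representation(values = "numeric", dt = "numeric",
                 relayIndex = "integer", scaleNote = "character"),
  prototype(values = c(0, 0), dt = 2, relayIndex = 0L, scaleNote = "raw"))

setValidity("PotentialTrace", function(object) {
  msg <- character()
  if (length(object@values) < 2L)
    msg <- c(msg, "'values' must have length >= 2")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must all be finite")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a positive scalar")
  if (length(object@relayIndex) != 1L || object@relayIndex < 0L)
    msg <- c(msg, "'relayIndex' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' @param values,dt,relayIndex,scaleNote see the class description.
#' @rdname PotentialTrace-class
#' @export
PotentialTrace <- function(values, dt = 2, relayIndex = 0L,
                           scaleNote = "raw") {
  new("PotentialTrace", values = as.numeric(values), dt = as.numeric(dt),
      relayIndex = as.integer(relayIndex), scaleNote = as.character(scaleNote))
}

#' Amplitude thresholds of the multithreshold decoder
#'
#' The three amplitude bands of the decoder (\code{c1 > c2 > c3 > 0}) plus the
#' standard deviation \code{sigma1} of the intrinsic noise that replaces
#' sub-threshold values.  Values are in the same scaled-potential units as the
#' traces they are applied to.  Defaults are the working point used throughout
#' the relay experiments: \code{c1 = 0.0015}, \code{c2 = 0.0010},
#' \code{c3 = 0.0008}, \code{sigma1 = 2.7e-5}.
#'
#' @slot c1 numeric(1), spike amplitude: inputs at or above it are clamped to
#'   it (all-or-none level).
#' @slot c2 numeric(1), floor of the pass-through band; values in
#'   \code{[c3, c2)} are restored up to \code{c2}.
#' @slot c3 numeric(1), spike detection threshold used for binarization.
#' @slot sigma1 numeric(1) >= 0, sub-threshold noise sd.
#'
#' @examples
#' th <- DecoderThresholds()
#' decodeMultithreshold(c(0.5, 0.0012, 0.0009, 1e-5), th)
#' @name DecoderThresholds-class
#' @aliases DecoderThresholds-class
#' @exportClass DecoderThresholds
setClass("DecoderThresholds",
  representation(c1 = "numeric", c2 = "numeric", c3 = "numeric",
                 sigma1 = "numeric"),
  prototype(c1 = 0.0015, c2 = 0.0010, c3 = 0.0008, sigma1 = 2.7e-5))

setValidity("DecoderThresholds", function(object) {
  msg <- character()
  v <- c(object@c1, object@c2, object@c3, object@sigma1)
  if (length(v) != 4L || !all(is.finite(v)))
    msg <- c(msg, "all thresholds must be finite scalars")
  else {
    if (!(object@c1 > object@c2 && object@c2 > object@c3 && object@c3 > 0))
      msg <- c(msg, "thresholds must satisfy c1 > c2 > c3 > 0")
    if (object@sigma1 < 0)
      msg <- c(msg, "'sigma1' must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param c1,c2,c3,sigma1 see the class description.
#' @rdname DecoderThresholds-class
#' @export
DecoderThresholds <- function(c1 = 0.0015, c2 = 0.0010, c3 = 0.0008,
                              sigma1 = 2.7e-5) {
  new("DecoderThresholds", c1 = as.numeric(c1), c2 = as.numeric(c2),
      c3 = as.numeric(c3), sigma1 = as.numeric(sigma1))
}

#' A binarized spike train
#'
#' The 0/1 vector obtained by thresholding a trace at the spike-detection
#' threshold \code{c3}; the object compared by [successRate()].
#'
#' @slot bits integer vector with entries in \{0, 1\}.
#' @slot thresholdUsed numeric(1), the threshold that produced the bits.
#'
#' @examples
#' binarize(c(0.001, 0.0001), c3 = 0.0008)
#' @name BinarySpikeTrain-class
#' @aliases BinarySpikeTrain-class
#' @exportClass BinarySpikeTrain
setClass("BinarySpikeTrain",
  representation(bits = "integer", thresholdUsed = "numeric"),
  prototype(bits = integer(), thresholdUsed = 0.0008))

setValidity("BinarySpikeTrain", function(object) {
  if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
    "'bits' entries must be 0 or 1"
  else TRUE
})

#' @param bits,thresholdUsed see the class description.
#' @rdname BinarySpikeTrain-class
#' @export
BinarySpikeTrain <- function(bits, thresholdUsed = 0.0008) {
  new("BinarySpikeTrain", bits = as.integer(bits),
      thresholdUsed = as.numeric(thresholdUsed))
}

#' Result of propagating a stimulus through a relay chain
#'
#' Holds the per-relay traces (or only the terminal one, for long chains), the
#' decoded drives in encoder--decoder mode, the initial stimulus and the
#' propagation mode.
#'
#' @slot traces list of [PotentialTrace-class] objects, relay indices
#'   contiguous; for \code{keep = "last"} only the terminal relay is kept.
#' @slot decoderOutputs list of numeric vectors (encoder--decoder mode only);
#'   element i is the decoded drive entering relay i+1 (the last element is
#'   the decode of the terminal trace).
#' @slot initialStimulus numeric vector, the stimulus \eqn{\varepsilon_t}.
#' @slot mode character(1): "nomodulation", "all_or_none" or
#'   "encoder_decoder".
#' @slot params the [NlariParams-class] of the relay encoders.
#' @slot thresholds the [DecoderThresholds-class] used (may be absent for
#'   nomodulation).
#'
#' @name RelayChainResult-class
#' @aliases RelayChainResult-class
#' @exportClass RelayChainResult
setClass("RelayChainResult",
  representation(traces = "list", decoderOutputs = "list",
                 initialStimulus = "numeric", mode = "character",
                 params = "NlariParams", thresholds = "DecoderThresholds"))

setValidity("RelayChainResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("nomodulation", "all_or_none", "encoder_decoder"))
    msg <- c(msg, "unknown propagation mode")
  n <- length(object@initialStimulus)
  for (tr in object@traces)
    if (!is(tr, "PotentialTrace") || length(tr@values) != n)
      msg <- c(msg, "all traces must be PotentialTrace objects of the stimulus length")
  if (length(msg)) unique(msg) else TRUE
})

#' OLS estimation result for the NLARI encoder
#'
#' Trend and coefficient estimates obtained by [fitTrend()] and
#' [fitNlariOls()], with standard errors, the derived coefficients
#' \eqn{\hat\alpha = 1 - \hat\theta_1}, \eqn{\hat\beta = \hat\theta_2},
#' \eqn{\hat\gamma = \hat\beta/(4 - 2\hat\alpha)} (delta-method standard
#' error), and the waveform indicators \eqn{\eta_1} (slope of the mean line)
#' and \eqn{\eta_2 = \hat\sigma/\hat\beta} (amplitude).
#'
#' @slot aHat,bHat numeric(1), trend intercept and slope (NA when the fit was
#'   run on an already-detrended series).
#' @slot theta1Hat,theta2Hat numeric(1), OLS coefficients of the differenced
#'   regression.
#' @slot s11,s22 numeric(1), their standard errors.
#' @slot sigmaHat numeric(1), residual standard deviation.
#' @slot alphaHat,betaHat,gammaHat numeric(1), derived coefficients.
#' @slot gammaSe numeric(1), delta-method standard error of gammaHat.
#' @slot eta1,eta2 numeric(1), waveform indicators.
#' @slot nUsed integer(1), effective sample size after lag loss.
#'
#' @name EstimationResult-class
#' @aliases EstimationResult-class
#' @exportClass EstimationResult
setClass("EstimationResult",
  representation(aHat = "numeric", bHat = "numeric",
                 theta1Hat = "numeric", theta2Hat = "numeric",
                 s11 = "numeric", s22 = "numeric", sigmaHat = "numeric",
                 alphaHat = "numeric", betaHat = "numeric",
                 gammaHat = "numeric", gammaSe = "numeric",
                 eta1 = "numeric", eta2 = "numeric", nUsed = "integer"))

setValidity("EstimationResult", function(object) {
  msg <- character()
  if (any(c(object@s11, object@s22, object@sigmaHat) < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors and sigmaHat must be >= 0")
  g <- object@betaHat / (4 - 2 * object@alphaHat)
  if (is.finite(g) && is.finite(object@gammaHat) &&
      abs(g - object@gammaHat) > 1e-12 * max(1, abs(g)))
    msg <- c(msg, "gammaHat inconsistent with alphaHat and betaHat")
  if (length(msg)) msg else TRUE
})
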