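#' Parameters of the random sound-wave stimulus generator
#'
#' The high-density stimulus is a thresholded realization of the NLARI
#' process near its flip bifurcation.  Its printed parameterization is
#' internally inconsistent (alpha = 0.71 with beta = 0.70 gives a stability
#' coefficient of 0.2713, not the stated 0.97), so two resolutions are
#' offered:
#' \describe{
#'   \item{derived (default)}{treat (alpha, gamma) = (0.71, 0.97) as
#'     authoritative and set beta = gamma * (4 - 2*alpha) = 2.5026.  Only a
#'     near-critical gamma sustains the large-amplitude oscillation a sound
#'     wave requires, and every other parameter triple in the simulation
#'     protocols obeys beta = gamma * (4 - 2*alpha).}
#'   \item{printed}{take beta = 0.70 as printed (gamma becomes 0.2713).}
#' }
#'
#' @param betaMode \code{"derived"} or \code{"printed"}.
#' @param sigma drive sd of the generator (0.0011 by default).
#' @return a [NlariParams-class].
#' @examples
#' stabilityCoefficient(soundWaveParams())            # 0.97
#' stabilityCoefficient(soundWaveParams("printed"))   # 0.2713...
#' @export
soundWaveParams <- function(betaMode = c("derived", "printed"),
                            sigma = 0.0011) {
  betaMode <- match.arg(betaMode)
  alpha <- 0.71
  beta <- if (betaMode == "derived") 0.97 * (4 - 2 * alpha) else 0.70
  NlariParams(alpha = alpha, beta = beta, omega = 0, sigma = sigma)
}

#' Generate a gated sound-wave stimulus
#'
#' Simulates the NLARI sound-wave signal \eqn{Y_t} from rest and applies the
#' all-or-none gate: \eqn{\varepsilon_t = c_1} where \eqn{Y_t \ge c_1},
#' intrinsic \eqn{N(0, \sigma_1^2)} noise elsewhere.  The result is the
#' dense spike-train drive used by the reliability experiments.
#'
#' @param n stimulus length.
#' @param params generator parameters, a [NlariParams-class]
#'   ([soundWaveParams()] by default).
#' @param thresholds a [DecoderThresholds-class] supplying \code{c1} and
#'   \code{sigma1}.
#' @param seed optional integer seed.
#' @return list with \code{original} (the ungated [PotentialTrace-class])
#'   and \code{stimulus} (the gated numeric drive).
#' @examples
#' s <- generateSoundStimulus(200, seed = 1)
#' mean(s$stimulus >= 0.0015)   # supra-threshold density, strictly in (0,1)
#' @export
generateSoundStimulus <- function(n, params = soundWaveParams(),
                                  thresholds = DecoderThresholds(),
                                  seed = NULL) {
  stopifnot(n >= 2, is(params, "NlariParams"),
            is(thresholds, "DecoderThresholds"))
  if (!is.null(seed)) set.seed(seed)
  original <- simulateNlari(params, n)
  stimulus <- allOrNoneGate(original@values, thresholds)
  list(original = original, stimulus = stimulus)
}

#' Generate i.i.d. Gaussian intrinsic noise
#'
#' @param sigma1 noise sd, >= 0.
#' @param n length.
#' @param seed optional integer seed.
#' @return numeric vector of \eqn{N(0, \sigma_1^2)} draws.
#' @examples
#' generateNoise(0, 5)   # all zeros
#' @export
generateNoise <- function(sigma1, n, seed = NULL) {
  stopifnot(sigma1 >= 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (sigma1 == 0) numeric(n) else rnorm(n, 0, sigma1)
}

#' Deterministic toy spike patterns
#'
#' Small 0/1 fixtures for exercising the fidelity metrics, scaled to
#' \{0, c1\} amplitudes.
#'
#' @param pattern either a 0/1 vector, or one of \code{"alternating"},
#'   \code{"ones"}, \code{"zeros"} with length \code{n}.
#' @param n pattern length when \code{pattern} is a keyword.
#' @param c1 spike amplitude.
#' @return list with \code{train} (a [BinarySpikeTrain-class]) and
#'   \code{amplitude} (the numeric \{0, c1\} sequence).
#' @examples
#' spikeBits(generateToyBinary("alternating", 4)$train)   # 1 0 1 0
#' @export
generateToyBinary <- function(pattern, n = NULL, c1 = 0.0015) {
  if (is.character(pattern)) {
    stopifnot(!is.null(n), n >= 1)
    bits <- switch(match.arg(pattern, c("alternating", "ones", "zeros")),
                   alternating = rep_len(c(1L, 0L), n),
                   ones = rep(1L, n),
                   zeros = rep(0L, n))
  } else {
    bits <- as.integer(pattern)
    if (!all(bits %in% c(0L, 1L))) stop("'pattern' must be 0/1")
  }
  list(train = BinarySpikeTrain(bits, thresholdUsed = c1),
       amplitude = bits * c1)
}
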