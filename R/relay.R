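#' Scale a raw recording into encoder units
#'
#' Raw membrane-potential recordings (mV scale) are divided by 1000 before
#' entering the encoder so that typical excursions stay inside its
#' contractive range; the fixed point is exponentially but not globally
#' stable, and large inputs can trigger runaway responses.
#'
#' @param raw numeric vector of raw values.
#' @return numeric vector, \code{raw / 1000}.
#' @examples
#' preprocessScale(c(1000, -500))   # 1, -0.5
#' @export
preprocessScale <- function(raw) {
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  raw / 1000
}

#' Scale a trace for display
#'
#' Multiplies the values by 1e5 (the display convention for encoder and
#' decoder outputs) and records the scaling in the trace's provenance.
#'
#' @param trace a [PotentialTrace-class] or numeric vector.
#' @return object of the same kind with values multiplied by 1e5.
#' @examples
#' displayScale(0.0015)   # 150
#' @export
displayScale <- function(trace) {
  if (is(trace, "PotentialTrace")) {
    PotentialTrace(trace@values * 1e5, dt = trace@dt,
                   relayIndex = trace@relayIndex,
                   scaleNote = paste0(trace@scaleNote, " x1e5 display"))
  } else {
    as.numeric(trace) * 1e5
  }
}

#' Centre a stimulus by its running mean
#'
#' Subtracts from each point the mean of all points up to and including it:
#' \code{out[t] = x[t] - mean(x[1:t])}.  For an i.i.d. stimulus with mean
#' \eqn{\omega} the running mean converges to \eqn{\omega}, so this removes
#' the drive mean without needing to know it.
#'
#' @param series non-empty numeric vector.
#' @return centred numeric vector of the same length.
#' @examples
#' centerRunningMean(c(1, 3))   # 0, 1
#' @export
centerRunningMean <- function(series) {
  stopifnot(is.numeric(series), length(series) >= 1L)
  series - cumsum(series) / seq_along(series)
}

#' All-or-none amplitude gate
#'
#' Values at or above \code{c1} are clamped to \code{c1} (a complete
#' response); values below elicit only intrinsic noise, a fresh
#' \eqn{N(0, \sigma_1^2)} draw per point.
#'
#' @param x numeric vector of potentials.
#' @param thresholds a [DecoderThresholds-class] object.
#' @return numeric vector of gated values.
#' @examples
#' th <- DecoderThresholds(sigma1 = 0)
#' allOrNoneGate(c(0.002, 0.0015, 0), th)   # 0.0015, 0.0015, 0
#' @export
allOrNoneGate <- function(x, thresholds = DecoderThresholds()) {
  stopifnot(is(thresholds, "DecoderThresholds"), is.numeric(x))
  supra <- x >= thresholds@c1
  out <- if (thresholds@sigma1 > 0)
    rnorm(length(x), 0, thresholds@sigma1) else numeric(length(x))
  out[supra] <- thresholds@c1
  out
}

#' Multithreshold amplitude decoder
#'
#' Piecewise correction of a relay's response before it enters the next
#' encoder: over-responses at or above \code{c1} are clamped to \code{c1},
#' values in \code{[c2, c1)} pass unchanged, attenuated spikes in
#' \code{[c3, c2)} are restored up to \code{c2}, and sub-threshold values are
#' replaced by fresh \eqn{N(0, \sigma_1^2)} intrinsic noise.  Band edges are
#' half-open with \code{>=} at the top of each band.
#'
#' @param y numeric vector of relay outputs.
#' @param thresholds a [DecoderThresholds-class] object.
#' @return numeric vector of decoded drives; no decoded value exceeds
#'   \code{c1}.
#' @examples
#' th <- DecoderThresholds()            # c1 = 0.0015, c2 = 0.001, c3 = 8e-4
#' decodeMultithreshold(c(0.5, 0.0012, 0.0009), th)
#' # 0.0015, 0.0012, 0.0010
#' @export
decodeMultithreshold <- function(y, thresholds = DecoderThresholds()) {
  stopifnot(is(thresholds, "DecoderThresholds"), is.numeric(y))
  out <- if (thresholds@sigma1 > 0)
    rnorm(length(y), 0, thresholds@sigma1) else numeric(length(y))
  out[y >= thresholds@c3] <- thresholds@c2
  band <- y >= thresholds@c2 & y < thresholds@c1
  out[band] <- y[band]
  out[y >= thresholds@c1] <- thresholds@c1
  out
}

#' Propagate a stimulus through a chain of relay encoders
#'
#' Runs the stimulus through \code{m} relays, each an NLARI encoder started
#' at rest (\eqn{Y_{i,-1} = Y_{i,0} = 0}), with one of three couplings
#' between consecutive relays:
#' \describe{
#'   \item{nomodulation}{relay i >= 2 is driven by the raw output of relay
#'     i-1.  Responses typically grow with \code{m}: the encoder's gain
#'     amplifies impulses, which is the over-response that modulation exists
#'     to prevent.}
#'   \item{all_or_none}{each relay's drive is gated by [allOrNoneGate()]:
#'     supra-threshold points are clamped to \code{c1}, the rest become
#'     intrinsic noise.  Over-response is prevented but attenuated spikes are
#'     lost.}
#'   \item{encoder_decoder}{each relay's output passes through
#'     [decodeMultithreshold()] before driving the next relay; the initial
#'     stimulus is gated first.  This is the error-correcting propagator.}
#' }
#'
#' @param stimulus numeric vector (the drive \eqn{\varepsilon_t}) or a
#'   [PotentialTrace-class].
#' @param params [NlariParams-class] of the relay encoders.
#' @param m number of relays, >= 1.
#' @param mode coupling between relays, see above.
#' @param thresholds [DecoderThresholds-class]; required for the modulated
#'   modes.
#' @param keep \code{"all"} stores every relay's trace and drive (memory
#'   scales with \code{m * n}); \code{"last"} keeps only the terminal relay.
#' @param seed optional integer seed for the sub-threshold noise draws.
#' @return a [RelayChainResult-class].
#' @examples
#' p <- NlariParams(alpha = 0.875, beta = 0.7481)     # gamma = 0.3325
#' th <- DecoderThresholds(sigma1 = 0)
#' stim <- c(rep(0, 5), rep(0.0015, 3), rep(0, 5), 0.0015, rep(0, 6))
#' res <- propagateChain(stim, p, m = 6, mode = "encoder_decoder",
#'                       thresholds = th)
#' successRate(binarize(stim, th@c3), binarize(finalTrace(res), th@c3))
#' @export
propagateChain <- function(stimulus, params, m,
                           mode = c("nomodulation", "all_or_none",
                                    "encoder_decoder"),
                           thresholds = DecoderThresholds(),
                           keep = c("all", "last"), seed = NULL) {
  mode <- match.arg(mode)
  keep <- match.arg(keep)
  if (is(stimulus, "PotentialTrace")) stimulus <- stimulus@values
  stopifnot(is.numeric(stimulus), length(stimulus) >= 1L,
            is(params, "NlariParams"), m >= 0,
            is(thresholds, "DecoderThresholds"))
  if (!is.null(seed)) set.seed(seed)
  if (m == 0) {
    # degenerate chain: identity on the (gated) stimulus
    drive <- if (mode == "nomodulation") stimulus
             else allOrNoneGate(stimulus, thresholds)
    return(new("RelayChainResult",
               traces = list(PotentialTrace(drive, relayIndex = 0L,
                                            scaleNote = "gated stimulus")),
               decoderOutputs = list(), initialStimulus = stimulus,
               mode = mode, params = params, thresholds = thresholds))
  }
  modeCode <- match(mode, c("nomodulation", "all_or_none", "encoder_decoder")) - 1L
  res <- cpp_chain(stimulus, params@alpha, params@beta, as.integer(m),
                   modeCode, thresholds@c1, thresholds@c2, thresholds@c3,
                   thresholds@sigma1, keep == "all")
  if (keep == "all") {
    traces <- lapply(seq_len(m), function(i)
      PotentialTrace(res$traces[[i]], relayIndex = i,
                     scaleNote = "chain output"))
    decOut <- if (mode == "encoder_decoder")
      c(res$drives[-1L], list(res$decoded)) else list()
  } else {
    traces <- list(PotentialTrace(res$final, relayIndex = as.integer(m),
                                  scaleNote = "chain output"))
    decOut <- if (mode == "encoder_decoder") list(res$decoded) else list()
  }
  new("RelayChainResult", traces = traces, decoderOutputs = decOut,
      initialStimulus = stimulus, mode = mode, params = params,
      thresholds = thresholds)
}

#' Terminal trace of a relay chain
#'
#' @param result a [RelayChainResult-class].
#' @return the [PotentialTrace-class] of the last relay.
#' @export
finalTrace <- function(result) {
  stopifnot(is(result, "RelayChainResult"))
  result@traces[[length(result@traces)]]
}
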