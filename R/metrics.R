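#' Binarize a trace at the spike-detection threshold
#'
#' Bit t is 1 iff the value is at or above \code{c3} (boundary inclusive).
#'
#' @param series numeric vector or [PotentialTrace-class].
#' @param c3 spike-detection threshold, > 0.
#' @return a [BinarySpikeTrain-class].
#' @examples
#' spikeBits(binarize(c(0.001, 0.0001), c3 = 0.0008))   # 1 0
#' @export
binarize <- function(series, c3 = 0.0008) {
  if (is(series, "PotentialTrace")) series <- series@values
  stopifnot(is.numeric(series), is.numeric(c3), length(c3) == 1L, c3 > 0)
  BinarySpikeTrain(as.integer(series >= c3), thresholdUsed = c3)
}

#' Propagation success rate of a spike train
#'
#' The percentage of positions where the binarized final output agrees with
#' the binarized initial input:
#' \deqn{r(m, n) = \left[1 - \frac{(v_m - v_0)^\top (v_m - v_0)}{n}\right]
#'       \times 100\%}
#' On 0/1 vectors the quadratic form is the Hamming distance, so the rate is
#' computed as an exact disagreement count.  100 means complete fidelity,
#' 0 complete distortion.
#'
#' @param v0 initial spike train: a [BinarySpikeTrain-class] or 0/1 vector.
#' @param vm final spike train of the same length.
#' @return the success rate in percent.
#' @examples
#' successRate(c(1, 0, 1, 0), c(1, 0, 1, 1))   # 75
#' @export
successRate <- function(v0, vm) {
  b0 <- if (is(v0, "BinarySpikeTrain")) v0@bits else as.integer(v0)
  bm <- if (is(vm, "BinarySpikeTrain")) vm@bits else as.integer(vm)
  if (!all(b0 %in% c(0L, 1L)) || !all(bm %in% c(0L, 1L)))
    stop("spike trains must be 0/1 vectors")
  if (length(b0) != length(bm))
    stop("spike trains must have equal length")
  if (length(b0) < 1L) stop("spike trains must be non-empty")
  100 * (1 - sum(b0 != bm) / length(b0))
}

#' Network-level propagation success rate
#'
#' A minicolumn delivers the same train to \code{h} receiving neurons; the
#' circuit succeeds only if every line does, so the network rate is the
#' single-neuron rate raised to the h-th power:
#' \eqn{100 \cdot (r/100)^h}.  Precision decays exponentially in \code{h},
#' which is why parallel delivery demands near-perfect single-neuron
#' fidelity.
#'
#' @param r single-neuron success rate in percent, in \code{[0, 100]}.
#' @param h number of receiving neurons, >= 1.
#' @return network success rate in percent.
#' @examples
#' networkSuccessRate(99.99, 1000)   # 90.48...
#' @export
networkSuccessRate <- function(r, h) {
  stopifnot(is.numeric(r), is.numeric(h), all(r >= 0 & r <= 100), all(h >= 1))
  100 * (r / 100)^h
}

#' First-order outcome probabilities under single-neuron transfer mistakes
#'
#' A synchronous spike event (SSE) delivers one thalamic train to \code{h}
#' receiving neurons, each through \code{m} relays; a relay can shift a
#' spike's timing (probability \code{ps}), raise a spurious spike (\code{pi})
#' or lose a spike (\code{pd}).  The first-order (single-mistake) outcome
#' probabilities are:
#' \describe{
#'   \item{entire_overlap}{all receivers get the same train: output rate up
#'     to h-fold with probability \code{h*m*ps}; up to (h+1)-fold with
#'     \code{h*m*pi}; rate decrease with \code{(m*pd)^h}.}
#'   \item{entire_nonoverlap}{receivers get disjoint trains: shape-preserving
#'     shift with \code{m*ps}; up to 2-fold rate with \code{m*pi}; decrease
#'     with \code{m*pd}.}
#' }
#' These linear approximations are equal to expected mistake counts, so they
#' can exceed 1 for large \code{h*m*p}; such values are clipped to 1 with a
#' warning.
#'
#' @param h receiving-neuron count, >= 1.
#' @param m relay count, >= 1.
#' @param ps,pi,pd mistake probabilities per relay, each in \code{[0, 1]}.
#' @param overlap \code{"entire_overlap"} or \code{"entire_nonoverlap"}.
#' @return named numeric vector of the three outcome probabilities.
#' @examples
#' sseOutcomeProbabilities(h = 3, m = 5, ps = 0.05, pi = 0.05, pd = 0.05,
#'                         overlap = "entire_overlap")
#' @export
sseOutcomeProbabilities <- function(h, m, ps, pi, pd,
                                    overlap = c("entire_overlap",
                                                "entire_nonoverlap")) {
  overlap <- match.arg(overlap)
  stopifnot(h >= 1, m >= 1,
            all(c(ps, pi, pd) >= 0), all(c(ps, pi, pd) <= 1))
  out <- if (overlap == "entire_overlap")
    c(rate_up_to_h_fold = h * m * ps,
      rate_up_to_h_plus_1_fold = h * m * pi,
      rate_decrease = (m * pd)^h)
  else
    c(shift_unchanged_shape = m * ps,
      rate_up_to_2_fold = m * pi,
      rate_decrease = m * pd)
  if (any(out > 1)) {
    warning("first-order approximation exceeds 1; clipping to [0, 1]")
    out <- pmin(out, 1)
  }
  out
}

#' Upper bound on the summed waiting time of scattered spike trains
#'
#' A thalamic train with \code{p} spikes at equal 1/p ms intervals is
#' scattered into sparser trains whose least interspike interval is enlarged
#' \code{q} times (\code{1 <= q <= p-1}).  With 1 ms per-spike processing
#' each train holds at most p/q spikes waiting at most \code{1 - q/p} ms, so
#' the summed waiting time is bounded by
#' \eqn{(p/q)(1 - q/p) = p/q - 1} ms.  Scattering (larger \code{q}) shortens
#' the wait roughly q-fold.
#'
#' @param p spike count of the thalamic train, integer >= 2.
#' @param q interval-enlargement factor, integer in \code{[1, p-1]}.
#' @return the bound \code{p/q - 1} in ms.
#' @examples
#' waitingTimeBound(6, 1)   # 5
#' waitingTimeBound(6, 5)   # 0.2
#' @export
waitingTimeBound <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L,
            p == round(p), q == round(q), p >= 2)
  if (q < 1 || q > p - 1)
    stop("'q' must lie in [1, p - 1]")
  p / q - 1
}
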