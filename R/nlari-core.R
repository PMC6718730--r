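#' Bounded odd restoring force
#'
#' The nonlinear restoring term \eqn{-\beta y e^{-y^2}} that pulls a perturbed
#' membrane potential back towards rest.  It is odd in \code{y} and bounded by
#' \eqn{\beta/\sqrt{2e}} in absolute value, so large excursions feel a weaker
#' pull than moderate ones: the fixed point is exponentially asymptotically
#' stable but not globally stable.
#'
#' @param y potential deviation(s), numeric.
#' @param beta restoration coefficient, numeric scalar.
#' @return numeric of the same length as \code{y}.
#' @examples
#' restoringForce(0, 0.7)          # 0
#' restoringForce(1, 1)            # -exp(-1)
#' @export
restoringForce <- function(y, beta) {
  stopifnot(is.numeric(y), is.numeric(beta), length(beta) == 1L)
  -beta * y * exp(-y^2)
}

#' One step of the NLARI recursion
#'
#' \deqn{Y_t = (2-\alpha) Y_{t-1} - (1-\alpha) Y_{t-2}
#'       - \beta Y_{t-1} e^{-Y_{t-1}^2} + \varepsilon_t}
#'
#' @param y1 value one step back (\eqn{Y_{t-1}}).
#' @param y2 value two steps back (\eqn{Y_{t-2}}).
#' @param params a [NlariParams-class] object.
#' @param eps drive at the current step.
#' @return the next value \eqn{Y_t}.
#' @examples
#' nlariStep(0, 0, NlariParams(0.71, 0.7), 0)   # the origin is a fixed point
#' @export
nlariStep <- function(y1, y2, params, eps = 0) {
  stopifnot(is(params, "NlariParams"))
  (2 - params@alpha) * y1 - (1 - params@alpha) * y2 +
    restoringForce(y1, params@beta) + eps
}

#' Simulate an NLARI membrane-potential trace
#'
#' Iterates the recursion from initial values \eqn{(Y_{-1}, Y_0)} (both zero
#' by default, the resting state).  The drive is either an explicit numeric
#' vector (its first \code{n} values are used) or i.i.d. Gaussian noise with
#' the mean \code{omega} and sd \code{sigma} stored in \code{params}, drawn
#' from R's RNG (seed it with [set.seed()] or the \code{seed} argument for
#' reproducibility).
#'
#' Trajectories whose magnitude exceeds 1e10 abort with a diagnostic naming
#' the step: this signals parameters outside the contractive regime for the
#' given stimulus scale.
#'
#' @param params a [NlariParams-class] object.
#' @param n number of steps to simulate (>= 2 so the result is a valid trace).
#' @param initial numeric(2), \eqn{(Y_{-1}, Y_0)}.
#' @param noise optional explicit drive vector of length >= n.
#' @param seed optional integer; when given, [set.seed()] is called first.
#' @param dt sampling step in ms.
#' @return a [PotentialTrace-class] of length \code{n}.
#' @examples
#' p <- NlariParams(alpha = 0.71, beta = 0.5 * (4 - 2 * 0.71))  # gamma = 0.5
#' tr <- simulateNlari(p, 200, initial = c(0.1, 0.1))
#' abs(traceValues(tr)[200]) < 1e-8   # decay to the stable fixed point
#' @export
simulateNlari <- function(params, n, initial = c(0, 0), noise = NULL,
                          seed = NULL, dt = 2) {
  stopifnot(is(params, "NlariParams"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise)) {
    noise <- if (params@sigma > 0 || params@omega != 0)
      rnorm(n, mean = params@omega, sd = params@sigma) else numeric(n)
  } else {
    if (length(noise) < n) stop("'noise' must supply at least n values")
    noise <- as.numeric(noise[seq_len(n)])
  }
  stopifnot(length(initial) == 2L, all(is.finite(initial)))
  # initial = (Y_{-1}, Y_0): Y_0 is the most recent value
  values <- cpp_nlari_recursion(noise, params@alpha, params@beta,
                                initial[2L], initial[1L])
  if (n == 1L) values <- c(initial[2L], values)  # pad to a valid trace
  PotentialTrace(values, dt = dt, relayIndex = 0L, scaleNote = "simulated")
}

#' Classify the deterministic regime by the stability coefficient
#'
#' Partition of \eqn{\gamma > 0}: \code{stable_fixed_point} on (0, 1),
#' \code{stable_period2} on \eqn{[1, e)}, \code{unstable_cycles} on
#' \eqn{[e, 3.07)} and \code{chaos} on \eqn{[3.07, \infty)}.  Boundary points
#' belong to the right-hand regime; the choice is documented and arbitrary
#' (see the methods vignette).
#'
#' @param gamma stability coefficient, a positive scalar.
#' @return character(1) label with the classifying \code{gamma} attached as
#'   attribute \code{"gamma"}.
#' @examples
#' classifyRegime(0.5)   # stable_fixed_point
#' classifyRegime(2.0)   # stable_period2
#' classifyRegime(4.0)   # chaos
#' @export
classifyRegime <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma <= 0) stop("'gamma' must be > 0")
  label <- if (gamma < 1) "stable_fixed_point"
  else if (gamma < exp(1)) "stable_period2"
  else if (gamma < 3.07) "unstable_cycles"
  else "chaos"
  structure(label, gamma = gamma)
}

#' Amplitude of the deterministic period-2 cycle
#'
#' Beyond the flip bifurcation at \eqn{\gamma = 1} the noise-free map settles
#' on an alternating cycle \eqn{(-1)^t a} with \eqn{a = \sqrt{\ln\gamma}}:
#' the alternating fixed amplitude solves \eqn{e^{-a^2} = 1/\gamma}.  The
#' amplitude is 0 at the bifurcation and strictly increasing in \eqn{\gamma}.
#'
#' @param gamma stability coefficient, >= 1.
#' @return the cycle amplitude \eqn{\sqrt{\ln\gamma}}.
#' @examples
#' period2Amplitude(exp(1))   # 1
#' period2Amplitude(1.5)      # 0.636772...
#' @export
period2Amplitude <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma < 1) stop("no period-2 cycle for gamma < 1")
  sqrt(log(gamma))
}
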