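#' Fit and remove a linear time trend
#'
#' Ordinary least squares of the raw trace on time,
#' \eqn{X_t = a + b t + u_t} with \eqn{t = 1, \ldots, n}.  Under the NLARI
#' model with Gaussian drive the conditional mean line is
#' \eqn{X_0 + (\omega/\alpha) t}, so the fitted slope estimates the waveform
#' slope indicator \eqn{\eta_1 = \omega/\alpha} and the residuals are the
#' detrended deviations \eqn{Y_t} that enter [fitNlariOls()].
#'
#' @param x numeric vector or [PotentialTrace-class], length >= 3.
#' @return list with \code{aHat}, \code{bHat}, and \code{detrended} (the
#'   residual series \eqn{Y_t}).
#' @examples
#' fitTrend(2 + 0.5 * (1:10))[c("aHat", "bHat")]   # 2, 0.5
#' @export
fitTrend <- function(x) {
  if (is(x, "PotentialTrace")) x <- x@values
  stopifnot(is.numeric(x), length(x) >= 3L, all(is.finite(x)))
  t <- seq_along(x)
  fit <- lm(x ~ t)
  list(aHat = unname(coef(fit)[1L]), bHat = unname(coef(fit)[2L]),
       detrended = unname(residuals(fit)))
}

#' Estimate the NLARI coefficients by ordinary least squares
#'
#' The recursion is rearranged into a no-intercept regression of the first
#' difference on its own lag and the restoring regressor:
#' \deqn{\Delta Y_t = \theta_1 \Delta Y_{t-1}
#'       + \theta_2 \left(-Y_{t-1} e^{-Y_{t-1}^2}\right) + \varepsilon_t}
#' with \eqn{\theta_1 = 1 - \alpha} and \eqn{\theta_2 = \beta}.  The first
#' two observations are lost to the lags (\code{nUsed = n - 2}).  The
#' intercept is absorbed by detrending, so pass a detrended series (from
#' [fitTrend()]) that has been scaled into encoder units
#' ([preprocessScale()]) when it comes from a raw recording.
#'
#' The derived estimates are \eqn{\hat\alpha = 1 - \hat\theta_1},
#' \eqn{\hat\beta = \hat\theta_2}, and
#' \eqn{\hat\gamma = \hat\theta_2 / (2 + 2\hat\theta_1)} with a delta-method
#' standard error from the OLS covariance of \eqn{(\hat\theta_1,
#' \hat\theta_2)}.  The amplitude indicator \eqn{\eta_2 =
#' \hat\sigma/\hat\beta} is filled in; the slope indicator \eqn{\eta_1}
#' comes from the trend fit and can be supplied via \code{bHat}.
#'
#' @param y detrended trace, numeric vector or [PotentialTrace-class],
#'   length >= 10.
#' @param aHat,bHat optional trend estimates to carry into the result (from
#'   [fitTrend()]).
#' @return an [EstimationResult-class].
#' @examples
#' p <- NlariParams(alpha = 0.71, beta = 0.7, sigma = 0.001)
#' y <- traceValues(simulateNlari(p, 5000, seed = 1))
#' fitNlariOls(y)
#' @export
fitNlariOls <- function(y, aHat = NA_real_, bHat = NA_real_) {
  if (is(y, "PotentialTrace")) y <- y@values
  stopifnot(is.numeric(y), length(y) >= 10L, all(is.finite(y)))
  n <- length(y)
  # rows t = 3..n: response dY_t, regressors dY_{t-1} and -Y_{t-1} e^{-Y^2}
  dy <- diff(y)
  resp <- dy[-1L]
  x1 <- dy[-(n - 1L)]
  ylag <- y[2:(n - 1L)]
  x2 <- -ylag * exp(-ylag^2)
  X <- cbind(dY_lag = x1, restoring = x2)
  xtx <- crossprod(X)
  if (!is.finite(rcond <- rcond(xtx)) || rcond < 1e-14)
    stop("singular design: the trace carries no usable variation ",
         "(e.g. identically zero)")
  fit <- lm(resp ~ X - 1)
  th <- unname(coef(fit))
  nUsed <- n - 2L
  sigmaHat <- sqrt(sum(residuals(fit)^2) / (nUsed - 2L))
  V <- sigmaHat^2 * solve(xtx)
  se <- sqrt(diag(V))
  alphaHat <- 1 - th[1L]
  betaHat <- th[2L]
  denom <- 2 + 2 * th[1L]               # = 4 - 2*alphaHat
  gammaHat <- betaHat / denom
  grad <- c(-2 * betaHat / denom^2, 1 / denom)
  gammaSe <- sqrt(drop(t(grad) %*% V %*% grad))
  new("EstimationResult",
      aHat = aHat, bHat = bHat,
      theta1Hat = th[1L], theta2Hat = th[2L],
      s11 = se[1L], s22 = se[2L], sigmaHat = sigmaHat,
      alphaHat = alphaHat, betaHat = betaHat,
      gammaHat = gammaHat, gammaSe = gammaSe,
      eta1 = bHat,
      eta2 = if (betaHat > 0) sigmaHat / betaHat else NA_real_,
      nUsed = nUsed)
}

#' Fit the full waveform model to a raw trace
#'
#' Convenience wrapper: scales a raw recording into encoder units, removes
#' the linear trend, fits the NLARI coefficients on the detrended series and
#' carries the trend slope into the waveform indicators.
#'
#' @param x raw trace, numeric vector or [PotentialTrace-class].
#' @param scale divide by 1000 first (set \code{FALSE} if \code{x} is
#'   already in encoder units).
#' @return an [EstimationResult-class].
#' @export
fitWaveform <- function(x, scale = TRUE) {
  if (is(x, "PotentialTrace")) x <- x@values
  if (scale) x <- preprocessScale(x)
  tr <- fitTrend(x)
  fitNlariOls(tr$detrended, aHat = tr$aHat, bHat = tr$bHat)
}

#' Waveform indicators of a fitted trace
#'
#' The slope indicator \eqn{\eta_1 = \omega/\alpha} (drift of the mean line,
#' estimated by the trend slope) and the amplitude indicator
#' \eqn{\eta_2 = \sigma/\beta} (fluctuation scale).  A positive/negative
#' \eqn{\eta_1} reflects an upward/downward drift; a large \eqn{\eta_2}
#' reflects high-amplitude fluctuation.
#'
#' @param est an [EstimationResult-class] with \code{betaHat > 0}.
#' @return named numeric vector \code{c(eta1, eta2)}.
#' @export
waveformIndicators <- function(est) {
  stopifnot(is(est, "EstimationResult"))
  if (!is.finite(est@betaHat) || est@betaHat <= 0)
    stop("amplitude indicator undefined for betaHat <= 0")
  c(eta1 = est@eta1, eta2 = est@sigmaHat / est@betaHat)
}

#' Test whether a fitted encoder sits in the stable fixed-point range
#'
#' The theoretical parameter intervals for a stable fixed point are
#' \eqn{\theta_1 \in (-1, 1)} (equivalently \eqn{\alpha \in (0, 2)}),
#' \eqn{\theta_2 \in (0, 4)} and \eqn{\gamma \in (0, 1)}.  The verdict is
#' \code{TRUE} iff each large-sample confidence interval
#' \eqn{\hat\theta \pm z_0 \cdot se} lies entirely inside its interval.
#'
#' @param est an [EstimationResult-class].
#' @param z0 critical value; 2.576 (99 percent, two-sided) by default, 1.645 for
#'   the one-tailed 5 percent case.
#' @return list with the overall \code{verdict} and per-parameter logicals
#'   \code{theta1InRange}, \code{theta2InRange}, \code{gammaInRange}.
#' @examples
#' p <- NlariParams(alpha = 0.71, beta = 0.7, sigma = 0.001)
#' y <- traceValues(simulateNlari(p, 20000, seed = 1))
#' testStableFixedPoint(fitNlariOls(y))$verdict
#' @export
testStableFixedPoint <- function(est, z0 = 2.576) {
  stopifnot(is(est, "EstimationResult"), is.numeric(z0), z0 > 0)
  inOpen <- function(lo, hi, a, b) is.finite(lo) && is.finite(hi) &&
    lo > a && hi < b
  t1 <- inOpen(est@theta1Hat - z0 * est@s11,
               est@theta1Hat + z0 * est@s11, -1, 1)
  t2 <- inOpen(est@theta2Hat - z0 * est@s22,
               est@theta2Hat + z0 * est@s22, 0, 4)
  tg <- inOpen(est@gammaHat - z0 * est@gammaSe,
               est@gammaHat + z0 * est@gammaSe, 0, 1)
  list(verdict = t1 && t2 && tg,
       theta1InRange = t1, theta2InRange = t2, gammaInRange = tg)
}
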