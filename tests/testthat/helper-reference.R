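# Plain-R reference implementations, independent of the compiled recursion.
# Used as oracles: slow, direct transcriptions of the update rules.

refNlari <- function(eps, alpha, beta, y1 = 0, y2 = 0) {
  out <- numeric(length(eps))
  for (t in seq_along(eps)) {
    yt <- (2 - alpha) * y1 - (1 - alpha) * y2 -
      beta * y1 * exp(-y1^2) + eps[t]
    out[t] <- yt
    y2 <- y1
    y1 <- yt
  }
  out
}

refDecode <- function(y, c1, c2, c3) {
  # noise-free decoder (sigma1 = 0): sub-threshold becomes 0
  ifelse(y >= c1, c1, ifelse(y >= c2, y, ifelse(y >= c3, c2, 0)))
}

refGate <- function(x, c1) ifelse(x >= c1, c1, 0)

# noise-free chain, all three couplings
refChain <- function(stim, alpha, beta, m, mode, c1, c2, c3) {
  drive <- if (mode == "nomodulation") stim else refGate(stim, c1)
  for (i in seq_len(m)) {
    y <- refNlari(drive, alpha, beta)
    if (i < m)
      drive <- switch(mode,
                      nomodulation = y,
                      all_or_none = refGate(y, c1),
                      encoder_decoder = refDecode(y, c1, c2, c3))
  }
  y
}

gridParams <- function(k) {
  gamma <- 0.0133 * k
  alpha <- 1 - 0.005 * k
  NlariParams(alpha = alpha, beta = gamma * (4 - 2 * alpha))
}

# sparse low-density spike drive in {0, c1}
sparseStimulus <- function(n, spikesAt, c1 = 0.0015) {
  s <- numeric(n)
  s[spikesAt] <- c1
  s
}
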