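test_that("scaling helpers compose as documented", {
  expect_equal(preprocessScale(rep(1000, 4)), rep(1, 4))
  expect_identical(preprocessScale(numeric(0)), numeric(0))
  expect_equal(displayScale(0.0015), 150)
  expect_equal(displayScale(0), 0)
  expect_equal(displayScale(preprocessScale(1)), 100)     # 1e5 / 1000
  tr <- displayScale(PotentialTrace(c(0.001, 0.002), scaleNote = "raw/1000"))
  expect_equal(traceValues(tr), c(100, 200))
  expect_match(tr@scaleNote, "x1e5 display")
})

test_that("running-mean centring removes the drive mean", {
  expect_equal(centerRunningMean(rep(3.2, 10)), rep(0, 10))
  expect_equal(centerRunningMean(c(1, 3)), c(0, 1))
  set.seed(11)
  x <- rnorm(20000, mean = 5, sd = 1)
  expect_lt(abs(mean(centerRunningMean(x))), 0.05)
})

test_that("all-or-none gate clamps supra-threshold values and mutes the rest", {
  th0 <- DecoderThresholds(sigma1 = 0)
  expect_equal(allOrNoneGate(c(0.002, 0.0015, 0.00149, 0), th0),
               c(0.0015, 0.0015, 0, 0))
  set.seed(1)
  g <- allOrNoneGate(rep(0, 1000), DecoderThresholds(sigma1 = 2.7e-5))
  expect_equal(sd(g), 2.7e-5, tolerance = 0.1)
  expect_true(all(g < 0.0015))
})

test_that("the multithreshold decoder maps each band as printed", {
  th0 <- DecoderThresholds(sigma1 = 0)
  # clamp, pass-through, floor, noise branches at the working thresholds
  expect_equal(decodeMultithreshold(0.5, th0), 0.0015)
  expect_equal(decodeMultithreshold(0.0015, th0), 0.0015)  # >= c1 inclusive
  expect_equal(decodeMultithreshold(0.0012, th0), 0.0012)
  expect_equal(decodeMultithreshold(0.0010, th0), 0.0010)  # >= c2 inclusive
  expect_equal(decodeMultithreshold(0.0009, th0), 0.0010)
  expect_equal(decodeMultithreshold(0.0008, th0), 0.0010)  # >= c3 inclusive
  expect_equal(decodeMultithreshold(0.00079, th0), 0)
  expect_equal(decodeMultithreshold(-1, th0), 0)
})

test_that("decoded drives never exceed c1 and stay in the allowed set", {
  th <- DecoderThresholds(sigma1 = 2.7e-5)
  set.seed(3)
  y <- c(rnorm(500, 0, 0.002), rnorm(500, 0, 1e-4))
  d <- decodeMultithreshold(y, th)
  expect_true(all(d <= th@c1))
  sub <- y < th@c3
  expect_true(all(d[!sub] >= th@c2))           # corrected values in [c2, c1]
  expect_true(all(abs(d[sub]) < th@c3))        # noise stays sub-threshold
})

test_that("a one-relay nomodulation chain is the plain encoder", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  set.seed(5)
  stim <- rnorm(150, 0, 0.001)
  res <- propagateChain(stim, p, m = 1, mode = "nomodulation")
  expect_identical(traceValues(finalTrace(res)),
                   traceValues(simulateNlari(p, 150, noise = stim)))
})

test_that("zero stimulus with sigma1 = 0 stays at rest in every mode", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  th0 <- DecoderThresholds(sigma1 = 0)
  for (mode in c("nomodulation", "all_or_none", "encoder_decoder")) {
    res <- propagateChain(numeric(50), p, m = 4, mode = mode,
                          thresholds = th0, keep = "all")
    for (tr in chainTraces(res))
      expect_identical(traceValues(tr), rep(0, 50))
  }
})

test_that("the compiled chain agrees with the R reference in all modes", {
  th0 <- DecoderThresholds(sigma1 = 0)
  set.seed(9)
  for (mode in c("nomodulation", "all_or_none", "encoder_decoder")) {
    for (rep in 1:3) {
      stim <- sample(c(0, 0.0005, 0.0012, 0.0015, 0.003), 80, replace = TRUE)
      p <- gridParams(sample(10:60, 1))
      m <- sample(1:5, 1)
      res <- propagateChain(stim, p, m = m, mode = mode, thresholds = th0)
      expect_equal(traceValues(finalTrace(res)),
                   refChain(stim, p@alpha, p@beta, m, mode,
                            th0@c1, th0@c2, th0@c3),
                   tolerance = 1e-12)
    }
  }
})

test_that("nomodulation amplifies across relays on a spiky drive", {
  p <- NlariParams(alpha = 0.71, beta = 0.7)
  stim <- sparseStimulus(600, seq(20, 580, by = 25))
  peak <- vapply(c(3, 10, 17), function(m) {
    max(abs(traceValues(finalTrace(
      propagateChain(stim, p, m = m, mode = "nomodulation")))))
  }, 0)
  expect_true(all(diff(peak) > 0))
  expect_gt(peak[3] / max(abs(stim)), 10)
})

test_that("all-or-none gating can only lose spikes without the decoder", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  th0 <- DecoderThresholds(sigma1 = 0)
  stim <- sparseStimulus(300, c(10, 40, 41, 90, 150, 250))
  res <- propagateChain(stim, p, m = 8, mode = "all_or_none",
                        thresholds = th0, keep = "all")
  supra <- vapply(chainTraces(res),
                  function(tr) sum(traceValues(tr) >= th0@c1), 0L)
  expect_true(all(diff(supra) <= 0))
})

test_that("noise-free encoder-decoder round trip preserves binarization", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)    # gamma = 0.3325
  th0 <- DecoderThresholds(sigma1 = 0)
  set.seed(21)
  for (m in c(1, 3, 6, 12)) {
    stim <- sample(c(0, 0.0015), 200, replace = TRUE, prob = c(0.6, 0.4))
    res <- propagateChain(stim, p, m = m, mode = "encoder_decoder",
                          thresholds = th0)
    expect_equal(successRate(binarize(stim, th0@c3),
                             binarize(finalTrace(res), th0@c3)), 100)
  }
})

test_that("a zero-length chain is the identity on the gated stimulus", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  th0 <- DecoderThresholds(sigma1 = 0)
  stim <- c(0, 0.002, 0.0015, 0.0004)
  res <- propagateChain(stim, p, m = 0, mode = "encoder_decoder",
                        thresholds = th0)
  expect_equal(traceValues(finalTrace(res)), c(0, 0.0015, 0.0015, 0))
})

test_that("chains are reproducible and overflow reports relay and step", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  th <- DecoderThresholds(sigma1 = 2.7e-5)
  stim <- sparseStimulus(100, c(5, 30, 60))
  a <- traceValues(finalTrace(propagateChain(stim, p, m = 5,
                                             mode = "encoder_decoder",
                                             thresholds = th, seed = 77)))
  b <- traceValues(finalTrace(propagateChain(stim, p, m = 5,
                                             mode = "encoder_decoder",
                                             thresholds = th, seed = 77)))
  expect_identical(a, b)
  bad <- NlariParams(alpha = 4, beta = 0.1)
  expect_error(propagateChain(rep(0.01, 400), bad, m = 2,
                              mode = "nomodulation"),
               "relay .*step|overflow")
})

test_that("decoder outputs are stored per relay in encoder-decoder mode", {
  p <- NlariParams(alpha = 0.875, beta = 0.7481)
  th0 <- DecoderThresholds(sigma1 = 0)
  stim <- sparseStimulus(60, c(10, 30))
  res <- propagateChain(stim, p, m = 3, mode = "encoder_decoder",
                        thresholds = th0, keep = "all")
  expect_length(chainTraces(res), 3)
  expect_length(decoderOutputs(res), 3)
  # stored decode of relay i matches decoding its stored trace
  for (i in 1:3)
    expect_equal(decoderOutputs(res)[[i]],
                 decodeMultithreshold(traceValues(chainTraces(res)[[i]]), th0))
})
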