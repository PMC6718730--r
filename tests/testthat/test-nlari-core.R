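test_that("restoring force has the closed form, odd symmetry and bound", {
  expect_identical(restoringForce(0, 0.7), 0)
  expect_equal(restoringForce(1, 1), -exp(-1))
  y <- seq(-3, 3, by = 0.17)
  expect_equal(restoringForce(-y, 1.3), -restoringForce(y, 1.3))
  expect_true(all(abs(restoringForce(y, 1.3)) <= 1.3 / sqrt(2 * exp(1)) + 1e-12))
})

test_that("a single step matches hand evaluation and fixes the origin", {
  p <- NlariParams(alpha = 0.71, beta = 1.29)
  expect_equal(nlariStep(0.1, 0.1, p, 0), 0.1 - 1.29 * 0.1 * exp(-0.01))
  expect_equal(nlariStep(0.1, 0.1, p, 0), -0.0277164, tolerance = 1e-5)
  expect_identical(nlariStep(0, 0, NlariParams(1.3, 2.2), 0), 0)
})

test_that("the linearized map loses stability exactly at gamma = 1", {
  # characteristic polynomial lambda^2 - (2 - alpha - beta) lambda + (1 - alpha)
  for (alpha in c(0.3, 0.71, 1.2)) {
    betaCrit <- 4 - 2 * alpha            # gamma = 1
    charAtMinus1 <- 1 + (2 - alpha - betaCrit) + (1 - alpha)
    expect_equal(charAtMinus1, 0)
    expect_equal(stabilityCoefficient(alpha, betaCrit), 1)
  }
})

test_that("stability coefficient reproduces the printed parameter pairs", {
  expect_equal(round(stabilityCoefficient(0.71, 0.7), 4), 0.2713)
  expect_equal(round(stabilityCoefficient(0.8750, 0.7481), 4), 0.3325)
  expect_equal(stabilityCoefficient(1, 2), 1)
  expect_equal(stabilityCoefficient(NlariParams(0.71, 0.7)),
               stabilityCoefficient(0.71, 0.7))
  expect_error(stabilityCoefficient(2, 1), "alpha = 2")
})

test_that("noise-free trajectories contract to the fixed point for gamma < 1", {
  for (g in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    p <- NlariParams(alpha = 0.71, beta = g * (4 - 2 * 0.71))
    y <- traceValues(simulateNlari(p, 500, initial = c(0.1, 0.1)))
    expect_lt(abs(y[500]), 1e-6)
  }
  p <- NlariParams(alpha = 0.71, beta = 0.5 * (4 - 2 * 0.71))
  expect_lt(abs(traceValues(simulateNlari(p, 200, initial = c(0.1, 0.1)))[200]),
            1e-8)
  # zero initials stay at rest
  expect_identical(traceValues(simulateNlari(p, 50)), rep(0, 50))
})

test_that("the period-2 branch appears at gamma > 1 with amplitude sqrt(log(gamma))", {
  # the cycle attracts generic initial conditions while gamma < sqrt(e)
  for (g in c(1.2, 1.5)) {
    p <- NlariParams(alpha = 0.71, beta = g * (4 - 2 * 0.71))
    y <- traceValues(simulateNlari(p, 10100, initial = c(0.1, 0.1)))
    tailY <- tail(y, 6)
    expect_true(all(abs(diff(sign(tailY))) == 2))   # strict alternation
    expect_equal(abs(tailY), rep(period2Amplitude(g), 6), tolerance = 1e-5)
    expect_lt(max(abs(abs(tailY) - sqrt(log(g)))), 1e-5)
  }
  # beyond sqrt(e) the cycle repels, but +/- sqrt(log(gamma)) is still the
  # exact period-2 orbit: started on it, the map stays on it
  for (g in c(2.0, 2.5)) {
    a <- period2Amplitude(g)
    p <- NlariParams(alpha = 0.71, beta = g * (4 - 2 * 0.71))
    y <- traceValues(simulateNlari(p, 10, initial = c(a, -a)))
    expect_equal(abs(y), rep(a, 10), tolerance = 1e-5)
    expect_true(all(abs(diff(sign(y))) == 2))
    # one exact step maps -a back to +a
    expect_equal(nlariStep(-a, a, p, 0), a, tolerance = 1e-12)
  }
  # just below the bifurcation the same initial condition decays instead
  p <- NlariParams(alpha = 0.71, beta = 0.999 * (4 - 2 * 0.71))
  expect_lt(abs(tail(traceValues(simulateNlari(p, 20000,
                                               initial = c(0.1, 0.1))), 1)),
            1e-3)
})

test_that("period-2 amplitude endpoints and domain", {
  expect_equal(period2Amplitude(exp(1)), 1)
  expect_equal(period2Amplitude(1), 0)
  expect_equal(period2Amplitude(1.5), 0.6367614, tolerance = 1e-6)
  g <- seq(1.1, 3, by = 0.2)
  expect_true(all(diff(vapply(g, period2Amplitude, 0)) > 0))
  expect_error(period2Amplitude(0.9), "no period-2")
})

test_that("the step agrees with its linearization in the small-signal limit", {
  p <- NlariParams(alpha = 0.8, beta = 1.1)
  for (y1 in c(1e-3, -1e-3, 5e-4)) {
    for (y2 in c(1e-3, -5e-4)) {
      full <- nlariStep(y1, y2, p, 0)
      lin <- (2 - p@alpha - p@beta) * y1 - (1 - p@alpha) * y2
      # relative to the state scale: the cubic correction is beta * y^3
      expect_lt(abs(full - lin), 1e-5 * max(abs(c(y1, y2))))
    }
  }
})

test_that("simulation is bit-identical under a fixed seed and matches the R oracle", {
  p <- NlariParams(alpha = 0.71, beta = 0.7, sigma = 0.0011)
  a <- traceValues(simulateNlari(p, 300, seed = 42))
  b <- traceValues(simulateNlari(p, 300, seed = 42))
  expect_identical(a, b)
  set.seed(7)
  eps <- rnorm(200, 0, 0.001)
  expect_equal(traceValues(simulateNlari(p, 200, noise = eps)),
               refNlari(eps, 0.71, 0.7))
})

test_that("runaway trajectories abort with the step index", {
  p <- NlariParams(alpha = 4, beta = 0.1)   # explosive linear part
  expect_error(simulateNlari(p, 500, initial = c(0.1, 0.1)),
               "overflow at step")
})

test_that("regimes partition by gamma with boundaries on the right", {
  expect_identical(as.character(classifyRegime(0.5)), "stable_fixed_point")
  expect_identical(as.character(classifyRegime(2.0)), "stable_period2")
  expect_identical(as.character(classifyRegime(4.0)), "chaos")
  expect_identical(as.character(classifyRegime(1)), "stable_period2")
  expect_identical(as.character(classifyRegime(exp(1))), "unstable_cycles")
  expect_identical(as.character(classifyRegime(3.07)), "chaos")
  expect_identical(attr(classifyRegime(0.25), "gamma"), 0.25)
  expect_error(classifyRegime(0), "> 0")
  expect_error(classifyRegime(-1), "> 0")
})

test_that("parameter and trace classes enforce their invariants", {
  expect_error(NlariParams(alpha = 0.7, beta = -1), "beta")
  expect_error(PotentialTrace(c(1, NA)), "finite")
  expect_error(PotentialTrace(1), "length")
  expect_error(DecoderThresholds(c1 = 0.001, c2 = 0.0015), "c1 > c2 > c3")
  expect_error(BinarySpikeTrain(c(0L, 2L)), "0 or 1")
})
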