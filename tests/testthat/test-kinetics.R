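tm8 <- seq(1, 30, length.out = 8)

test_that("evalModel evaluates the two-exponential form and validates input", {
  # all dynamics zero: offset only
  expect_equal(evalModel(c(0, 1, 0, 1, 1), 10), 1.0)
  # decaying term vanishes at large t
  expect_equal(evalModel(c(0, 1, 0.3, 4, 0.9), 1e6), 0.9, tolerance = 1e-12)
  # frozen independent hand evaluation:
  # 0.02*5*exp(-5/8) + 0.1*exp(-5/15) + 0.95
  expect_equal(evalModel(c(0.02, 8, 0.1, 15, 0.95), 5), 1.07517927,
               tolerance = 1e-7)
  # uptake variant saturates to x3 + x5
  expect_equal(evalModel(c(0, 1, 0.3, 4, 0.9), 1e6, variant = "uptake"), 1.2,
               tolerance = 1e-12)
  expect_error(evalModel(c(0, NA, 0, 1, 1), 1), "finite")
  expect_error(evalModel(c(0, -1, 0, 1, 1), 1), "time constants")
  expect_error(evalModel(c(0, 1, 0, 1, 1), -2), ">= 0")
})

test_that("normalizeCurve divides by the first frame and flags dead baselines", {
  tm <- seq(1, 30, length.out = 8)
  raw <- c(100, 110, 120, 118, 116, 114, 112, 110)
  nc <- normalizeCurve(raw, tm)
  expect_true(nc$fittable)
  expect_identical(nc$values[1], 1)
  expect_equal(nc$values, raw / 100)
  # constant curve: all ones
  expect_equal(normalizeCurve(rep(7, 8), tm)$values, rep(1, 8))
  # degenerate baseline: flagged, not an exception
  dead <- normalizeCurve(c(0, raw[-1]), tm)
  expect_false(dead$fittable)
  expect_null(dead$values)
})

test_that("fitVoxel recovers noiseless curves exactly (r2 = 1, derived params within 1%)", {
  truth <- c(0.02, 8, 0.1, 15, 0.95)
  y <- evalModel(truth, tm8)
  fit <- fitVoxel(y, tm8)
  expect_true(isConverged(fit))
  expect_equal(fitR2(fit), 1, tolerance = 1e-6)
  w <- c(tm8[1], tm8[8])
  expect_equal(fitDyn(fit), computeDyn(truth, w), tolerance = 0.01)
  expect_equal(fitTT(fit), computeTT(truth, w), tolerance = 0.01)
  expect_equal(fitAOT(fit), computeAOT(truth, w), tolerance = 0.01)
})

test_that("fitVoxel on a constant curve reports no enhancement", {
  fit <- fitVoxel(rep(1, 8), tm8)
  expect_true(isConverged(fit))
  expect_lt(fitDyn(fit), 1e-6)
  expect_equal(fitTT(fit), 0)
  expect_equal(fitAOT(fit), 0)
})

test_that("a poorly fitting voxel is retained with its low r2, not discarded", {
  # seeded noise curve: the fit exists and converges, r2 simply ends up low,
  # leaving exclusion to the downstream r2 > 0.6 filter
  set.seed(40)
  repeat {
    y <- c(1, 1 + rnorm(7, 0, 0.02))
    fit <- fitVoxel(y, tm8)
    if (fitR2(fit) < 0.6) break
  }
  expect_true(isConverged(fit))
  expect_lt(fitR2(fit), 0.6)
  expect_true(is.finite(fitDyn(fit)))
})

test_that("fitVoxel supports the uptake model variant", {
  ctl <- kineticsControl(modelVariant = "uptake")
  truth <- c(0.01, 12, 0.15, 8, 1)
  y <- evalModel(truth, tm8, variant = "uptake")
  fit <- fitVoxel(y, tm8, control = ctl)
  expect_equal(fitR2(fit), 1, tolerance = 1e-6)
  w <- c(tm8[1], tm8[8])
  expect_equal(fitDyn(fit),
               computeDyn(truth, w, variant = "uptake"), tolerance = 0.01)
})

test_that("fitVoxel validates its inputs", {
  expect_error(fitVoxel(rep(1, 5), seq(1, 30, length.out = 5)), "at least 7")
  expect_error(fitVoxel(c(1, -1, rep(1, 6)), tm8), "> 0")
  expect_error(fitVoxel(normalizeCurve(c(0, rep(1, 7)), tm8)), "unfittable")
})

test_that("computeDyn matches a dense-grid maximum oracle and is never negative", {
  w <- c(1, 30)
  # flat fitted curve
  expect_equal(computeDyn(c(0, 1, 0, 1, 1), w), 0)
  # monotone rising 1 + 0.2 (1 - exp(-t/5)) == -0.2 exp(-t/5) + 1.2
  p <- c(0, 1, -0.2, 5, 1.2)
  tg <- seq(1, 30, length.out = 1e5)
  fv <- -0.2 * exp(-tg / 5) + 1.2
  oracle <- 100 * (max(fv) - fv[1])
  expect_equal(computeDyn(p, w), oracle, tolerance = 1e-4)
  expect_gte(computeDyn(c(0.01, 5, 0.3, 3, 0.7), w), 0)
})

test_that("computeTT measures time above threshold", {
  w <- c(1, 30)
  # never reaches 1.05
  expect_equal(computeTT(c(0, 1, 0, 1, 1.02), w), 0)
  # constant 1.10 over a 29-min window
  expect_equal(computeTT(c(0, 1, 0, 1, 1.10), w), 29)
  # hump with analytic crossings vs root-finding oracle, within a grid step
  p <- c(0.05, 6, 0, 10, 1)
  step <- 29 / 999
  expect_lt(abs(computeTT(p, w) - ttRootOracle(p, w)), step + 1e-9)
})

test_that("computeAOT matches rectangles and fine-grid quadrature", {
  # at threshold exactly: zero area
  expect_equal(computeAOT(c(0, 1, 0, 1, 1.05), c(1, 30)), 0)
  # constant 1.15 over a 20-min window: (0.15 - 0.05) * 20 = 2
  expect_equal(computeAOT(c(0, 1, 0, 1, 1.15), c(5, 25)), 2, tolerance = 1e-9)
  # generic parameter set vs trapezoid oracle
  p <- c(0.03, 10, 0.05, 8, 0.98)
  expect_equal(computeAOT(p, c(1, 30)), aotTrapzOracle(p, c(1, 30)),
               tolerance = 1e-3)
})

test_that("TT and AOT are monotone in the threshold and coupled to Dyn", {
  w <- c(tm8[1], tm8[8])
  L <- diff(w)
  params <- randomKineticParams(25, tm8, seed = 421)
  for (p in params) {
    t1 <- computeTT(p, w, threshold = 0.05)
    t2 <- computeTT(p, w, threshold = 0.10)
    a1 <- computeAOT(p, w, threshold = 0.05)
    a2 <- computeAOT(p, w, threshold = 0.10)
    expect_lte(t2, t1 + 1e-12)
    expect_lte(a2, a1 + 1e-12)
    dyn <- computeDyn(p, w)
    if (dyn > 5)
      expect_lte(a1, (dyn / 100 - 0.05) * L + 1e-9)
    if (t1 == 0) expect_equal(a1, 0)
  }
})
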