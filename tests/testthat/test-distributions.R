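test_that("buildHistograms bins BBBo voxels and conserves counts", {
  d <- c(10, 10, 1)
  mask <- array(FALSE, d); mask[1:100] <- TRUE
  maps <- makeMaps(d, dynVals = 10, r2Vals = 0.9, idx = 1:100)
  # hand-binnable AOT values: 30 at 0.5, 30 at 1.5, 40 at 3.0
  maps@aot[1:100] <- rep(c(0.5, 1.5, 3.0), times = c(30, 30, 40))
  bbbo <- makeBBBo(mask)
  hs <- buildHistograms(maps, bbbo,
                        breaks = list(aot = c(0, 1, 2, 4)))
  expect_identical(hs@histograms$aot$counts, c(30L, 30L, 40L))
  # conservation across every parameter and any binning
  for (nm in c("dyn", "tt", "aot"))
    expect_equal(sum(hs@histograms[[nm]]$counts), 100L)
  fine <- buildHistograms(maps, bbbo, binWidths = c(dyn = 1, tt = 1, aot = 0.1))
  for (nm in c("dyn", "tt", "aot"))
    expect_equal(sum(fine@histograms[[nm]]$counts), 100L)
})

test_that("an empty BBBo mask yields all-zero histograms", {
  d <- c(6, 6, 2)
  maps <- makeMaps(d)
  hs <- buildHistograms(maps, makeBBBo(array(FALSE, d)))
  for (nm in c("dyn", "tt", "aot")) {
    expect_true(all(hs@histograms[[nm]]$counts == 0))
  }
  expect_equal(hs@nVoxels, 0L)
})

test_that("averageHistograms returns bin-wise mean and SEM across subjects", {
  d <- c(4, 4, 4)
  mk <- function(vals) {
    n <- length(vals)
    maps <- makeMaps(d, dynVals = 10, r2Vals = 0.9, idx = seq_len(n))
    maps@aot[seq_len(n)] <- vals
    mask <- array(FALSE, d); mask[seq_len(n)] <- TRUE
    buildHistograms(maps, makeBBBo(mask),
                    binWidths = c(dyn = 2.5, tt = 2.5, aot = 1))
  }
  h1 <- mk(c(0.5, 0.5, 1.5))        # counts 2, 1
  h2 <- mk(c(0.5, 1.5, 1.5, 1.5))   # counts 1, 3
  avg <- averageHistograms(list(h1, h2), "aot")
  expect_equal(avg$mean, c(1.5, 2))
  expect_equal(avg$sem, c(sd(c(2, 1)) / sqrt(2), sd(c(1, 3)) / sqrt(2)))
})

test_that("fitExponential recovers noiseless decay and rejects sparse input", {
  centers <- seq(0.1, 3.9, by = 0.2)
  counts <- 1000 * exp(-centers / 1)
  fit <- fitExponential(counts, centers)
  expect_equal(fit@amplitude, 1000, tolerance = 1e-6)
  expect_equal(fit@tau, 1, tolerance = 1e-6)
  expect_gte(fit@r2, 1 - 1e-9)
  expect_error(fitExponential(c(0, 10, 0, 0), 1:4), "3 nonempty")
  expect_error(fitExponential(c(5, 7), c(1, 2)), "3 nonempty")
})

test_that("fitExponential recovers the scale of a seeded exponential sample", {
  set.seed(42)
  tau <- 1.4
  x <- rexp(30000, rate = 1 / tau)
  edges <- seq(0, ceiling(max(x)) + 0.2, by = 0.2)
  counts <- tabulate(findInterval(x, edges), nbins = length(edges) - 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  fit <- fitExponential(counts, centers)
  expect_equal(fit@tau, tau, tolerance = 0.1)
})

test_that("cumulativeFraction behaves like an empirical CDF", {
  v <- c(0.2, 0.5, 0.9, 1.4, 3.2)
  expect_equal(cumulativeFraction(v, 0.1), 0)
  expect_equal(cumulativeFraction(v, 10), 100)
  expect_equal(cumulativeFraction(v, 1), 60)
  # nondecreasing in the threshold
  th <- seq(0, 4, by = 0.25)
  fr <- vapply(th, function(t) cumulativeFraction(v, t), 1.0)
  expect_true(all(diff(fr) >= 0))
  expect_error(cumulativeFraction(numeric(0), 1), "empty")
})

test_that("empirical cumulative fractions of seeded exponential samples track the CDF", {
  set.seed(7)
  lam <- calibrateExponentialRate(50.4, 0.6)
  n <- 40000
  x <- rexp(n, lam)
  for (th in c(0.6, 1, 2, 4)) {
    expect_equal(cumulativeFraction(x, th), exponentialCdfPercent(th, lam),
                 tolerance = 3 / sqrt(n) * 100 / exponentialCdfPercent(th, lam))
  }
})

test_that("the calibrated exponential AOT model reproduces its anchor and tail", {
  lam <- calibrateExponentialRate(50.4, 0.6)
  # the anchor is reproduced exactly
  expect_equal(exponentialCdfPercent(0.6, lam), 50.4, tolerance = 1e-12)
  # the far tail: ~99% of voxels below AOT 4
  expect_equal(round(exponentialCdfPercent(4, lam)), 99)
  expect_error(calibrateExponentialRate(120, 0.6), "percentBelow")
  expect_error(calibrateExponentialRate(50, -1), "threshold")
})
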