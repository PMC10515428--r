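smallSpec <- function(...) {
  phantomSpec(dim = c(24, 24, 24), nClusters = 2, clusterRadii = c(2.5, 3),
              noiseSigma = 0, seed = 42, ...)
}

test_that("phantom generation is a pure function of spec and seed", {
  a <- generatePhantom(smallSpec())
  b <- generatePhantom(smallSpec())
  expect_identical(seriesArray(a$series), seriesArray(b$series))
  expect_identical(bbboMask(a$truth), bbboMask(b$truth))
  c <- generatePhantom(phantomSpec(dim = c(24, 24, 24), nClusters = 2,
                                   clusterRadii = c(2.5, 3), noiseSigma = 0,
                                   seed = 43))
  expect_false(identical(seriesArray(a$series), seriesArray(c$series)))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generatePhantom(smallSpec())); after <- runif(1)
  expect_identical(before, after)
})

test_that("phantom truth bookkeeping matches its own cluster table", {
  ph <- generatePhantom(phantomSpec(dim = c(32, 32, 32), nClusters = 3,
                                    clusterRadii = c(2.5, 3, 3.5),
                                    noiseSigma = 0, seed = 7))
  tab <- clusterTable(ph$truth)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$nVoxels >= 30))
  expect_true(all(tab$isBBBo))
  expect_equal(sum(bbboMask(ph$truth)), sum(tab$nVoxels))
  expect_true(all(tab$dyn >= 6 & tab$dyn <= 30))
  # every enhancing voxel sits inside the brain
  expect_true(all(brainMask(ph$truth)[bbboMask(ph$truth)]))
})

test_that("kinetics applied to noiseless phantom curves reproduces the truth maps", {
  ph <- generatePhantom(smallSpec())
  cl <- which(bbboMask(ph$truth))
  pick <- cl[seq(1, length(cl), length.out = 5)]
  arr <- seriesArray(ph$series)
  d <- dim(arr)
  tm <- acquisitionTimes(ph$series)
  mat <- matrix(arr, nrow = prod(d[1:3]))
  for (i in pick) {
    nc <- normalizeCurve(mat[i, ], tm)
    fit <- fitVoxel(nc)
    expect_equal(fitDyn(fit), dynMap(ph$truth)[i], tolerance = 1e-6)
    expect_equal(fitTT(fit), ttMap(ph$truth)[i], tolerance = 1e-6)
    expect_equal(fitAOT(fit), aotMap(ph$truth)[i], tolerance = 1e-6)
  }
})

test_that("sham phantoms have an empty truth mask and only small components", {
  sham <- generateShamPhantom(phantomSpec(dim = c(32, 32, 32), nClusters = 0,
                                          clusterRadii = numeric(0),
                                          nSham = 15, noiseSigma = 0,
                                          seed = 9))
  expect_equal(sum(bbboMask(sham$truth)), 0)
  tab <- clusterTable(sham$truth)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$nVoxels < 30))
  expect_true(all(!tab$isBBBo))
  # enhancing blobs exist in the series even though none qualifies as BBBo
  expect_gt(sum(tab$nVoxels), 0)
  expect_error(generateShamPhantom(phantomSpec(nClusters = 2)),
               "nClusters = 0")
})

test_that("a cluster that cannot fit inside the brain is a spec error", {
  expect_error(generatePhantom(phantomSpec(dim = c(16, 16, 16), nClusters = 1,
                                           clusterRadii = 20)),
               "does not fit")
})

test_that("generateDoseResponse produces the exact 4PL surface at zero noise", {
  plate <- generateDoseResponse(trueIc50 = 7.1, hill = 1, top = 95,
                                bottom = 5, noiseSd = 0, seed = 1)
  mu <- 5 + 90 / (1 + plate$concentration_nM / 7.1)
  expect_equal(plate$confluence_pct, mu)
  expect_equal(sum(plate$concentration_nM == plate$concentration_nM[1]), 6)
  a <- generateDoseResponse(seed = 4); b <- generateDoseResponse(seed = 4)
  expect_identical(a, b)
  expect_error(generateDoseResponse(trueIc50 = 7.1,
                                    concentrations = c(100, 300, 900, 2700)),
               "span the transition")
})

test_that("generateEfficacyCohort reproduces its group structure", {
  sd0 <- generateEfficacyCohort(sdRates = c(0, 0), sdBaselines = c(0, 0),
                                seed = 2)
  r <- growthRate(sd0$v_baseline_mm3, sd0$v_day8_mm3)
  expect_equal(r[sd0$group == "combined"], rep(1.18, 5))
  expect_equal(r[sd0$group == "doxoOnly"], rep(2.6, 5))
  expect_equal(sd0$v_baseline_mm3[sd0$group == "combined"], rep(8.09, 5))
  a <- generateEfficacyCohort(seed = 5); b <- generateEfficacyCohort(seed = 5)
  expect_identical(a, b)
  expect_named(a, c("mouse_id", "group", "v_baseline_mm3", "v_day8_mm3"))
})
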