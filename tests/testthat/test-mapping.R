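test_that("labelComponents agrees with the flood-fill oracle", {
  set.seed(42)
  for (i in 1:8) {
    d <- sample(6:12, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.25, d)
    for (conn in c(26, 6)) {
      lab <- labelComponents(m, conn)
      expect_identical(sort(lab$sizes), sort(floodFillSizes(m, conn)))
      expect_equal(sum(lab$labels > 0), sum(m))
    }
  }
})

test_that("labelComponents handles edge cases", {
  m <- array(FALSE, c(3, 3, 3))
  expect_length(labelComponents(m)$sizes, 0)
  m[] <- TRUE
  expect_identical(labelComponents(m)$sizes, 27L)
  # two corner voxels touch diagonally under 26- but not 6-connectivity
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_identical(labelComponents(m, 26)$sizes, 2L)
  expect_identical(sort(labelComponents(m, 6)$sizes), c(1L, 1L))
})

test_that("classifyBBBo applies r2, Dyn and cluster-size filters", {
  d <- c(20, 20, 5)
  # a 40-voxel block and a 12-voxel block, both enhancing and well fitted
  blockA <- which(array(slice.index(array(0, d), 1) %in% 1:4 &
                        slice.index(array(0, d), 2) %in% 1:5 &
                        slice.index(array(0, d), 3) %in% 1:2, d))
  blockB <- which(array(slice.index(array(0, d), 1) %in% 15:17 &
                        slice.index(array(0, d), 2) %in% 15:18 &
                        slice.index(array(0, d), 3) == 5, d))
  idx <- c(blockA, blockB)
  maps <- makeMaps(d, dynVals = 20, r2Vals = 0.9, idx = idx)
  res <- classifyBBBo(maps)
  expect_equal(nVoxels(res), 40L)
  expect_equal(nrow(clusterTable(res)), 1L)
  expect_equal(clusterTable(res)$nVoxels, 40L)

  # good Dyn but poor fit: excluded by the r2 filter
  maps2 <- makeMaps(d, dynVals = 20, r2Vals = 0.5, idx = blockA)
  expect_equal(nVoxels(classifyBBBo(maps2)), 0L)
  # strong fit but sub-threshold Dyn (e.g. 4%): excluded regardless of size
  maps3 <- makeMaps(d, dynVals = 4, r2Vals = 0.95, idx = blockA)
  expect_equal(nVoxels(classifyBBBo(maps3)), 0L)
  # all-zero dyn map
  maps4 <- makeMaps(d, dynVals = 0, r2Vals = 0.95, idx = idx)
  res4 <- classifyBBBo(maps4)
  expect_equal(nVoxels(res4), 0L)
  expect_equal(nrow(clusterTable(res4)), 0L)
})

test_that("classification conserves counts and is monotone in its thresholds", {
  set.seed(43)
  for (i in 1:5) {
    d <- c(16, 16, 8)
    n <- prod(d)
    idx <- which(runif(n) < 0.4)
    maps <- makeMaps(d, dynVals = runif(length(idx), 0, 15),
                     r2Vals = runif(length(idx), 0.3, 1), idx = idx)
    base <- classifyBBBo(maps, minCluster = 5)
    expect_equal(nVoxels(base), sum(clusterTable(base)$nVoxels))
    expect_true(all(clusterTable(base)$nVoxels >= 5))
    expect_equal(volumeMm3(base),
                 nVoxels(base) * prod(voxelDims(maps)))
    # raising any threshold never increases the count
    expect_lte(nVoxels(classifyBBBo(maps, r2Min = 0.8, minCluster = 5)),
               nVoxels(base))
    expect_lte(nVoxels(classifyBBBo(maps, dynMin = 8, minCluster = 5)),
               nVoxels(base))
    expect_lte(nVoxels(classifyBBBo(maps, minCluster = 10)), nVoxels(base))
  }
})

test_that("bbboVolume multiplies voxel count by voxel volume", {
  d <- c(10, 10, 10)
  idx <- 1:40
  maps <- makeMaps(d, dynVals = 20, r2Vals = 0.9, idx = idx)
  res <- classifyBBBo(maps, minCluster = 1)
  expect_equal(bbboVolume(res), 40 * 0.39 * 0.39 * 0.4)
  expect_equal(bbboVolume(res, dims = c(1, 1, 1)), 40)
  # 30 voxels at the acquisition resolution are ~1.83 mm^3
  expect_equal(30 * prod(c(0.39, 0.39, 0.4)), 1.8252, tolerance = 1e-9)
  empty <- classifyBBBo(makeMaps(d))
  expect_equal(bbboVolume(empty), 0)
})

test_that("groupRatio rounds the treated/sham fold and guards division", {
  expect_equal(groupRatio(1785, 62.5), 29)
  expect_equal(groupRatio(5, 5), 1)
  expect_error(groupRatio(100, 0), "undefined")
})

test_that("fitBrain respects the mask and recovers phantom kinetics", {
  ph <- generatePhantom(phantomSpec(dim = c(20, 20, 20), nClusters = 1,
                                    clusterRadii = 2.5, noiseSigma = 0,
                                    seed = 11))
  brain <- brainMask(ph$truth)
  maps <- fitBrain(ph$series, brain)
  expect_identical(dim(fittedMask(maps)), dim(brain))
  # out-of-mask voxels are absent from the maps
  expect_true(all(is.na(dynMap(maps)[!fittedMask(maps)])))
  expect_true(all(!fittedMask(maps)[!brain]))
  # cluster voxels match ground truth within 1%
  cl <- bbboMask(ph$truth)
  expect_true(any(cl))
  expect_equal(dynMap(maps)[cl], dynMap(ph$truth)[cl], tolerance = 0.01)
  expect_equal(aotMap(maps)[cl], aotMap(ph$truth)[cl], tolerance = 0.01)
  # background fits are flat
  bg <- brain & !cl
  expect_lt(max(dynMap(maps)[bg]), 1e-6)
  # a mask excluding the cluster leaves the cluster unfitted
  maps2 <- fitBrain(ph$series, brain & !cl)
  expect_true(all(!fittedMask(maps2)[cl]))
  # empty mask: empty maps, no error
  maps3 <- fitBrain(ph$series, array(FALSE, dim(brain)))
  expect_equal(sum(fittedMask(maps3)), 0)
})

test_that("air voxels with no baseline are excluded as unfittable", {
  ph <- generatePhantom(phantomSpec(dim = c(16, 16, 16), nClusters = 0,
                                    clusterRadii = numeric(0),
                                    noiseSigma = 0, seed = 3))
  wholeGrid <- array(TRUE, dim(brainMask(ph$truth)))
  maps <- fitBrain(ph$series, wholeGrid)
  expect_identical(fittedMask(maps), brainMask(ph$truth))
})

test_that("registerSeries recovers identity and known translations", {
  # smooth blob phantom, 3 frames
  d <- c(20, 20, 20)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  blob <- array(exp(-((g$x - 10.5)^2 + (g$y - 10.5)^2 + (g$z - 10.5)^2) / 30), d)
  vd <- c(0.5, 0.5, 0.5)
  tm <- seq(1, 30, length.out = 8)

  arr <- array(0, c(d, 8))
  for (f in 1:8) arr[, , , f] <- blob
  # frame 3: content shifted by exactly +2 voxels along x
  shifted <- array(0, d)
  shifted[3:d[1], , ] <- blob[1:(d[1] - 2), , ]
  arr[, , , 3] <- shifted

  reg <- registerSeries(DceSeries(arr, tm, vd))
  tr <- attr(reg, "transforms")
  # aligned frames: identity within 0.05 voxel / 0.05 degrees
  ident <- tr[c(2, 4:8), ]
  expect_lt(max(abs(as.matrix(ident[, c("tx", "ty", "tz")]) / vd[1])), 0.05)
  expect_lt(max(abs(as.matrix(ident[, c("rx", "ry", "rz")]))), 0.05)
  # the shifted frame: translation recovered within 0.2 voxel of (2, 0, 0)
  expect_lt(abs(tr$tx[3] / vd[1] - 2), 0.2)
  expect_lt(abs(tr$ty[3] / vd[2]), 0.2)
  expect_lt(abs(tr$tz[3] / vd[3]), 0.2)
  # the realigned frame resembles the reference
  expect_gt(cor(as.vector(seriesArray(reg)[, , , 3]), as.vector(blob)), 0.999)
  # frame 1 is untouched
  expect_identical(seriesArray(reg)[, , , 1], blob)

  # a single-frame series cannot even be constructed: the container
  # requires the minimum number of post-contrast time points
  expect_error(DceSeries(array(blob, c(d, 1)), 15), "at least 7")
})
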