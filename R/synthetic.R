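#' @include kinetics.R
NULL

#' Specification of a synthetic DCE phantom
#'
#' Describes a mouse-brain-like phantom: an ellipsoidal brain inside a
#' rectangular grid, cortically placed spherical enhancement clusters with
#' slow-accumulation kinetics, optional small isolated enhancing blobs
#' (below the minimal cluster size, the sham pattern), and Gaussian noise
#' on the normalized signal.
#'
#' The defaults emulate the study conditions: the acquisition's zero-filled
#' voxel size, 8 frames within 1--30 min post injection, clusters whose
#' voxel counts total roughly the reported treated-group BBBo count, Dyn
#' between 6 and 30 percent, and 2 percent signal noise.
#'
#' @param dim Grid dimensions (voxels).
#' @param voxelDims Voxel edge lengths, mm.
#' @param times Acquisition times, minutes post injection (>= 7 frames).
#' @param brainAxesFrac Ellipsoid semi-axes as fractions of the grid dims.
#' @param nClusters Number of enhancing clusters.
#' @param clusterRadii Sphere radii in voxels (recycled to
#'   \code{nClusters}).
#' @param dynRange Accepted range of true cluster Dyn, percent.
#' @param nSham Number of isolated enhancing blobs (each below the minimal
#'   cluster size).
#' @param shamSize Integer range of blob sizes in voxels.
#' @param noiseSigma Gaussian noise SD on the normalized signal
#'   (dimensionless; the baseline frame is the noiseless normalization
#'   reference, so noise applies from the second frame on).
#' @param baseline Raw intensity assigned to normalized value 1.
#' @param seed Generator seed; a fixed seed gives byte-identical output.
#' @return A validated list of class \code{"phantomSpec"}.
#' @export
phantomSpec <- function(dim = c(64L, 64L, 64L),
                        voxelDims = c(0.39, 0.39, 0.4),
                        times = seq(1, 30, length.out = 8),
                        brainAxesFrac = c(0.42, 0.42, 0.42),
                        nClusters = 4L,
                        clusterRadii = c(4, 5, 4.5, 5.5),
                        dynRange = c(6, 30),
                        nSham = 0L,
                        shamSize = c(1L, 5L),
                        noiseSigma = 0.02,
                        baseline = 1000,
                        seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L))
  .checkVoxelDims(voxelDims)
  .checkTimes(times)
  stopifnot(length(brainAxesFrac) == 3L, all(brainAxesFrac > 0),
            all(brainAxesFrac <= 0.5))
  stopifnot(nClusters >= 0L, nSham >= 0L, noiseSigma >= 0, baseline > 0,
            length(dynRange) == 2L, dynRange[1L] > 5, dynRange[2L] > dynRange[1L])
  if (nClusters > 0L)
    clusterRadii <- rep_len(clusterRadii, nClusters)
  spec <- list(dim = dim, voxelDims = as.numeric(voxelDims),
               times = as.numeric(times),
               brainAxesFrac = as.numeric(brainAxesFrac),
               nClusters = as.integer(nClusters),
               clusterRadii = clusterRadii,
               dynRange = as.numeric(dynRange),
               nSham = as.integer(nSham),
               shamSize = as.integer(shamSize),
               noiseSigma = noiseSigma, baseline = baseline,
               seed = as.integer(seed))
  class(spec) <- "phantomSpec"
  spec
}

.ellipsoidMask <- function(dim, axesFrac) {
  ctr <- (dim + 1) / 2
  ax <- axesFrac * dim
  x <- (seq_len(dim[1L]) - ctr[1L]) / ax[1L]
  y <- (seq_len(dim[2L]) - ctr[2L]) / ax[2L]
  z <- (seq_len(dim[3L]) - ctr[3L]) / ax[3L]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

## draw one slow-accumulation parameter set with f(t1) = 1 and true Dyn in
## range (rejection sampling; deterministic under the caller's seed)
.drawClusterParams <- function(times, dynRange, maxTries = 2000L) {
  t1 <- times[1L]
  window <- c(t1, times[length(times)])
  for (i in seq_len(maxTries)) {
    x1 <- stats::runif(1, 0.005, 0.08)
    x2 <- stats::runif(1, 8, 25)
    x3 <- stats::runif(1, -0.08, 0.08)
    x4 <- stats::runif(1, 5, 25)
    x5 <- 1 - x1 * t1 * exp(-t1 / x2) - x3 * exp(-t1 / x4)
    if (x5 < 0.5) next
    p <- c(x1, x2, x3, x4, x5)
    dyn <- computeDyn(p, window)
    if (dyn >= dynRange[1L] && dyn <= dynRange[2L]) return(p)
  }
  stop("could not draw cluster kinetics in the requested Dyn range")
}

.sphereVoxels <- function(center, radius, dim) {
  rng <- function(c, d) max(1L, floor(c - radius)):min(d, ceiling(c + radius))
  g <- expand.grid(x = rng(center[1L], dim[1L]),
                   y = rng(center[2L], dim[2L]),
                   z = rng(center[3L], dim[3L]))
  keep <- (g$x - center[1L])^2 + (g$y - center[2L])^2 +
          (g$z - center[3L])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

## cortical placement: center as far out radially as full containment of
## the sphere allows, capped at 0.85 of the ellipsoid radius
.placeClusters <- function(spec, maxTries = 500L) {
  dim <- spec$dim
  ctr <- (dim + 1) / 2
  ax <- spec$brainAxesFrac * dim
  placed <- list()
  for (k in seq_len(spec$nClusters)) {
    r <- spec$clusterRadii[k]
    rho <- min(0.85, 1 - (r + 1.5) / min(ax))
    if (rho <= 0) stop("cluster radius ", r, " does not fit inside the brain")
    ok <- FALSE
    for (i in seq_len(maxTries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      center <- ctr + rho * ax * u
      far <- all(vapply(placed, function(p)
        sqrt(sum((p$center - center)^2)) >= p$radius + r + 3, TRUE))
      if (far) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", spec$nClusters,
                  " non-touching clusters; reduce their number or size")
    placed[[k]] <- list(center = center, radius = r)
  }
  placed
}

.placeShamBlobs <- function(spec, avoid, maxTries = 2000L) {
  dim <- spec$dim
  ctr <- (dim + 1) / 2
  ax <- spec$brainAxesFrac * dim
  blobs <- list()
  off6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(spec$nSham)) {
    size <- sample(spec$shamSize[1L]:spec$shamSize[2L], 1L)
    ok <- FALSE
    for (i in seq_len(maxTries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rho <- stats::runif(1, 0, 0.8)
      center <- round(ctr + rho * ax * u)
      far <- all(vapply(avoid, function(p)
        sqrt(sum((p$center - center)^2)) >= p$radius + 4, TRUE))
      if (far) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place sham blobs away from clusters")
    vox <- matrix(center, 1L, 3L)
    while (nrow(vox) < size) {
      base <- vox[sample(nrow(vox), 1L), ]
      cand <- base + off6[sample(6L, 1L), ]
      if (any(cand < 1L) || any(cand > dim)) next
      if (!any(vox[, 1L] == cand[1L] & vox[, 2L] == cand[2L] &
               vox[, 3L] == cand[3L]))
        vox <- rbind(vox, cand)
    }
    blobs[[k]] <- list(center = center, radius = 2, voxels = vox)
    avoid <- c(avoid, blobs[k])
  }
  blobs
}

#' Generate a synthetic DCE phantom with ground truth
#'
#' Builds the 4D series and the analytic truth for a treated-style phantom:
#' flat unit curves in background brain, per-cluster two-exponential curves
#' in the enhancement clusters and sham blobs, Gaussian noise on the
#' normalized signal (the baseline frame is the noiseless normalization
#' reference), air at zero intensity. Truth Dyn/TT/AOT are computed from
#' the generating parameters with the same dense-grid definitions the
#' analysis uses; the true BBBo mask contains the enhancing components of
#' at least 30 voxels.
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return A list with elements \code{series} (\linkS4class{DceSeries}),
#'   \code{truth} (\linkS4class{PhantomTruth}) and \code{spec}.
#' @examples
#' ph <- generatePhantom(phantomSpec(dim = c(24, 24, 24), nClusters = 1,
#'                                   clusterRadii = 3, noiseSigma = 0,
#'                                   seed = 7))
#' ph$truth
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  withSeed(spec$seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  dim <- spec$dim
  times <- spec$times
  nT <- length(times)
  window <- c(times[1L], times[length(times)])
  brain <- .ellipsoidMask(dim, spec$brainAxesFrac)

  clusters <- .placeClusters(spec)
  comps <- lapply(clusters, function(cl) {
    vox <- .sphereVoxels(cl$center, cl$radius, dim)
    list(voxels = vox, params = .drawClusterParams(times, spec$dynRange))
  })
  if (spec$nSham > 0L) {
    blobs <- .placeShamBlobs(spec, clusters)
    comps <- c(comps, lapply(blobs, function(b)
      list(voxels = b$voxels,
           params = .drawClusterParams(times, spec$dynRange))))
  }
  for (cmp in comps) {
    lin <- cmp$voxels[, 1L] + (cmp$voxels[, 2L] - 1L) * dim[1L] +
      (cmp$voxels[, 3L] - 1L) * dim[1L] * dim[2L]
    if (!all(brain[lin]))
      stop("enhancing component extends outside the brain mask")
  }

  ## normalized signal per voxel and frame
  norm <- array(0, c(dim, nT))
  nSpatial <- prod(dim)
  for (f in seq_len(nT)) {
    vol <- array(0, dim)
    vol[brain] <- 1
    norm[, , , f] <- vol
  }
  truthDyn <- array(NA_real_, dim); truthDyn[brain] <- 0
  truthTT <- truthDyn; truthAOT <- truthDyn
  tab <- NULL
  for (k in seq_along(comps)) {
    cmp <- comps[[k]]
    lin <- cmp$voxels[, 1L] + (cmp$voxels[, 2L] - 1L) * dim[1L] +
      (cmp$voxels[, 3L] - 1L) * dim[1L] * dim[2L]
    f <- evalModel(cmp$params, times)
    for (j in seq_len(nT)) norm[lin + (j - 1L) * nSpatial] <- f[j]
    s <- .curveSummary(cmp$params, window, 0.05, 1000L, "washout")
    truthDyn[lin] <- s$dyn; truthTT[lin] <- s$tt; truthAOT[lin] <- s$aot
    tab <- rbind(tab, data.frame(
      label = k, nVoxels = length(lin),
      x1 = cmp$params[1L], x2 = cmp$params[2L], x3 = cmp$params[3L],
      x4 = cmp$params[4L], x5 = cmp$params[5L],
      dyn = s$dyn, tt = s$tt, aot = s$aot,
      isBBBo = length(lin) >= 30L && s$dyn > 5))
  }
  if (is.null(tab))
    tab <- data.frame(label = integer(0), nVoxels = integer(0),
                      x1 = numeric(0), x2 = numeric(0), x3 = numeric(0),
                      x4 = numeric(0), x5 = numeric(0), dyn = numeric(0),
                      tt = numeric(0), aot = numeric(0), isBBBo = logical(0))

  mask <- array(FALSE, dim)
  for (k in seq_along(comps)) {
    if (nrow(tab) >= k && tab$isBBBo[k]) {
      v <- comps[[k]]$voxels
      mask[v[, 1L] + (v[, 2L] - 1L) * dim[1L] +
           (v[, 3L] - 1L) * dim[1L] * dim[2L]] <- TRUE
    }
  }

  if (spec$noiseSigma > 0) {
    bidx <- which(brain)
    for (f in 2:nT) {
      eps <- stats::rnorm(length(bidx), 0, spec$noiseSigma)
      norm[bidx + (f - 1L) * nSpatial] <-
        pmax(norm[bidx + (f - 1L) * nSpatial] + eps, 1e-6)
    }
  }

  series <- DceSeries(norm * spec$baseline, times, spec$voxelDims)
  truth <- new("PhantomTruth", dyn = truthDyn, tt = truthTT, aot = truthAOT,
               mask = mask, brain = brain, clusters = tab,
               voxelDims = spec$voxelDims)
  list(series = series, truth = truth, spec = spec)
}

#' Generate a sham phantom
#'
#' A phantom with no cluster of minimal size: only small isolated enhancing
#' blobs (each below 30 voxels), so the true BBBo mask is empty.
#'
#' @param spec A \code{\link{phantomSpec}} with \code{nClusters = 0}; the
#'   default carries 40 isolated blobs of 1--5 voxels.
#' @return As \code{\link{generatePhantom}}.
#' @export
generateShamPhantom <- function(spec = phantomSpec(nClusters = 0L,
                                                   clusterRadii = numeric(0),
                                                   nSham = 40L)) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (spec$nClusters != 0L)
    stop("a sham phantom must have nClusters = 0")
  if (any(spec$shamSize >= 30L))
    stop("sham blobs must stay below the minimal cluster size")
  res <- generatePhantom(spec)
  stopifnot(!any(res$truth@mask))
  res
}

#' Generate a synthetic dose-response plate
#'
#' Confluence values from a four-parameter logistic curve plus Gaussian
#' noise, clipped to [0, 100] percent, with \code{wells} replicate wells
#' per concentration. Defaults reproduce the study's in vitro design: six
#' wells per concentration, the Gl261 IC50 (7.1 nM) as generating truth.
#'
#' @param trueIc50 Generating IC50, nM.
#' @param hill Hill slope.
#' @param top,bottom Confluence asymptotes, percent.
#' @param concentrations Positive concentrations, nM, spanning the
#'   transition.
#' @param wells Replicate wells per concentration.
#' @param noiseSd Gaussian noise SD, percent confluence.
#' @param seed Seed; fixed seed gives an identical plate.
#' @return data.frame with columns concentration_nM, well, confluence_pct.
#' @export
generateDoseResponse <- function(trueIc50 = 7.1, hill = 1, top = 95,
                                 bottom = 5,
                                 concentrations = 0.4 * 3^(0:7),
                                 wells = 6L, noiseSd = 5, seed = 1L) {
  stopifnot(trueIc50 > 0, all(concentrations > 0), wells >= 1L,
            noiseSd >= 0, top > bottom)
  if (min(concentrations) > trueIc50 || max(concentrations) < trueIc50)
    stop("concentrations must span the transition around the IC50")
  withSeed(seed, {
    df <- expand.grid(well = seq_len(wells),
                      concentration_nM = concentrations)
    mu <- bottom + (top - bottom) /
      (1 + (df$concentration_nM / trueIc50)^hill)
    df$confluence_pct <- pmin(pmax(mu + stats::rnorm(nrow(df), 0, noiseSd),
                                   0), 100)
    df[, c("concentration_nM", "well", "confluence_pct")]
  })
}

#' Generate a synthetic efficacy cohort
#'
#' Baseline tumor volumes and day-8 growth-rate folds for two treatment
#' groups. Defaults use the study's printed group means: growth rates
#' 1.18 (combined treatment) and 2.6 (drug only) with SEM-implied SDs at
#' n = 5, baseline volumes near 8.09 and 5.76 mm^3.
#'
#' @param nPerGroup Mice per group (>= 2).
#' @param meanRates Length-2 mean growth-rate folds (combined, drug-only).
#' @param sdRates Length-2 rate SDs; the default converts the printed SEMs
#'   (0.14, 0.44) to SDs at the study's n = 5.
#' @param meanBaselines Length-2 mean baseline volumes, mm^3.
#' @param sdBaselines Length-2 baseline SDs, mm^3.
#' @param seed Seed.
#' @return data.frame with columns mouse_id, group, v_baseline_mm3,
#'   v_day8_mm3.
#' @export
generateEfficacyCohort <- function(nPerGroup = 5L,
                                   meanRates = c(1.18, 2.6),
                                   sdRates = c(0.14, 0.44) * sqrt(5),
                                   meanBaselines = c(8.09, 5.76),
                                   sdBaselines = c(1.5, 1.5),
                                   seed = 1L) {
  stopifnot(nPerGroup >= 2L, length(meanRates) == 2L, length(sdRates) == 2L,
            all(sdRates >= 0), all(meanBaselines > 0))
  withSeed(seed, {
    groups <- c("combined", "doxoOnly")
    out <- NULL
    for (g in 1:2) {
      vb <- pmax(stats::rnorm(nPerGroup, meanBaselines[g], sdBaselines[g]), 1)
      rate <- pmax(stats::rnorm(nPerGroup, meanRates[g], sdRates[g]), 0.05)
      out <- rbind(out, data.frame(
        mouse_id = sprintf("%s_%02d", groups[g], seq_len(nPerGroup)),
        group = groups[g],
        v_baseline_mm3 = vb,
        v_day8_mm3 = vb * rate))
    }
    out
  })
}
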