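# Independent oracles and small fixture builders used across the suite.

# Exhaustive flood-fill component labeling, written deliberately unlike the
# package implementation (depth-first over coordinate triples, no padding,
# no vectorized neighbor arithmetic).
floodFillSizes <- function(mask, connectivity = 26) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  neighbors <- function(x, y, z) {
    out <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
      nx <- x + dx; ny <- y + dy; nz <- z + dz
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3])
        next
      out <- rbind(out, c(nx, ny, nz))
    }
    out
  }
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    n <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      n <- n + 1L
      nb <- neighbors(v[1], v[2], v[3])
      for (k in seq_len(NROW(nb))) {
        w <- nb[k, ]
        if (mask[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# Time-over-threshold oracle by root finding on the model curve:
# locates every threshold crossing with uniroot on a fine bracketing scan,
# then sums the above-threshold interval lengths exactly.
ttRootOracle <- function(params, window, threshold = 0.05, nScan = 20000) {
  f <- function(t) evalModel(params, t) - (1 + threshold)
  tg <- seq(window[1], window[2], length.out = nScan)
  fv <- f(tg)
  roots <- c()
  for (i in seq_len(nScan - 1)) {
    if (fv[i] == 0) roots <- c(roots, tg[i])
    else if (fv[i] * fv[i + 1] < 0)
      roots <- c(roots, uniroot(f, c(tg[i], tg[i + 1]), tol = 1e-12)$root)
  }
  pts <- sort(unique(c(window, roots)))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (f(mid) >= 0) total <- total + (pts[i + 1] - pts[i])
  }
  total
}

# Fine-grid trapezoid AOT oracle (pracma::trapz, 1e5 points).
aotTrapzOracle <- function(params, window, threshold = 0.05) {
  tg <- seq(window[1], window[2], length.out = 1e5)
  pracma::trapz(tg, pmax(evalModel(params, tg) - (1 + threshold), 0))
}

# Random slow-accumulation parameter sets with f(t1) = 1, mirroring the
# phantom generator's kinetic ranges.
randomKineticParams <- function(n, times, dynRange = c(6, 30), seed = 42) {
  set.seed(seed)
  t1 <- times[1]
  window <- c(t1, times[length(times)])
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    x1 <- runif(1, 0.005, 0.08)
    x2 <- runif(1, 8, 25)
    x3 <- runif(1, -0.08, 0.08)
    x4 <- runif(1, 5, 25)
    x5 <- 1 - x1 * t1 * exp(-t1 / x2) - x3 * exp(-t1 / x4)
    if (x5 < 0.5) next
    p <- c(x1, x2, x3, x4, x5)
    dyn <- computeDyn(p, window)
    if (dyn < dynRange[1] || dyn > dynRange[2]) next
    k <- k + 1L
    out[[k]] <- p
  }
  out
}

# Hand-built ParamMaps with given dyn/r2 values at given linear indices.
makeMaps <- function(dims, dynVals = NULL, r2Vals = NULL, idx = NULL,
                     voxelDims = c(0.39, 0.39, 0.4)) {
  empty <- array(NA_real_, dims)
  fitted <- array(FALSE, dims)
  dyn <- empty; tt <- empty; aot <- empty; r2 <- empty
  if (!is.null(idx)) {
    fitted[idx] <- TRUE
    dyn[idx] <- dynVals
    r2[idx] <- r2Vals
    tt[idx] <- 10
    aot[idx] <- 1
  }
  new("ParamMaps", dyn = dyn, tt = tt, aot = aot, r2 = r2,
      fittedMask = fitted, voxelDims = voxelDims)
}

# A small BBBoResult wrapping an arbitrary mask (for histogram tests).
makeBBBo <- function(mask, voxelDims = c(0.39, 0.39, 0.4)) {
  n <- sum(mask)
  new("BBBoResult", mask = mask,
      clusters = data.frame(label = 1L, nVoxels = as.integer(n)),
      nVoxels = as.integer(n), volumeMm3 = n * prod(voxelDims),
      voxelDims = voxelDims,
      thresholds = list(r2Min = 0.6, dynMin = 5, minCluster = 30,
                        connectivity = 26))
}
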