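#' @include kinetics.R components.R
NULL

#' Voxelwise kinetic fitting over a brain mask
#'
#' Runs normalization and the kinetic fit (\code{\link{fitVoxel}} machinery)
#' for every in-mask voxel of a series and assembles the Dyn, TT, AOT and r2
#' maps. Voxels whose first-frame intensity is at or below the noise floor
#' (fraction \code{control$epsBaseline} of the series maximum) are excluded
#' from \code{fittedMask}, as are voxels whose fit fails outright.
#'
#' @param series A \linkS4class{DceSeries}.
#' @param brainMask 3D logical array matching the series grid. An empty mask
#'   yields empty maps.
#' @param control A \code{\link{kineticsControl}}.
#' @return A \linkS4class{ParamMaps}.
#' @export
fitBrain <- function(series, brainMask, control = kineticsControl()) {
  stopifnot(is(series, "DceSeries"))
  d <- dim(series@data)
  brainMask <- .checkMask(brainMask, d[1:3], "brainMask")
  times <- series@times
  window <- c(times[1L], times[length(times)])
  nSpatial <- prod(d[1:3])

  empty <- array(NA_real_, d[1:3])
  fitted <- array(FALSE, d[1:3])
  maps <- list(dyn = empty, tt = empty, aot = empty, r2 = empty)

  idx <- which(brainMask)
  if (length(idx)) {
    eps <- control$epsBaseline * max(series@data)
    mat <- matrix(series@data, nrow = nSpatial, ncol = d[4L])
    baseline <- mat[idx, 1L]
    idx <- idx[baseline > eps]          # unfittable: no baseline signal
    if (length(idx)) {
      ctx <- .fitContext(times, control)
      Y <- t(mat[idx, , drop = FALSE] / mat[idx, 1L])
      Y[1L, ] <- 1
      ## vectorized variable-projection stage: exact linear solves for all
      ## voxels at every candidate time-constant pair
      npair <- nrow(ctx$pairs)
      nv <- length(idx)
      sseMat <- matrix(0, npair, nv)
      coefCube <- array(0, c(3L, nv, npair))
      for (i in seq_len(npair)) {
        cf <- qr.coef(ctx$qrs[[i]], Y)
        cf[is.na(cf)] <- 0
        fittedY <- qr.fitted(ctx$qrs[[i]], Y)
        sseMat[i, ] <- colSums((Y - fittedY)^2)
        coefCube[, , i] <- cf
      }
      for (v in seq_len(nv)) {
        y <- Y[, v]
        best <- .fitFromStage(y, times, control, ctx, sseMat[, v],
                              matrix(coefCube[, v, ], nrow = 3L))
        if (is.null(best) || any(!is.finite(best$params))) next
        s <- .curveSummary(best$params, window, control$threshold,
                           control$gridN, control$modelVariant)
        i <- idx[v]
        fitted[i] <- TRUE
        maps$dyn[i] <- s$dyn
        maps$tt[i] <- s$tt
        maps$aot[i] <- s$aot
        maps$r2[i] <- .r2FromSse(best$sse, y)
      }
    }
  }
  new("ParamMaps", dyn = maps$dyn, tt = maps$tt, aot = maps$aot,
      r2 = maps$r2, fittedMask = fitted, voxelDims = series@voxelDims)
}

#' Classify BBB-opening voxels
#'
#' A voxel represents BBBo iff its fit has r2 > \code{r2Min} and
#' Dyn > \code{dynMin} percent, and it belongs to a 3D connected component
#' of at least \code{minCluster} such voxels. Filters are applied in the
#' order r2, Dyn, cluster size (the result does not depend on the order).
#'
#' @param maps A \linkS4class{ParamMaps}.
#' @param r2Min Goodness-of-fit threshold (default 0.6).
#' @param dynMin Dyn threshold in percent (default 5).
#' @param minCluster Minimal connected-component size in voxels (default 30).
#' @param connectivity 26 (default) or 6.
#' @param within Optional 3D logical array restricting the classification
#'   (used e.g. to exclude tumor voxels); NULL for the whole grid.
#' @return A \linkS4class{BBBoResult}.
#' @export
classifyBBBo <- function(maps, r2Min = 0.6, dynMin = 5, minCluster = 30,
                         connectivity = 26, within = NULL) {
  stopifnot(is(maps, "ParamMaps"))
  d <- dim(maps@fittedMask)
  pass <- maps@fittedMask &
    !is.na(maps@r2) & maps@r2 > r2Min &
    !is.na(maps@dyn) & maps@dyn > dynMin
  if (!is.null(within)) {
    within <- .checkMask(within, d, "within")
    pass <- pass & within
  }
  lab <- labelComponents(pass, connectivity)
  keep <- which(lab$sizes >= minCluster)
  mask <- array(lab$labels %in% keep, d)
  clusters <- data.frame(label = keep,
                         nVoxels = as.integer(lab$sizes[keep]))
  ## relabel retained components 1..k for a compact export
  n <- sum(clusters$nVoxels)
  new("BBBoResult", mask = mask, clusters = clusters,
      nVoxels = as.integer(n),
      volumeMm3 = n * prod(maps@voxelDims),
      voxelDims = maps@voxelDims,
      thresholds = list(r2Min = r2Min, dynMin = dynMin,
                        minCluster = minCluster,
                        connectivity = connectivity))
}

#' BBBo volume from a voxel count
#'
#' @param result A \linkS4class{BBBoResult}.
#' @param dims Voxel dimensions in mm; defaults to those stored in
#'   \code{result}.
#' @return Volume in mm^3 (voxel count x voxel volume).
#' @export
bbboVolume <- function(result, dims = voxelDims(result)) {
  .checkVoxelDims(dims)
  nVoxels(result) * prod(dims)
}

#' Fold ratio between group means
#'
#' Ratio of mean treated to mean sham BBBo voxel counts, rounded to the
#' nearest integer fold.
#'
#' @param meanTreated,meanSham Group means; \code{meanSham} must be > 0.
#' @return Integer fold.
#' @examples
#' groupRatio(1785, 62.5)   # 29
#' @export
groupRatio <- function(meanTreated, meanSham) {
  if (!is.finite(meanSham) || meanSham <= 0)
    stop("'meanSham' must be > 0: fold is undefined")
  round(meanTreated / meanSham)
}
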