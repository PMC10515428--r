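#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## DceSeries
## ---------------------------------------------------------------------------

#' Delayed-contrast MRI time series
#'
#' Container for a repeated post-contrast T1 acquisition: a 4D intensity
#' array indexed (x, y, z, frame), the acquisition times of the frames in
#' minutes post contrast injection, and the voxel dimensions in mm.
#'
#' @slot data 4D numeric array, one 3D volume per time point.
#' @slot times Numeric vector of acquisition times (minutes, strictly
#'   increasing, all positive, at least 7 points).
#' @slot voxelDims Numeric length-3 vector, voxel edge lengths in mm.
#'
#' @export
setClass("DceSeries",
  representation(data = "array", times = "numeric", voxelDims = "numeric"))

setValidity("DceSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("'data' must be a 4D array (x, y, z, frame)")
  if (any(d[1:3] < 1L)) return("spatial dimensions must all be >= 1")
  if (d[4L] != length(object@times))
    return(sprintf("frame count (%d) != number of acquisition times (%d)",
                   d[4L], length(object@times)))
  tchk <- tryCatch({ .checkTimes(object@times); NULL },
                   error = function(e) conditionMessage(e))
  if (!is.null(tchk)) return(tchk)
  vchk <- tryCatch({ .checkVoxelDims(object@voxelDims); NULL },
                   error = function(e) conditionMessage(e))
  if (!is.null(vchk)) return(vchk)
  if (any(!is.finite(object@data))) return("intensities must all be finite")
  if (any(object@data < 0)) return("intensities must be >= 0")
  TRUE
})

#' Construct a DceSeries
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param times Acquisition times in minutes post contrast injection.
#' @param voxelDims Voxel edge lengths in mm (default the acquisition's
#'   zero-filled resolution, 0.39 x 0.39 x 0.4 mm).
#' @return A \linkS4class{DceSeries}.
#' @examples
#' arr <- array(1000, dim = c(4, 4, 4, 8))
#' s <- DceSeries(arr, seq(1, 30, length.out = 8))
#' nFrames(s)
#' @export
DceSeries <- function(data, times, voxelDims = c(0.39, 0.39, 0.4)) {
  new("DceSeries", data = data, times = as.numeric(times),
      voxelDims = as.numeric(voxelDims))
}

#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "DceSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("voxelDims", "DceSeries", function(x) x@voxelDims)

#' @rdname accessors
#' @export
setMethod("seriesArray", "DceSeries", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("nFrames", "DceSeries", function(x) dim(x@data)[4L])

setMethod("show", "DceSeries", function(object) {
  d <- dim(object@data)
  cat("DceSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames\n")
  cat("  times (min):", paste(signif(object@times, 3), collapse = ", "), "\n")
  cat("  voxel size (mm):", paste(object@voxelDims, collapse = " x "), "\n")
})

## ---------------------------------------------------------------------------
## KineticFit (single voxel)
## ---------------------------------------------------------------------------

#' Per-voxel kinetic fit
#'
#' The result of fitting the two-exponential enhancement model to a single
#' normalized voxel curve, together with the three derived parameters:
#' Dyn (maximal fitted signal increase, percent of baseline), TT (time over
#' the 5\% enhancement threshold, minutes) and AOT (area over the threshold,
#' min x normalized units).
#'
#' @slot params Numeric length-5 kinetic parameters (x1..x5).
#' @slot r2 Goodness of fit, 1 - SSE/SST.
#' @slot dyn Maximal fitted signal increase over the first time point (\%).
#' @slot tt Time over threshold (min).
#' @slot aot Area over threshold (min x normalized units).
#' @slot converged Logical, whether the optimizer returned a usable fit.
#' @slot window Fit window, c(t_first, t_last) in minutes.
#' @slot variant Model variant, "washout" or "uptake".
#' @export
setClass("KineticFit",
  representation(params = "numeric", r2 = "numeric", dyn = "numeric",
                 tt = "numeric", aot = "numeric", converged = "logical",
                 window = "numeric", variant = "character"))

setValidity("KineticFit", function(object) {
  if (length(object@params) != 5L) return("'params' must have length 5")
  if (object@converged) {
    if (!all(is.finite(object@params))) return("converged fit has non-finite params")
    if (object@params[2L] <= 0 || object@params[4L] <= 0)
      return("time constants x2, x4 must be > 0")
    if (is.finite(object@dyn) && object@dyn < 0) return("dyn must be >= 0")
    if (is.finite(object@aot) && object@aot < 0) return("aot must be >= 0")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("kineticParams", "KineticFit", function(x) x@params)

setMethod("show", "KineticFit", function(object) {
  if (!object@converged) {
    cat("KineticFit: <not converged>\n"); return(invisible(NULL))
  }
  cat(sprintf("KineticFit (%s): r2 = %.4f\n", object@variant, object@r2))
  cat(sprintf("  x = (%.4g, %.4g, %.4g, %.4g, %.4g)\n",
              object@params[1], object@params[2], object@params[3],
              object@params[4], object@params[5]))
  cat(sprintf("  Dyn = %.2f%%  TT = %.2f min  AOT = %.4g\n",
              object@dyn, object@tt, object@aot))
})

## ---------------------------------------------------------------------------
## ParamMaps
## ---------------------------------------------------------------------------

#' Voxelwise kinetic parameter maps
#'
#' 3D maps of Dyn, TT, AOT and r2 produced by \code{\link{fitBrain}}.
#' Values are NA outside \code{fittedMask}.
#'
#' @slot dyn,tt,aot,r2 3D numeric arrays.
#' @slot fittedMask 3D logical array: voxels that were normalized and fitted.
#' @slot voxelDims Voxel edge lengths, mm.
#' @export
setClass("ParamMaps",
  representation(dyn = "array", tt = "array", aot = "array", r2 = "array",
                 fittedMask = "array", voxelDims = "numeric"))

setValidity("ParamMaps", function(object) {
  d <- dim(object@fittedMask)
  if (length(d) != 3L) return("maps must be 3D")
  for (nm in c("dyn", "tt", "aot", "r2"))
    if (!identical(dim(slot(object, nm)), d))
      return(paste0("'", nm, "' map dimensions differ from fittedMask"))
  if (!is.logical(object@fittedMask)) return("fittedMask must be logical")
  if (any(!is.na(object@dyn[!object@fittedMask])))
    return("map values present outside fittedMask")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("dynMap", "ParamMaps", function(x) x@dyn)
#' @rdname accessors
#' @export
setMethod("ttMap", "ParamMaps", function(x) x@tt)
#' @rdname accessors
#' @export
setMethod("aotMap", "ParamMaps", function(x) x@aot)
#' @rdname accessors
#' @export
setMethod("r2Map", "ParamMaps", function(x) x@r2)
#' @rdname accessors
#' @export
setMethod("fittedMask", "ParamMaps", function(x) x@fittedMask)
#' @rdname accessors
#' @export
setMethod("voxelDims", "ParamMaps", function(x) x@voxelDims)

setMethod("show", "ParamMaps", function(object) {
  cat("ParamMaps:", paste(dim(object@fittedMask), collapse = " x "),
      "grid,", sum(object@fittedMask), "fitted voxels\n")
  if (any(object@fittedMask)) {
    dv <- object@dyn[object@fittedMask]
    cat(sprintf("  Dyn range: %.2f .. %.2f %%\n",
                min(dv, na.rm = TRUE), max(dv, na.rm = TRUE)))
  }
})

## ---------------------------------------------------------------------------
## BBBoResult
## ---------------------------------------------------------------------------

#' BBB-opening classification result
#'
#' Binary BBBo mask with its cluster inventory after the r2, Dyn and
#' minimal-cluster-size filters.
#'
#' @slot mask 3D logical array of BBBo voxels.
#' @slot clusters data.frame with columns \code{label} and \code{nVoxels},
#'   one row per retained connected component.
#' @slot nVoxels Total retained voxel count.
#' @slot volumeMm3 \code{nVoxels} times the voxel volume.
#' @slot voxelDims Voxel edge lengths, mm.
#' @slot thresholds Named list of the filter settings used.
#' @export
setClass("BBBoResult",
  representation(mask = "array", clusters = "data.frame", nVoxels = "integer",
                 volumeMm3 = "numeric", voxelDims = "numeric",
                 thresholds = "list"))

setValidity("BBBoResult", function(object) {
  if (length(dim(object@mask)) != 3L) return("'mask' must be 3D")
  if (!is.logical(object@mask)) return("'mask' must be logical")
  if (sum(object@mask) != object@nVoxels)
    return("mask voxel count != nVoxels")
  if (nrow(object@clusters) &&
      sum(object@clusters$nVoxels) != object@nVoxels)
    return("nVoxels != sum of cluster sizes")
  vv <- prod(object@voxelDims)
  if (abs(object@volumeMm3 - object@nVoxels * vv) > 1e-8 * max(1, vv))
    return("volumeMm3 != nVoxels x voxel volume")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("bbboMask", "BBBoResult", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("clusterTable", "BBBoResult", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("nVoxels", "BBBoResult", function(x) x@nVoxels)
#' @rdname accessors
#' @export
setMethod("volumeMm3", "BBBoResult", function(x) x@volumeMm3)
#' @rdname accessors
#' @export
setMethod("voxelDims", "BBBoResult", function(x) x@voxelDims)

setMethod("show", "BBBoResult", function(object) {
  cat("BBBoResult:", object@nVoxels, "BBBo voxels in",
      nrow(object@clusters), "clusters;",
      sprintf("volume = %.3f mm^3\n", object@volumeMm3))
  th <- object@thresholds
  if (length(th))
    cat(sprintf("  filters: r2 > %s, Dyn > %s%%, cluster >= %s voxels\n",
                th$r2Min, th$dynMin, th$minCluster))
})

## ---------------------------------------------------------------------------
## HistogramSet / ExponentialFit
## ---------------------------------------------------------------------------

#' Histograms of Dyn, TT and AOT over BBBo voxels
#'
#' @slot histograms Named list (dyn, tt, aot); each element a list with
#'   \code{edges}, \code{centers} and \code{counts}.
#' @slot nVoxels Number of BBBo voxels the counts sum to.
#' @export
setClass("HistogramSet",
  representation(histograms = "list", nVoxels = "integer"))

setValidity("HistogramSet", function(object) {
  for (nm in names(object@histograms)) {
    h <- object@histograms[[nm]]
    if (!all(c("edges", "centers", "counts") %in% names(h)))
      return("each histogram needs edges, centers, counts")
    if (any(diff(h$edges) <= 0)) return("bin edges must be strictly increasing")
    if (any(h$counts < 0)) return("counts must be >= 0")
    if (length(h$counts) != length(h$edges) - 1L)
      return("counts length must be length(edges) - 1")
    if (sum(h$counts) != object@nVoxels)
      return(paste0("'", nm, "' counts do not sum to nVoxels"))
  }
  TRUE
})

setMethod("show", "HistogramSet", function(object) {
  cat("HistogramSet over", object@nVoxels, "BBBo voxels:\n")
  for (nm in names(object@histograms))
    cat(sprintf("  %s: %d bins\n", nm,
                length(object@histograms[[nm]]$counts)))
})

#' Exponential decay fit of a histogram
#'
#' Least-squares fit of A * exp(-x / tau) to histogram counts over bin
#' centers.
#'
#' @slot amplitude Fitted A (counts).
#' @slot tau Decay scale, same units as the histogram axis.
#' @slot r2 Goodness of fit.
#' @export
setClass("ExponentialFit",
  representation(amplitude = "numeric", tau = "numeric", r2 = "numeric"))

setValidity("ExponentialFit", function(object) {
  if (object@tau <= 0) return("tau must be > 0")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  TRUE
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf("ExponentialFit: A = %.4g, tau = %.4g (r2 = %.3f)\n",
              object@amplitude, object@tau, object@r2))
})

## ---------------------------------------------------------------------------
## Ic50Fit
## ---------------------------------------------------------------------------

#' Four-parameter logistic IC50 fit
#'
#' @slot ic50 Half-maximal inhibitory concentration, nM.
#' @slot hill Hill slope.
#' @slot top,bottom Upper and lower confluence asymptotes (\%).
#' @slot se Standard error of the IC50 (nM, delta method from log10 space).
#' @slot r2 Goodness of fit on the concentration means.
#' @export
setClass("Ic50Fit",
  representation(ic50 = "numeric", hill = "numeric", top = "numeric",
                 bottom = "numeric", se = "numeric", r2 = "numeric"))

setValidity("Ic50Fit", function(object) {
  if (object@ic50 <= 0) return("ic50 must be > 0")
  if (object@top < object@bottom) return("top must be >= bottom")
  TRUE
})

setMethod("show", "Ic50Fit", function(object) {
  cat(sprintf("Ic50Fit: IC50 = %.3g nM (SE %.2g), hill = %.2f, top = %.1f, bottom = %.1f, r2 = %.3f\n",
              object@ic50, object@se, object@hill, object@top,
              object@bottom, object@r2))
})

## ---------------------------------------------------------------------------
## PhantomTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic DCE phantom
#'
#' Analytic Dyn/TT/AOT maps computed from the generating kinetic parameters,
#' the true BBBo mask (clusters of at least the minimal cluster size), the
#' brain mask and the per-cluster parameter table.
#'
#' @slot dyn,tt,aot 3D numeric arrays (NA outside the brain).
#' @slot mask 3D logical array, the true BBBo voxels.
#' @slot brain 3D logical brain mask.
#' @slot clusters data.frame, one row per generated enhancing component
#'   (label, nVoxels, x1..x5, dyn, tt, aot, isBBBo).
#' @slot voxelDims Voxel edge lengths, mm.
#' @export
setClass("PhantomTruth",
  representation(dyn = "array", tt = "array", aot = "array", mask = "array",
                 brain = "array", clusters = "data.frame",
                 voxelDims = "numeric"))

setValidity("PhantomTruth", function(object) {
  d <- dim(object@mask)
  for (nm in c("dyn", "tt", "aot", "brain"))
    if (!identical(dim(slot(object, nm)), d))
      return("all truth maps must share dimensions")
  if (any(object@mask & !object@brain))
    return("true BBBo voxels must lie inside the brain")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("dynMap", "PhantomTruth", function(x) x@dyn)
#' @rdname accessors
#' @export
setMethod("ttMap", "PhantomTruth", function(x) x@tt)
#' @rdname accessors
#' @export
setMethod("aotMap", "PhantomTruth", function(x) x@aot)
#' @rdname accessors
#' @export
setMethod("bbboMask", "PhantomTruth", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "PhantomTruth", function(x) x@brain)
#' @rdname accessors
#' @export
setMethod("clusterTable", "PhantomTruth", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("voxelDims", "PhantomTruth", function(x) x@voxelDims)

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", sum(object@mask), "true BBBo voxels in",
      sum(object@clusters$isBBBo), "clusters (of",
      nrow(object@clusters), "enhancing components)\n")
})
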