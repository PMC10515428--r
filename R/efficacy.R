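#' @include mapping.R
NULL

#' Tumor volume from an enhancing ROI
#'
#' Number of ROI voxels times the voxel volume.
#'
#' @param roi 3D logical array (enhancing-region mask).
#' @param voxelDims Voxel edge lengths in mm.
#' @return Volume in mm^3.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[1:2, 1:2, 1] <- TRUE
#' tumorVolume(m, c(0.39, 0.39, 0.4))
#' @export
tumorVolume <- function(roi, voxelDims = c(0.39, 0.39, 0.4)) {
  if (!is.array(roi) || length(dim(roi)) != 3L)
    stop("'roi' must be a 3D array")
  .checkVoxelDims(voxelDims)
  sum(roi != 0) * prod(voxelDims)
}

#' Tumor growth rate as a volume fold change
#'
#' Follow-up volume divided by baseline volume (dimensionless fold over the
#' observation interval).
#'
#' @param vBaseline Baseline (treatment-day) volume, mm^3, > 0.
#' @param vFollowup Follow-up (day-8) volume, mm^3, >= 0.
#' @return Fold change(s).
#' @export
growthRate <- function(vBaseline, vFollowup) {
  if (any(!is.finite(vBaseline)) || any(vBaseline <= 0))
    stop("baseline volume must be > 0")
  if (any(vFollowup < 0)) stop("follow-up volume must be >= 0")
  vFollowup / vBaseline
}

#' BBBo classification outside the tumor
#'
#' Classifies BBBo voxels restricted to brain-and-not-tumor, i.e. the
#' whole-brain ROI minus the enhancing tumor ROI, then re-applies the
#' minimal-cluster-size filter (the filter defines what counts as BBBo).
#'
#' @param maps A \linkS4class{ParamMaps}.
#' @param brain 3D logical brain mask.
#' @param tumor 3D logical tumor ROI; voxels outside the brain mask trigger
#'   a warning and the intersection is used.
#' @param ... Passed to \code{\link{classifyBBBo}} (r2Min, dynMin,
#'   minCluster, connectivity).
#' @return A \linkS4class{BBBoResult}.
#' @export
bbboOutsideTumor <- function(maps, brain, tumor, ...) {
  stopifnot(is(maps, "ParamMaps"))
  d <- dim(maps@fittedMask)
  brain <- .checkMask(brain, d, "brain")
  tumor <- .checkMask(tumor, d, "tumor")
  if (any(tumor & !brain)) {
    warning("tumor ROI extends outside the brain mask; using the intersection")
    tumor <- tumor & brain
  }
  classifyBBBo(maps, ..., within = brain & !tumor)
}

#' Compare two groups with Student's t-test
#'
#' Two-sided, pooled-variance (equal-variance) two-sample t-test.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return The \code{htest} object from \code{\link[stats]{t.test}} with
#'   \code{var.equal = TRUE}.
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  stats::t.test(a, b, var.equal = TRUE)
}
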