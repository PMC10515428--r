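#' @include AllClasses.R
NULL

#' Read an acquisition-time table
#'
#' Accepts a CSV with columns \code{frame, minutes} (or a single
#' \code{minutes} column) or a JSON array of minutes. Times must be
#' positive, strictly increasing, with at least 7 points.
#'
#' @param path File path (.csv or .json).
#' @return Numeric vector of minutes post contrast injection.
#' @export
readAcquisitionTimes <- function(path) {
  if (!file.exists(path)) stop("times file not found: ", path)
  times <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.numeric(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path)
    if ("minutes" %in% names(df)) {
      if ("frame" %in% names(df)) df <- df[order(df$frame), , drop = FALSE]
      as.numeric(df$minutes)
    } else if (ncol(df) == 1L) {
      as.numeric(df[[1L]])
    } else stop("times CSV must have a 'minutes' column: ", path)
  }
  tryCatch(.checkTimes(times),
           error = function(e) stop("malformed times table '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  times
}

#' Read a 4D DCE series from a NIfTI volume
#'
#' @param path 4D NIfTI file (one 3D volume per time point).
#' @param times Acquisition times, or a path passed to
#'   \code{\link{readAcquisitionTimes}}.
#' @param voxelDims Voxel dimensions; \code{NULL} (default) takes them from
#'   the NIfTI header.
#' @return A \linkS4class{DceSeries}.
#' @export
readDceSeries <- function(path, times, voxelDims = NULL) {
  if (!file.exists(path)) stop("series file not found: ", path)
  if (is.character(times)) times <- readAcquisitionTimes(times)
  img <- RNifti::readNifti(path)
  arr <- unclass(img)
  if (length(dim(arr)) != 4L)
    stop("'", path, "' is not a 4D volume (found ",
         length(dim(arr)), " dimensions)")
  if (is.null(voxelDims)) voxelDims <- RNifti::pixdim(img)[1:3]
  DceSeries(array(as.numeric(arr), dim(arr)), times, voxelDims)
}

#' Read a 0/1 mask volume
#'
#' @param path 3D NIfTI file; voxels > 0.5 are TRUE.
#' @return 3D logical array.
#' @export
readMaskVolume <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- unclass(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("'", path, "' is not a 3D volume")
  array(arr > 0.5, dim(arr))
}

#' Write a 3D/4D array as NIfTI
#'
#' @param arr Numeric or logical array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxelDims Voxel dimensions, mm.
#' @return The path, invisibly.
#' @export
writeVolume <- function(arr, path, voxelDims = c(0.39, 0.39, 0.4)) {
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxelDims, rep(1, max(0L, nd - 3L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a BBBo result as JSON plus a cluster label map
#'
#' @param result A \linkS4class{BBBoResult}.
#' @param prefix Output path prefix; writes \code{<prefix>.json} and
#'   \code{<prefix>_labels.nii.gz}.
#' @param connectivity Connectivity used to relabel the retained clusters.
#' @return Named vector of the written paths, invisibly.
#' @export
writeBBBoResult <- function(result, prefix, connectivity = 26) {
  stopifnot(is(result, "BBBoResult"))
  lab <- labelComponents(bbboMask(result), connectivity)
  jsonPath <- paste0(prefix, ".json")
  labPath <- paste0(prefix, "_labels.nii.gz")
  jsonlite::write_json(
    list(nVoxels = nVoxels(result),
         volumeMm3 = volumeMm3(result),
         voxelDims = voxelDims(result),
         thresholds = result@thresholds,
         clusters = clusterTable(result)),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeVolume(lab$labels, labPath, voxelDims(result))
  invisible(c(json = jsonPath, labels = labPath))
}
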