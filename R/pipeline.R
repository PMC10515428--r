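#' @include io.R distributions.R register.R
NULL

#' Pipeline configuration
#'
#' One declarative object holding every analysis setting. Defaults equal
#' the study's filter set: r2 > 0.6, Dyn > 5 percent, minimal cluster of
#' 30 voxels at the 5 percent enhancement threshold.
#'
#' @param r2Min Goodness-of-fit threshold.
#' @param dynMin Dyn threshold, percent.
#' @param threshold Enhancement threshold, fraction of baseline.
#' @param minCluster Minimal cluster size, voxels.
#' @param connectivity 26 or 6.
#' @param binWidths Histogram bin widths (dyn, tt, aot).
#' @param register Whether to rigidly register frames to the first frame
#'   before fitting (off by default: synthetic phantoms are aligned by
#'   construction; enable for scanner data).
#' @param seed Seed recorded with every run.
#' @param control A \code{\link{kineticsControl}}; its \code{threshold} is
#'   kept in sync with \code{threshold}.
#' @return A list of class \code{"dcmConfig"}.
#' @export
dcmConfig <- function(r2Min = 0.6, dynMin = 5, threshold = 0.05,
                      minCluster = 30, connectivity = 26,
                      binWidths = c(dyn = 2.5, tt = 2.5, aot = 0.2),
                      register = FALSE, seed = 1L,
                      control = kineticsControl(threshold = threshold)) {
  stopifnot(r2Min <= 1, dynMin >= 0, threshold >= 0, minCluster >= 1,
            connectivity %in% c(6, 26))
  control$threshold <- threshold
  structure(list(r2Min = r2Min, dynMin = dynMin, threshold = threshold,
                 minCluster = minCluster, connectivity = connectivity,
                 binWidths = binWidths, register = register,
                 seed = as.integer(seed), control = control),
            class = "dcmConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A \code{\link{dcmConfig}}.
#' @param path JSON file path.
#' @return \code{readConfig} returns a \code{dcmConfig} equal to the one
#'   written.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "dcmConfig"))
  x <- unclass(config)
  x$binWidths <- as.list(x$binWidths)   # keep names through JSON
  x$control <- unclass(x$control)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  x <- jsonlite::fromJSON(path)
  ctl <- x$control
  control <- kineticsControl(
    gridN = ctl$gridN, threshold = ctl$threshold,
    modelVariant = ctl$modelVariant,
    tcLower = ctl$tcLower, tcUpper = ctl$tcUpper, nGrid = ctl$nGrid,
    nStarts = ctl$nStarts, maxIter = ctl$maxIter,
    extraRestarts = ctl$extraRestarts, seed = ctl$seed,
    epsBaseline = ctl$epsBaseline)
  dcmConfig(r2Min = x$r2Min, dynMin = x$dynMin, threshold = x$threshold,
            minCluster = x$minCluster, connectivity = x$connectivity,
            binWidths = unlist(x$binWidths), register = x$register,
            seed = x$seed, control = control)
}

#' Run the full BBBo mapping pipeline
#'
#' Registration (optional), voxelwise kinetic fitting, BBBo classification,
#' histogram construction and a summary, in one call.
#'
#' @param series A \linkS4class{DceSeries}, or the path to a 4D NIfTI file.
#' @param brainMask 3D logical array, or the path to a 0/1 NIfTI mask.
#' @param times Required when \code{series} is a path: numeric vector or a
#'   times-table path.
#' @param config A \code{\link{dcmConfig}}.
#' @param outDir If not NULL, artifacts are written there: summary.json,
#'   histogram CSVs, the BBBo label map and the parameter maps.
#' @return A list of class \code{"bbboPipeline"} with elements
#'   \code{maps}, \code{bbbo}, \code{histograms}, \code{summary} and, when
#'   registration ran, \code{transforms}.
#' @export
runPipeline <- function(series, brainMask, times = NULL,
                        config = dcmConfig(), outDir = NULL) {
  stopifnot(inherits(config, "dcmConfig"))
  if (is.character(series)) {
    if (is.null(times)) stop("'times' is required when 'series' is a path")
    series <- readDceSeries(series, times)
  }
  stopifnot(is(series, "DceSeries"))
  if (is.character(brainMask)) brainMask <- readMaskVolume(brainMask)
  d <- dim(seriesArray(series))
  brainMask <- .checkMask(brainMask, d[1:3], "brainMask")

  transforms <- NULL
  if (isTRUE(config$register)) {
    series <- registerSeries(series)
    transforms <- attr(series, "transforms")
  }
  maps <- fitBrain(series, brainMask, config$control)
  bbbo <- classifyBBBo(maps, r2Min = config$r2Min, dynMin = config$dynMin,
                       minCluster = config$minCluster,
                       connectivity = config$connectivity)
  hists <- buildHistograms(maps, bbbo, binWidths = config$binWidths)
  summary <- list(
    nVoxels = nVoxels(bbbo),
    volumeMm3 = volumeMm3(bbbo),
    nClusters = nrow(clusterTable(bbbo)),
    nFitted = sum(fittedMask(maps)),
    seed = config$seed,
    config = list(r2Min = config$r2Min, dynMin = config$dynMin,
                  threshold = config$threshold,
                  minCluster = config$minCluster,
                  connectivity = config$connectivity))
  out <- structure(list(maps = maps, bbbo = bbbo, histograms = hists,
                        summary = summary, transforms = transforms),
                   class = "bbboPipeline")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in c("dyn", "tt", "aot")) {
      h <- hists@histograms[[nm]]
      utils::write.csv(data.frame(bin_center = h$centers, count = h$counts),
                       file.path(outDir, paste0("hist_", nm, ".csv")),
                       row.names = FALSE)
    }
    writeBBBoResult(bbbo, file.path(outDir, "bbbo"),
                    connectivity = config$connectivity)
    vd <- voxelDims(maps)
    m <- dynMap(maps); m[is.na(m)] <- 0
    writeVolume(m, file.path(outDir, "dyn.nii.gz"), vd)
    a <- aotMap(maps); a[is.na(a)] <- 0
    writeVolume(a, file.path(outDir, "aot.nii.gz"), vd)
  }
  out
}

#' @export
print.bbboPipeline <- function(x, ...) {
  cat("BBBo pipeline result\n")
  cat("  fitted voxels:", x$summary$nFitted, "\n")
  cat("  BBBo voxels:  ", x$summary$nVoxels,
      sprintf("(%.3f mm^3) in %d clusters\n",
              x$summary$volumeMm3, x$summary$nClusters))
  invisible(x)
}
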