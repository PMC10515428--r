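#' @include mapping.R
NULL

.oneHistogram <- function(values, width = NULL, edges = NULL) {
  if (is.null(edges)) {
    if (is.null(width) || width <= 0) stop("bin width must be > 0")
    top <- if (length(values)) max(values) else 0
    edges <- seq(0, width * (floor(top / width) + 1L), by = width)
    if (length(edges) < 2L) edges <- c(0, width)
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (length(values) && (any(values < edges[1L]) ||
                         any(values >= edges[length(edges)])))
    stop("histogram edges do not cover the data")
  counts <- if (length(values))
    tabulate(findInterval(values, edges), nbins = length(edges) - 1L)
  else integer(length(edges) - 1L)
  list(edges = edges,
       centers = (edges[-1L] + edges[-length(edges)]) / 2,
       counts = as.integer(counts))
}

#' Histograms of Dyn, TT and AOT over BBBo voxels
#'
#' Bins the parameter-map values of the voxels classified as BBBo. Counts
#' always sum to the number of BBBo voxels; an empty mask yields all-zero
#' histograms. Bins are left-closed, \code{[e_i, e_{i+1})}, starting at 0.
#'
#' @param maps A \linkS4class{ParamMaps}.
#' @param bbbo A \linkS4class{BBBoResult} on the same grid.
#' @param binWidths Named numeric vector of bin widths, defaults
#'   c(dyn = 2.5, tt = 2.5, aot = 0.2) (percent, minutes, AOT units).
#' @param breaks Optional named list of explicit bin-edge vectors overriding
#'   the widths, e.g. \code{list(aot = c(0, 1, 2, 4))}.
#' @return A \linkS4class{HistogramSet}.
#' @export
buildHistograms <- function(maps, bbbo,
                            binWidths = c(dyn = 2.5, tt = 2.5, aot = 0.2),
                            breaks = NULL) {
  stopifnot(is(maps, "ParamMaps"), is(bbbo, "BBBoResult"))
  if (!identical(dim(maps@fittedMask), dim(bbbo@mask)))
    stop("maps and BBBo result are on different grids")
  sel <- bbbo@mask
  hs <- list()
  for (nm in c("dyn", "tt", "aot")) {
    vals <- slot(maps, nm)[sel]
    vals <- vals[!is.na(vals)]
    hs[[nm]] <- .oneHistogram(vals,
                              width = unname(binWidths[nm]),
                              edges = breaks[[nm]])
  }
  new("HistogramSet", histograms = hs, nVoxels = as.integer(sum(sel)))
}

#' Bin-wise average of per-subject histograms
#'
#' Group-level histograms (mean and SEM per bin across subjects), for
#' histograms built with identical edges.
#'
#' @param histList List of \linkS4class{HistogramSet} objects.
#' @param param "dyn", "tt" or "aot".
#' @return data.frame with columns center, mean, sem.
#' @export
averageHistograms <- function(histList, param = c("aot", "dyn", "tt")) {
  param <- match.arg(param)
  stopifnot(length(histList) >= 1L)
  hs <- lapply(histList, function(h) h@histograms[[param]])
  nb <- max(vapply(hs, function(h) length(h$counts), 1L))
  ## pad shorter histograms with empty upper bins (same width assumed)
  counts <- vapply(hs, function(h) c(h$counts, rep(0L, nb - length(h$counts))),
                   numeric(nb))
  widest <- hs[[which.max(vapply(hs, function(h) length(h$counts), 1L))]]
  counts <- matrix(counts, nrow = nb)
  data.frame(center = widest$centers,
             mean = rowMeans(counts),
             sem = apply(counts, 1L, stats::sd) / sqrt(ncol(counts)))
}

#' Exponential decay fit of histogram counts
#'
#' Least squares of \eqn{A e^{-x/\tau}} on raw counts over bin centers,
#' through the last nonempty bin. Raw counts (not log counts) keep empty
#' interior bins usable and avoid reweighting the tail.
#'
#' @param counts Histogram counts.
#' @param centers Bin centers (same length).
#' @return An \linkS4class{ExponentialFit}.
#' @examples
#' x <- seq(0.1, 4, by = 0.2)
#' fitExponential(1000 * exp(-x / 1), x)
#' @export
fitExponential <- function(counts, centers) {
  if (length(counts) != length(centers))
    stop("'counts' and 'centers' must have the same length")
  last <- max(which(counts > 0), 0L)
  if (sum(counts[seq_len(last)] > 0) < 3L)
    stop("need at least 3 nonempty bins for an exponential fit")
  x <- centers[seq_len(last)]
  y <- counts[seq_len(last)]
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ x[pos])
  slope <- unname(coef(lf)[2L])
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(x))
  a0 <- exp(unname(coef(lf)[1L]))
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = c(A = a0, tau = tau0),
    fn = function(p) p[1L] * exp(-x / p[2L]) - y,
    lower = c(0, 1e-8), upper = c(Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)))
  p <- coef(fit)
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse < 1e-12)
  new("ExponentialFit", amplitude = unname(p[1L]), tau = unname(p[2L]),
      r2 = r2)
}

#' Cumulative fraction of values below a threshold
#'
#' @param values Nonempty numeric vector (e.g. per-voxel AOT).
#' @param threshold Cut point; values strictly below it are counted.
#' @return Percentage in [0, 100].
#' @export
cumulativeFraction <- function(values, threshold) {
  if (!length(values)) stop("'values' is empty")
  100 * mean(values < threshold)
}

#' Calibrate an exponential AOT distribution from one cumulative fraction
#'
#' Given that \code{percentBelow} percent of the voxels lie below
#' \code{threshold}, returns the rate \eqn{\lambda = -\ln(1 - f)/x} of the
#' exponential distribution with that cumulative fraction.
#'
#' @param percentBelow Percentage in (0, 100).
#' @param threshold Positive cut point on the AOT axis.
#' @return Rate \eqn{\lambda} (1 / AOT units).
#' @examples
#' lam <- calibrateExponentialRate(50.4, 0.6)
#' exponentialCdfPercent(4, lam)   # ~99
#' @export
calibrateExponentialRate <- function(percentBelow, threshold) {
  if (percentBelow <= 0 || percentBelow >= 100)
    stop("'percentBelow' must be in (0, 100)")
  if (threshold <= 0) stop("'threshold' must be > 0")
  -log(1 - percentBelow / 100) / threshold
}

#' Exponential cumulative distribution, in percent
#'
#' @param x Evaluation point(s), >= 0.
#' @param rate Exponential rate, > 0.
#' @return 100 x (1 - exp(-rate * x)).
#' @export
exponentialCdfPercent <- function(x, rate) {
  if (rate <= 0) stop("'rate' must be > 0")
  if (any(x < 0)) stop("'x' must be >= 0")
  100 * stats::pexp(x, rate)
}
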