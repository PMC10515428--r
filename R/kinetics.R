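#' @include AllClasses.R
NULL

#' Control settings for the kinetic fit
#'
#' @param gridN Number of points of the dense evaluation grid used for the
#'   derived parameters Dyn, TT and AOT (over the scan window; no
#'   extrapolation beyond the last frame).
#' @param threshold Enhancement threshold as a fraction of baseline
#'   (default 0.05, i.e. the 5\% signal-increase level defining TT and AOT).
#' @param modelVariant "washout" for
#'   \eqn{x_1 t e^{-t/x_2} + x_3 e^{-t/x_4} + x_5} (default) or "uptake" for
#'   the alternative reading \eqn{x_1 t e^{-t/x_2} + x_3 (1 - e^{-t/x_4}) + x_5}.
#' @param tcLower,tcUpper Bounds for the time constants x2 and x4 (minutes).
#'   \code{NULL} (default) resolves, per curve, to the mean inter-frame
#'   spacing and twice the scan-window length: time constants shorter than
#'   the sampling interval are not identifiable and admit unphysical
#'   between-sample spikes.
#' @param nGrid Number of log-spaced candidate values per time-constant axis
#'   in the variable-projection start search.
#' @param nStarts Number of best start pairs polished with bounded
#'   Levenberg-Marquardt.
#' @param maxIter Maximum LM iterations per start.
#' @param extraRestarts Additional random restarts (seeded); 0 by default,
#'   the deterministic variable-projection multistart makes them redundant.
#' @param seed Seed for the optional random restarts.
#' @param epsBaseline Baseline floor for normalization, as a fraction of the
#'   largest intensity in the series; voxels whose first-frame intensity is
#'   at or below the floor are flagged unfittable.
#' @return A list of class \code{"kineticsControl"}.
#' @export
kineticsControl <- function(gridN = 1000L, threshold = 0.05,
                            modelVariant = c("washout", "uptake"),
                            tcLower = NULL, tcUpper = NULL,
                            nGrid = 5L, nStarts = 10L, maxIter = 60L,
                            extraRestarts = 0L, seed = 1L,
                            epsBaseline = 1e-6) {
  modelVariant <- match.arg(modelVariant)
  stopifnot(gridN >= 2L, threshold >= 0, nGrid >= 2L, nStarts >= 1L,
            maxIter >= 1L, extraRestarts >= 0L, epsBaseline >= 0)
  structure(list(gridN = as.integer(gridN), threshold = threshold,
                 modelVariant = modelVariant, tcLower = tcLower,
                 tcUpper = tcUpper, nGrid = as.integer(nGrid),
                 nStarts = as.integer(nStarts), maxIter = as.integer(maxIter),
                 extraRestarts = as.integer(extraRestarts), seed = seed,
                 epsBaseline = epsBaseline),
            class = "kineticsControl")
}

#' Evaluate the two-exponential enhancement model
#'
#' The per-voxel signal model for normalized delayed-contrast curves,
#' derived from the Tofts two-compartment exchange picture: a slow uptake
#' term \eqn{x_1 t e^{-t/x_2}}, a decaying term in \eqn{x_4}, and an
#' asymptotic offset \eqn{x_5}.
#'
#' @param params Numeric length-5 vector (x1..x5); x2 and x4 must be > 0.
#' @param t Time(s) in minutes post contrast injection, >= 0.
#' @param variant "washout" (default): \eqn{x_3 e^{-t/x_4}};
#'   "uptake": \eqn{x_3 (1 - e^{-t/x_4})}.
#' @return Dimensionless model signal at \code{t}.
#' @examples
#' evalModel(c(0, 1, 0, 1, 1), 10)           # all dynamics zero: offset only
#' evalModel(c(0.02, 8, 0.1, 15, 0.95), 5)
#' @export
evalModel <- function(params, t, variant = c("washout", "uptake")) {
  variant <- match.arg(variant)
  if (!is.numeric(params) || length(params) != 5L || any(!is.finite(params)))
    stop("'params' must be 5 finite numbers")
  if (params[2L] <= 0 || params[4L] <= 0)
    stop("time constants x2 and x4 must be > 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  second <- if (variant == "washout") exp(-t / params[4L])
            else 1 - exp(-t / params[4L])
  params[1L] * t * exp(-t / params[2L]) + params[3L] * second + params[5L]
}

#' Normalize a raw voxel curve to its first time point
#'
#' @param raw Raw intensity sequence, one value per frame.
#' @param times Acquisition times (minutes), strictly increasing, length >= 7.
#' @param eps Noise floor: if \code{raw[1] <= eps} the voxel is flagged
#'   unfittable rather than divided through (background air has no baseline).
#' @return A list with \code{times}, \code{values} (first value exactly 1)
#'   and \code{fittable}. Unfittable voxels carry \code{values = NULL}.
#' @examples
#' normalizeCurve(c(100, 110, 120, 118, 117, 116, 115, 114),
#'                seq(1, 30, length.out = 8))$values
#' @export
normalizeCurve <- function(raw, times, eps = 1e-6) {
  times <- .checkTimes(times)
  if (length(raw) != length(times))
    stop("'raw' and 'times' must have the same length")
  if (!all(is.finite(raw))) stop("'raw' must be finite")
  if (raw[1L] <= eps)
    return(list(times = times, values = NULL, fittable = FALSE))
  values <- raw / raw[1L]
  values[1L] <- 1
  list(times = times, values = values, fittable = TRUE)
}

## dense-grid curve summary: Dyn, TT, AOT computed from the fitted curve ----
.curveSummary <- function(params, window, threshold, gridN, variant) {
  tg <- seq(window[1L], window[2L], length.out = gridN)
  f <- evalModel(params, tg, variant)
  L <- window[2L] - window[1L]
  dyn <- 100 * (max(f) - f[1L])
  above <- f >= 1 + threshold
  dt <- L / (gridN - 1L)
  ## trapezoidal count of above-threshold intervals: a grid cell with one
  ## endpoint above contributes half a step, halving the per-crossing bias
  tt <- dt * sum((above[-gridN] + above[-1L]) / 2)
  excess <- pmax(f - (1 + threshold), 0)
  aot <- dt * (sum(excess) - 0.5 * (excess[1L] + excess[gridN]))
  list(dyn = dyn, tt = tt, aot = aot)
}

#' Maximal fitted signal increase (Dyn)
#'
#' 100 x (maximum of the fitted curve over the scan window minus its value
#' at the first time point), evaluated on a dense grid; never negative.
#'
#' @param params Kinetic parameters (x1..x5).
#' @param window c(t_first, t_last) in minutes.
#' @param gridN Dense-grid resolution.
#' @param variant Model variant.
#' @return Dyn in percent of baseline.
#' @export
computeDyn <- function(params, window, gridN = 1000L,
                       variant = c("washout", "uptake")) {
  variant <- match.arg(variant)
  .curveSummary(params, window, 0.05, gridN, variant)$dyn
}

#' Time over threshold (TT)
#'
#' Duration, within the scan window, for which the fitted curve is at or
#' above the enhancement threshold (default 5\% above baseline), estimated
#' by a trapezoidal count of above-threshold cells on a dense grid.
#'
#' @inheritParams computeDyn
#' @param threshold Enhancement threshold (fraction of baseline).
#' @return TT in minutes, in [0, window length].
#' @export
computeTT <- function(params, window, threshold = 0.05, gridN = 1000L,
                      variant = c("washout", "uptake")) {
  variant <- match.arg(variant)
  .curveSummary(params, window, threshold, gridN, variant)$tt
}

#' Area over threshold (AOT)
#'
#' Integral over the scan window of the fitted curve's excess above the
#' enhancement threshold, \eqn{\int \max(f(t) - (1 + thr), 0)\, dt}, by
#' trapezoidal quadrature on a dense grid.
#'
#' @inheritParams computeTT
#' @return AOT in minutes x normalized units, >= 0.
#' @export
computeAOT <- function(params, window, threshold = 0.05, gridN = 1000L,
                       variant = c("washout", "uptake")) {
  variant <- match.arg(variant)
  .curveSummary(params, window, threshold, gridN, variant)$aot
}

## ---------------------------------------------------------------------------
## the fit itself
## ---------------------------------------------------------------------------

## Precompute the variable-projection start search for a fixed time vector.
## The model is linear in (x1, x3, x5) given (x2, x4): for each candidate
## time-constant pair the linear subproblem is solved exactly by QR, and the
## best pairs seed the full 5-parameter Levenberg-Marquardt polish.
.fitContext <- function(times, control) {
  lo <- if (is.null(control$tcLower)) mean(diff(times)) else control$tcLower
  hi <- if (is.null(control$tcUpper)) 2 * (times[length(times)] - times[1L])
        else control$tcUpper
  if (lo <= 0 || hi <= lo) stop("invalid time-constant bounds")
  tc <- exp(seq(log(lo), log(hi), length.out = control$nGrid))
  pairs <- expand.grid(x2 = tc, x4 = tc)
  qrs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x2 <- pairs$x2[i]; x4 <- pairs$x4[i]
    second <- if (control$modelVariant == "washout") exp(-times / x4)
              else 1 - exp(-times / x4)
    B <- cbind(times * exp(-times / x2), second, 1)
    qrs[[i]] <- qr(B)
  }
  list(times = times, lo = lo, hi = hi, pairs = pairs, qrs = qrs)
}

.polish <- function(start, y, times, lo, hi, variant, maxIter) {
  res <- function(p) evalModel(p, times, variant) - y
  jac <- function(p) {
    e2 <- exp(-times / p[2L])
    e4 <- exp(-times / p[4L])
    d3 <- if (variant == "washout") e4 else 1 - e4
    d4 <- if (variant == "washout") p[3L] * e4 * times / p[4L]^2
          else -p[3L] * e4 * times / p[4L]^2
    cbind(times * e2, p[1L] * times^2 * e2 / p[2L]^2, d3, d4, 1)
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, fn = res, jac = jac,
      lower = c(-Inf, lo, -Inf, lo, -Inf),
      upper = c(Inf, hi, Inf, hi, Inf),
      control = minpack.lm::nls.lm.control(maxiter = maxIter))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  if (any(!is.finite(p))) return(NULL)
  list(params = p, sse = sum(residuals(fit)^2))
}

## Sequential multistart polish from a completed variable-projection stage.
## `sse` is the per-pair linear-solve SSE, `coefs` a 3 x npair matrix of
## the corresponding linear coefficients. Starts are polished in order of
## grid SSE with two early exits: a machine-zero SSE (converged), or, after
## at least three polishes, two consecutive relative improvements below
## 0.1% (plateau; further basins would not change the fit materially).
.fitFromStage <- function(y, times, control, ctx, sse, coefs) {
  npair <- length(sse)
  ord <- order(sse)[seq_len(min(control$nStarts, npair))]
  gi <- ord[1L]
  ## grid solution kept as fall-back (and as the exact answer when SSE ~ 0)
  best <- list(params = c(coefs[1L, gi], ctx$pairs$x2[gi], coefs[2L, gi],
                          ctx$pairs$x4[gi], coefs[3L, gi]),
               sse = sse[gi])
  if (sse[gi] > 1e-18) {
    sst <- sum((y - mean(y))^2)
    improvements <- numeric(0)
    for (i in ord) {
      start <- c(coefs[1L, i], ctx$pairs$x2[i], coefs[2L, i],
                 ctx$pairs$x4[i], coefs[3L, i])
      pol <- .polish(start, y, times, ctx$lo, ctx$hi,
                     control$modelVariant, control$maxIter)
      imp <- 0
      if (!is.null(pol) && pol$sse < best$sse) {
        imp <- (best$sse - pol$sse) / best$sse
        best <- pol
      }
      ## an essentially perfect fit: no further basins can matter
      if (best$sse <= max(1e-15, 1e-9 * sst)) break
      improvements <- c(improvements, imp)
      k <- length(improvements)
      ## plateau exit, only for clearly non-interpolating (noisy) fits:
      ## near-perfectly-fittable curves keep searching for the exact basin
      if (best$sse > max(1e-4, 1e-4 * sst) &&
          k >= 3L && all(improvements[(k - 1L):k] < 1e-3)) break
    }
    if (control$extraRestarts > 0L) {
      starts <- withSeed(control$seed, {
        n <- control$extraRestarts
        cbind(stats::runif(n, -0.1, 0.1),
              exp(stats::runif(n, log(ctx$lo), log(ctx$hi))),
              stats::runif(n, -0.2, 0.2),
              exp(stats::runif(n, log(ctx$lo), log(ctx$hi))),
              stats::runif(n, 0.5, 1.5))
      })
      for (k in seq_len(nrow(starts))) {
        pol <- .polish(starts[k, ], y, times, ctx$lo, ctx$hi,
                       control$modelVariant, control$maxIter)
        if (!is.null(pol) && pol$sse < best$sse) best <- pol
      }
    }
  }
  best
}

## Fit one normalized curve; ctx from .fitContext (rebuilt if NULL).
.fitCurve <- function(y, times, control, ctx = NULL) {
  if (is.null(ctx)) ctx <- .fitContext(times, control)
  npair <- nrow(ctx$pairs)
  sse <- numeric(npair)
  coefs <- matrix(0, 3L, npair)
  for (i in seq_len(npair)) {
    cf <- qr.coef(ctx$qrs[[i]], y)
    cf[is.na(cf)] <- 0
    fitted <- qr.fitted(ctx$qrs[[i]], y)
    sse[i] <- sum((y - fitted)^2)
    coefs[, i] <- cf
  }
  .fitFromStage(y, times, control, ctx, sse, coefs)
}

.r2FromSse <- function(sse, y) {
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12) {
    if (sse / length(y) < 1e-12) 1 else 0
  } else 1 - sse / sst
}

#' Fit the kinetic model to one normalized voxel curve
#'
#' Bounded nonlinear least squares of the two-exponential model. Because the
#' model is linear in x1, x3 and x5 given the time constants, starts are
#' found by exact linear solves over a log-spaced grid of (x2, x4) pairs
#' (variable projection); the best pairs are polished with bounded
#' Levenberg-Marquardt and the lowest-SSE solution is kept. The procedure is
#' deterministic.
#'
#' @param curve A normalized curve as returned by \code{\link{normalizeCurve}},
#'   or a numeric vector of normalized values.
#' @param times Acquisition times (required when \code{curve} is numeric).
#' @param control A \code{\link{kineticsControl}}.
#' @return A \linkS4class{KineticFit}.
#' @examples
#' tm <- seq(1, 30, length.out = 8)
#' y <- evalModel(c(0.02, 8, 0.1, 15, 0.95), tm)
#' fitVoxel(y, tm)
#' @export
fitVoxel <- function(curve, times = NULL, control = kineticsControl()) {
  if (is.list(curve)) {
    if (!isTRUE(curve$fittable))
      stop("curve is flagged unfittable (baseline at or below noise floor)")
    times <- curve$times
    y <- curve$values
  } else {
    y <- curve
  }
  times <- .checkTimes(times)
  if (length(y) != length(times)) stop("curve and times lengths differ")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("normalized values must be finite and > 0")
  best <- .fitCurve(y, times, control)
  window <- c(times[1L], times[length(times)])
  if (is.null(best) || any(!is.finite(best$params))) {
    return(new("KineticFit", params = rep(NA_real_, 5), r2 = NA_real_,
               dyn = NA_real_, tt = NA_real_, aot = NA_real_,
               converged = FALSE, window = window,
               variant = control$modelVariant))
  }
  s <- .curveSummary(best$params, window, control$threshold, control$gridN,
                     control$modelVariant)
  new("KineticFit", params = unname(best$params),
      r2 = .r2FromSse(best$sse, y),
      dyn = s$dyn, tt = s$tt, aot = s$aot, converged = TRUE,
      window = window, variant = control$modelVariant)
}

#' Simple accessors for KineticFit
#'
#' @param fit A \linkS4class{KineticFit}.
#' @return The corresponding scalar.
#' @name kineticFitAccessors
NULL

#' @rdname kineticFitAccessors
#' @export
fitR2 <- function(fit) fit@r2

#' @rdname kineticFitAccessors
#' @export
fitDyn <- function(fit) fit@dyn

#' @rdname kineticFitAccessors
#' @export
fitTT <- function(fit) fit@tt

#' @rdname kineticFitAccessors
#' @export
fitAOT <- function(fit) fit@aot

#' @rdname kineticFitAccessors
#' @export
isConverged <- function(fit) fit@converged
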