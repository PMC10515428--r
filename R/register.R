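#' @include AllClasses.R
NULL

## Trilinear resampling of `vol` under a rigid transform. `par` is
## (tx, ty, tz, rx, ry, rz): translations in mm and rotations in degrees
## about the volume centre. Inverse mapping: each target voxel samples the
## moving volume at R * (p - c) + c + t (mm coordinates from voxelDims).
.resampleRigid <- function(vol, par, voxelDims) {
  d <- dim(vol)
  th <- par[4:6] * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx

  ctr <- (d + 1) / 2 * voxelDims
  ix <- (seq_len(d[1]) * voxelDims[1])
  iy <- (seq_len(d[2]) * voxelDims[2])
  iz <- (seq_len(d[3]) * voxelDims[3])
  g <- expand.grid(x = ix, y = iy, z = iz)
  p <- t(R %*% (t(as.matrix(g)) - ctr)) +
    matrix(ctr + par[1:3], nrow(g), 3, byrow = TRUE)
  ## back to voxel indices
  vx <- p[, 1] / voxelDims[1]
  vy <- p[, 2] / voxelDims[2]
  vz <- p[, 3] / voxelDims[3]
  x0 <- floor(vx); y0 <- floor(vy); z0 <- floor(vz)
  fx <- vx - x0; fy <- vy - y0; fz <- vz - z0
  out <- numeric(nrow(g))
  val <- function(xi, yi, zi) {
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    v <- numeric(length(xi))
    idx <- xi[ok] + (yi[ok] - 1) * d[1] + (zi[ok] - 1) * d[1] * d[2]
    v[ok] <- vol[idx]
    v
  }
  out <- val(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
         val(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
         val(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
         val(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
         val(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
         val(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
         val(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
         val(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  array(out, d)
}

.ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

## integer-shift normalized correlation, cheap capture-range search
.shiftNcc <- function(fixed, moving, s) {
  d <- dim(fixed)
  src <- list(max(1, 1 - s[1]):min(d[1], d[1] - s[1]),
              max(1, 1 - s[2]):min(d[2], d[2] - s[2]),
              max(1, 1 - s[3]):min(d[3], d[3] - s[3]))
  dst <- list(src[[1]] + s[1], src[[2]] + s[2], src[[3]] + s[3])
  .ncc(fixed[dst[[1]], dst[[2]], dst[[3]]],
       moving[src[[1]], src[[2]], src[[3]]])
}

#' Rigidly register each frame of a series to the first frame
#'
#' 6-degree-of-freedom (translation + rotation) alignment maximizing
#' normalized correlation with trilinear interpolation. A coarse
#' integer-voxel translation search provides the capture range, followed by
#' Nelder-Mead refinement of all six parameters. Frame 1 is the reference
#' and passes through unchanged. If refinement fails to improve on the
#' identity the frame is passed through unaligned with a warning.
#'
#' @param series A \linkS4class{DceSeries} with at least 2 frames.
#' @param maxShift Half-width (voxels) of the integer translation search.
#' @param maxit Nelder-Mead iteration cap per frame.
#' @return The aligned \linkS4class{DceSeries}; the per-frame transforms
#'   (tx, ty, tz in mm; rx, ry, rz in degrees) and achieved correlations are
#'   attached as attribute \code{"transforms"}.
#' @export
registerSeries <- function(series, maxShift = 4L, maxit = 300L) {
  stopifnot(is(series, "DceSeries"))
  arr <- series@data
  d <- dim(arr)
  if (d[4L] < 2L) stop("registration needs at least 2 frames")
  vd <- series@voxelDims
  fixed <- arr[, , , 1L]
  out <- arr
  log <- matrix(0, nrow = d[4L], ncol = 8L,
                dimnames = list(NULL, c("frame", "tx", "ty", "tz",
                                        "rx", "ry", "rz", "ncc")))
  log[, "frame"] <- seq_len(d[4L])
  log[1L, "ncc"] <- 1
  shifts <- as.matrix(expand.grid(sx = -maxShift:maxShift,
                                  sy = -maxShift:maxShift,
                                  sz = -maxShift:maxShift))
  for (f in 2:d[4L]) {
    moving <- arr[, , , f]
    ncc0 <- .ncc(fixed, moving)
    sc <- apply(shifts, 1L, function(s) .shiftNcc(fixed, moving, s))
    s0 <- shifts[which.max(sc), ]
    ## moving sampled at p + t  <=>  content shifted by -t; initial t in mm
    par0 <- c(-as.numeric(s0) * vd, 0, 0, 0)
    obj <- function(par) -.ncc(fixed, .resampleRigid(moving, par, vd))
    opt <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt) || !all(is.finite(opt$par)) || -opt$value < ncc0) {
      warning("registration did not improve frame ", f,
              "; passing it through unaligned")
      log[f, c("tx", "ty", "tz", "rx", "ry", "rz")] <- NA_real_
      log[f, "ncc"] <- ncc0
      next
    }
    out[, , , f] <- pmax(.resampleRigid(moving, opt$par, vd), 0)
    log[f, c("tx", "ty", "tz", "rx", "ry", "rz")] <- opt$par
    log[f, "ncc"] <- -opt$value
  }
  res <- DceSeries(out, series@times, vd)
  attr(res, "transforms") <- as.data.frame(log)
  res
}
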