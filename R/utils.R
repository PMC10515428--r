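#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so generators are pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## shared argument checks -----------------------------------------------------

.checkTimes <- function(times, minPoints = 7L) {
  if (!is.numeric(times) || length(times) < minPoints)
    stop("acquisition times must be numeric with at least ", minPoints,
         " points, got ", length(times))
  if (any(!is.finite(times)))
    stop("acquisition times must all be finite")
  if (any(times <= 0))
    stop("acquisition times must all be positive (minutes post injection)")
  if (any(diff(times) <= 0))
    stop("acquisition times must be strictly increasing")
  invisible(as.numeric(times))
}

.checkVoxelDims <- function(voxelDims) {
  if (!is.numeric(voxelDims) || length(voxelDims) != 3L ||
      any(!is.finite(voxelDims)) || any(voxelDims <= 0))
    stop("'voxelDims' must be three positive numbers (mm)")
  invisible(as.numeric(voxelDims))
}

.checkMask <- function(mask, dims, what = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'", what, "' must be a 3D array")
  if (!identical(dim(mask), as.integer(dims)))
    stop("'", what, "' dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match the image grid (", paste(dims, collapse = "x"), ")")
  storage.mode(mask) <- "logical"
  invisible(mask)
}
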