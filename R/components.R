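#' @include utils.R
NULL

#' Label connected components in a 3D binary mask
#'
#' Breadth-first labeling with 26- (default) or 6-connectivity.
#' 26-connectivity joins voxels sharing a face, edge or corner, the usual
#' choice for lesion masks since it is least likely to split curved
#' cortical sheets.
#'
#' @param mask 3D logical array.
#' @param connectivity 26 or 6.
#' @return A list with \code{labels} (3D integer array, 0 = background) and
#'   \code{sizes} (integer vector; \code{sizes[k]} is the voxel count of
#'   component k).
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE; m[4, 4, 4] <- TRUE
#' labelComponents(m)$sizes
#' @export
labelComponents <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  pd <- d + 2L
  padded <- array(FALSE, pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.logical(mask)

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  loff <- off[, 1L] + off[, 2L] * pd[1L] + off[, 3L] * pd[1L] * pd[2L]

  lab <- integer(prod(pd))
  fg <- which(padded)
  sizes <- integer(0)
  cur <- 0L
  for (i in fg) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    frontier <- i
    n <- 1L
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[padded[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      n <- n + length(nb)
      frontier <- nb
    }
    sizes[cur] <- n
  }
  labArr <- array(lab, pd)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L),
                           drop = FALSE]
  dim(labArr) <- d
  list(labels = labArr, sizes = sizes)
}
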