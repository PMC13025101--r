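# P5: probability-based peak picking on P3 maps -- local maxima above a
# probability cutoff, refined to sub-pixel positions by three-point quadratic
# interpolation along each dimension.

#' Find local maxima of a probability map
#'
#' A point is a local maximum when its value is strictly greater than all
#' face and diagonal neighbours (out-of-grid neighbours count as -Inf, so
#' edge maxima are allowed). Exact plateaus yield no maximum, which keeps the
#' picker deterministic; maps from continuous data almost surely have none.
#'
#' @param p3 a [P3Map-class] (or plain numeric array).
#' @param cutoff minimum probability, in [0, 1].
#' @return integer matrix of 1-based grid subscripts, one row per maximum.
#' @export
findLocalMaxima <- function(p3, cutoff = 0) {
  a <- if (is(p3, "P3Map")) p3@data else p3
  dims <- dim(a)
  n <- length(dims)
  isMax <- array(TRUE, dim = dims)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), n)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  idx <- seq_len(prod(dims))
  sub <- linearToSub(idx, dims)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(sub, 2L, offs[r, ], `+`)
    ok <- rep(TRUE, nrow(nb))
    for (k in seq_len(n)) ok <- ok & nb[, k] >= 1L & nb[, k] <= dims[k]
    nbv <- rep(-Inf, length(idx))
    nbv[ok] <- a[subToLinear(nb[ok, , drop = FALSE], dims)]
    isMax <- isMax & array(a > nbv, dim = dims)
  }
  keep <- which(isMax & a >= cutoff)
  linearToSub(keep, dims)
}

#' Sub-pixel refinement by quadratic interpolation
#'
#' Along each dimension, fits a parabola through the maximum and its two
#' neighbours; the vertex offset is
#' \eqn{\delta = (y_{-1} - y_{+1}) / (2 (y_{-1} - 2 y_0 + y_{+1}))},
#' clipped to (-0.5, 0.5). At a grid edge, or at zero curvature, the offset
#' is 0 (flagged via the "degenerate" attribute).
#'
#' @param p3 a [P3Map-class] or numeric array.
#' @param index 1-based subscript of a local maximum.
#' @return numeric vector of fractional offsets per dimension.
#' @export
refineQuadratic <- function(p3, index) {
  a <- if (is(p3, "P3Map")) p3@data else p3
  dims <- dim(a)
  n <- length(dims)
  delta <- numeric(n)
  degenerate <- logical(n)
  for (k in seq_len(n)) {
    if (index[k] <= 1L || index[k] >= dims[k]) { degenerate[k] <- TRUE; next }
    at <- function(off) {
      i <- index; i[k] <- i[k] + off
      a[matrix(i, 1L)]
    }
    ym <- at(-1L); y0 <- at(0L); yp <- at(1L)
    curv <- ym - 2 * y0 + yp
    if (curv == 0) { degenerate[k] <- TRUE; next }
    delta[k] <- max(min((ym - yp) / (2 * curv), 0.4999999), -0.4999999)
  }
  attr(delta, "degenerate") <- degenerate
  delta
}

#' Pick peaks from a probability map
#'
#' Locates local maxima at or above the cutoff, refines each to sub-pixel
#' precision, and returns the list sorted by probability (descending).
#' Positions are 0-based fractional grid indices, consistent with the
#' package frequency-axis convention (omega maps to index N (omega + 1/2)).
#'
#' @param p3 a [P3Map-class] or numeric array.
#' @param cutoff probability cutoff in [0, 1].
#' @return data.frame with columns `dim1..dimN` (0-based fractional
#'   positions), `seed1..seedN` (integer 0-based maximum indices) and
#'   `probability`.
#' @export
pickPeaks <- function(p3, cutoff = 0.5) {
  a <- if (is(p3, "P3Map")) p3@data else p3
  dims <- dim(a)
  n <- length(dims)
  seeds <- findLocalMaxima(a, cutoff)
  pos <- matrix(numeric(0), 0L, n)
  if (nrow(seeds) > 0)
    pos <- t(apply(seeds, 1L, function(ix) (ix - 1) + refineQuadratic(a, ix)))
  if (n == 1L) pos <- t(pos)
  prob <- if (nrow(seeds) > 0) a[subToLinear(seeds, dims)] else numeric(0)
  out <- data.frame(pos, seeds - 1L, prob)
  names(out) <- c(paste0("dim", seq_len(n)), paste0("seed", seq_len(n)), "probability")
  out[order(-out$probability), , drop = FALSE]
}

#' Write a peak list as TSV
#'
#' @param peaks data.frame from [pickPeaks()].
#' @param path output file.
#' @export
writePeakList <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
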