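# Non-uniform sampling: schedule generation, time-domain subsampling,
# CS-IST compressed-sensing reconstruction, and regeneration of time-domain
# data from processed spectra.

# 1D Poisson-gap positions (sinusoidally weighted gap lengths), adjusted to
# hit exactly k of T increments; always includes t = 0.
poissonGap1D <- function(T, k) {
  if (k >= T) return(0:(T - 1))
  drawOnce <- function(adj) {
    pos <- integer(0)
    x <- 0
    while (x < T) {
      pos <- c(pos, x)
      g <- stats::rpois(1, adj * sin((x + 0.5) / (T + 1) * pi / 2))
      x <- x + 1L + g
    }
    pos
  }
  adj <- 2 * (T / k - 1) # initial guess for the gap intensity
  for (it in 1:200) {
    pos <- drawOnce(adj)
    if (length(pos) == k) return(pos)
    adj <- max(0, adj * (1 + 0.1 * sign(length(pos) - k)) + 0.01 * (length(pos) - k))
  }
  # fall back: trim or pad the closest draw
  if (length(pos) > k) sort(c(0, sample(pos[-1], k - 1)))
  else sort(unique(c(pos, sample(setdiff(0:(T - 1), pos), k - length(pos)))))
}

#' Generate a NUS schedule
#'
#' For \code{"uniform_random"}, increments are drawn uniformly without
#' replacement over the full indirect grid. \code{"poisson_gap"} uses
#' sinusoidally weighted Poisson gap lengths per indirect dimension; with two
#' indirect dimensions the schedule is the tensor product of per-dimension
#' 1D schedules with fraction \code{fraction^(1/2)} each, trimmed or padded
#' to the exact total count. The t = 0 increment is always kept.
#'
#' @param grid an [AcqGrid-class]; dimension 1 is the (fully sampled) direct
#'   dimension, schedules cover the remaining indirect dimensions.
#' @param fraction sampled fraction in (0, 1].
#' @param kind "uniform_random" or "poisson_gap".
#' @param seed optional seed.
#' @return A [SamplingSchedule-class].
#' @export
makeSchedule <- function(grid, fraction, kind = c("uniform_random", "poisson_gap"),
                         seed = NULL) {
  kind <- match.arg(kind)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  Tn <- grid@points[-1L]
  total <- prod(Tn)
  k <- round(fraction * total)
  if (k < 1) stop("fraction yields zero sampled increments")
  draw <- function() {
    if (kind == "uniform_random") {
      keep <- if (k == total) seq_len(total) else
        sort(unique(c(1L, sample.int(total, k)))) # 1 = the all-zero tuple
      while (length(keep) < k)
        keep <- sort(unique(c(keep, sample.int(total, k - length(keep)))))
      keep <- keep[seq_len(k)]
      idx <- linearToSub(keep, Tn) - 1L
    } else {
      per <- lapply(seq_along(Tn), function(d)
        poissonGap1D(Tn[d], max(1L, round(Tn[d] * fraction^(1 / length(Tn))))))
      idx <- as.matrix(expand.grid(per))
      # adjust the product set to the exact count, keeping t = 0
      lin <- subToLinear(idx + 1L, Tn)
      if (length(lin) > k) {
        drop <- sample(which(rowSums(idx != 0) > 0), length(lin) - k)
        idx <- idx[-drop, , drop = FALSE]
      } else if (length(lin) < k) {
        pool <- setdiff(seq_len(total), lin)
        idx <- rbind(idx, linearToSub(sample(pool, k - length(lin)), Tn) - 1L)
      }
      idx
    }
  }
  idx <- if (is.null(seed)) draw() else withSeed(seed, draw())
  idx <- idx[order(subToLinear(idx + 1L, Tn)), , drop = FALSE]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  new("SamplingSchedule", indices = idx, fraction = fraction, kind = kind,
      gridPoints = Tn)
}

scheduleMask <- function(schedule) {
  m <- array(FALSE, dim = schedule@gridPoints)
  m[subToLinear(schedule@indices + 1L, schedule@gridPoints)] <- TRUE
  m
}

#' Subsample a hypercomplex FID according to a schedule
#'
#' Unsampled indirect increments are stored as zeros with an attached logical
#' mask (attribute \code{"sampledMask"}, over the indirect grid) marking
#' which increments were actually measured.
#'
#' @param fid array from [simulateFid()].
#' @param schedule a [SamplingSchedule-class] matching the fid's indirect
#'   dimensions.
#' @return the masked fid array with the \code{"sampledMask"} attribute.
#' @export
subsampleFid <- function(fid, schedule) {
  d <- dim(fid)
  n <- length(d) - 1L
  Tn <- d[2:n]
  if (!all(Tn == schedule@gridPoints)) stop("schedule does not fit the fid grid")
  m <- scheduleMask(schedule)
  full <- array(rep(as.numeric(m), each = d[1L]), dim = d[-length(d)])
  out <- fid * as.numeric(full) # broadcast over components
  attr(out, "sampledMask") <- m
  out
}

# Soft threshold on the joint hypercomplex magnitude: shrink the length of
# the 2^n-component vector at every grid point by lambda, to zero at most.
softThresholdHC <- function(comp, lambda) {
  d <- dim(comp)
  nc <- d[length(d)]
  m <- matrix(comp, ncol = nc)
  mag <- sqrt(rowSums(m * m))
  scl <- pmax(0, 1 - lambda / pmax(mag, .Machine$double.eps))
  array(m * scl, dim = d)
}

#' CS-IST reconstruction of a subsampled FID
#'
#' Iterative soft thresholding with data-consistency reinsertion: transform
#' the current time-domain estimate to the frequency domain, soft-threshold
#' the hypercomplex magnitude with a threshold decaying linearly from
#' \code{0.9 x max} to 0, transform back, and re-impose the measured
#' increments. The estimate is therefore exactly data-consistent at the
#' measured increments at every iteration. The completed FID is then put
#' through the standard processing chain.
#'
#' @param sparseFid output of [subsampleFid()] (with its sampledMask).
#' @param grid the [AcqGrid-class].
#' @param nIterations number of IST iterations (default 200).
#' @param threshold0 initial threshold as a fraction of the maximum
#'   hypercomplex magnitude (default 0.9).
#' @return An [NMRSpectrum-class]; attribute \code{"istRelChange"} carries the
#'   final relative update size, with a warning if it exceeds 1e-3.
#' @export
csIstReconstruct <- function(sparseFid, grid, nIterations = 200, threshold0 = 0.9) {
  m <- attr(sparseFid, "sampledMask")
  if (is.null(m)) stop("sparseFid must carry a sampledMask (see subsampleFid)")
  d <- dim(sparseFid)
  n <- length(d) - 1L
  full <- array(rep(as.numeric(m), each = d[1L]), dim = d[-length(d)])
  measured <- which(rep(as.numeric(full) > 0, times = d[length(d)]))
  data <- as.numeric(sparseFid)
  z <- array(data, dim = d)
  Z0 <- hcFFT(z)
  lam0 <- threshold0 * max(sqrt(rowSums(matrix(Z0, ncol = d[length(d)])^2)))
  rel <- Inf
  for (it in seq_len(nIterations)) {
    lam <- lam0 * (1 - it / nIterations)
    Z <- hcFFT(z)
    Z <- softThresholdHC(Z, lam)
    znew <- hcIFFT(Z)
    znew[measured] <- data[measured]
    rel <- sqrt(sum((znew - z)^2) / max(sum(z^2), .Machine$double.eps))
    z <- znew
  }
  if (rel > 1e-3)
    warning(sprintf("CS-IST did not settle (final relative update %.2g)", rel))
  out <- processSpectrum(z, grid)
  attr(out, "istRelChange") <- rel
  out
}

# Discrete Hilbert pair: given the real (absorption) part of the DFT of a
# causal complex signal (zero-filled by >= 2), reconstruct the full complex
# spectrum along dimension `dim` of an (unshifted) array.
hilbertPairDim <- function(x, dimK) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  perm <- seq_along(d)
  if (dimK != 1L) { perm <- c(dimK, perm[-dimK]); x <- aperm(x, perm) }
  dp <- dim(x); if (is.null(dp)) dp <- length(x)
  xm <- matrix(x, nrow = dp[1])
  N <- nrow(xm)
  r <- stats::mvfft(xm, inverse = TRUE) / N  # "time" signal of the real part
  h <- c(1, rep(2, N / 2 - 1), rep(0, N / 2)) # causal projection (t=0..N/2-1)
  z <- stats::mvfft(r * h)
  out <- array(z, dim = dp)
  if (dimK != 1L) out <- aperm(out, order(perm))
  out
}

#' Regenerate time-domain data from a processed spectrum
#'
#' Inverts the processing chain: when all quadrature components are present
#' the inversion is exact (inverse FT per dimension, remove the zero-filled
#' tail, divide out the apodization window). For an absorption-only
#' spectrum the missing quadrature parts are first restored with the
#' discrete Hilbert transform (valid because zero filling by a factor >= 2
#' makes the underlying time signal causal), as done when turning archived
#' frequency-domain spectra back into FIDs.
#'
#' @param spectrum an [NMRSpectrum-class] whose grid records the zero-fill
#'   factors (all must be >= 2).
#' @return hypercomplex FID array of the original (pre-zero-fill) size.
#' @export
toTimeDomain <- function(spectrum) {
  grid <- spectrum@grid
  if (any(grid@zeroFill < 2L))
    stop("time-domain regeneration requires zero-fill metadata with factor >= 2")
  n <- grid@nDims
  d <- dim(spectrum@components)
  comp <- spectrum@components
  if (d[n + 1L] == 1L) {
    # restore quadrature via the Hilbert relation, dimension at a time
    x <- array(comp, dim = d[seq_len(n)]) # absorption, shifted axes
    for (k in seq_len(n)) { # unshift all axes first
      N <- d[k]
      idx <- rep(list(quote(expr = )), n); idx[[k]] <- shiftIndex(N)
      x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    }
    comps <- list(x) # components indexed by bit pattern, built up per dim
    for (k in seq_len(n)) {
      comps <- unlist(lapply(comps, function(a) {
        z <- hilbertPairDim(a, k)
        list(Re(z), Im(z))
      }), recursive = FALSE)
    }
    # comps is ordered with dim-1 bit slowest; reorder to bit-k fastest-in-k
    nc <- 2L^n
    comp <- array(0, dim = c(d[seq_len(n)], nc))
    cm <- matrix(comp, ncol = nc)
    for (i in seq_len(nc)) {
      bitsFast <- as.integer(intToBits(i - 1L))[seq_len(n)] # bit per dim
      j <- sum(bitsFast * 2L^((n - 1L):0L)) + 1L            # position in comps
      cm[, i] <- as.numeric(comps[[j]])
    }
    comp <- array(cm, dim = c(d[seq_len(n)], nc))
    shifted <- FALSE
  } else shifted <- TRUE
  for (k in seq_len(n)) {
    Tk <- grid@points[k]
    Nk <- Tk * grid@zeroFill[k]
    w <- apodWindow(Tk, grid@apod) * c(0.5, rep(1, Tk - 1L))
    sh <- if (shifted) order(shiftIndex(Nk)) else seq_len(Nk)
    comp <- hcApplyDim(comp, k, function(z) {
      z <- stats::mvfft(z[sh, , drop = FALSE], inverse = TRUE) / Nk
      z[seq_len(Tk), , drop = FALSE] / w
    }, newLen = Tk)
  }
  comp
}

#' Re-zero-fill a spectrum
#'
#' Regenerates the time domain and reprocesses with larger zero-fill
#' factors, e.g. the extra doubling applied before probability-map
#' generation for finer peak-position sampling.
#'
#' @param spectrum an [NMRSpectrum-class] with full quadrature.
#' @param factor multiplicative increase of the zero-fill factors.
#' @return the reprocessed [NMRSpectrum-class].
#' @export
rezeroFill <- function(spectrum, factor = 2L) {
  fid <- toTimeDomain(spectrum)
  g <- spectrum@grid
  g2 <- acqGrid(g@points, g@zeroFill * as.integer(factor), g@apod)
  out <- processSpectrum(fid, g2)
  out@sigmaNoise <- spectrum@sigmaNoise
  out
}

#' Read/write plain-text NUS schedules
#'
#' One increment tuple per line, space-separated 0-based integers (nuslist
#' dialect).
#'
#' @param schedule a [SamplingSchedule-class].
#' @param path file path.
#' @param gridPoints,fraction,kind metadata to attach on read.
#' @return `readSchedule` returns a [SamplingSchedule-class].
#' @export
writeSchedule <- function(schedule, path) {
  utils::write.table(schedule@indices, path, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path, gridPoints, fraction = NA_real_,
                         kind = "uniform_random") {
  idx <- as.matrix(utils::read.table(path))
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  if (is.na(fraction)) fraction <- nrow(idx) / prod(gridPoints)
  new("SamplingSchedule", indices = idx, fraction = fraction, kind = kind,
      gridPoints = as.integer(gridPoints))
}
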