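# Simulation of hypercomplex FIDs from the damped complex-exponential model,
# standard frequency-domain processing, ground-truth label masks and skyline
# projections.

#' Simulate a hypercomplex FID
#'
#' Evaluates the superposition of damped complex exponentials
#' \eqn{X(t_1,\dots,t_n) = \sum_j s_j A_j \prod_n e^{-t_n/\tau_{nj}}
#' e^{i(2\pi\omega_{nj} t_n + \phi_{nj})}} on the acquisition grid, returning
#' all 2^n real quadrature components (States convention): component
#' \code{1 + sum(bit_k 2^(k-1))} carries the sine part in every dimension k
#' with bit_k = 1. Amplitudes are used literally as time-domain amplitudes;
#' the spectrum synthesizers rescale them to spectral signal-to-noise units
#' via [peakHeightFactor()].
#'
#' @param params a [SignalParams-class]; frequencies must lie strictly inside
#'   the Nyquist band and relaxation times and amplitudes must be positive.
#' @param grid an [AcqGrid-class].
#' @return numeric array with dim \code{c(points, 2^n)}.
#' @examples
#' g <- acqGrid(c(16, 16))
#' p <- signalParams(1, c(0, 0), c(1e6, 1e6))
#' fid <- simulateFid(p, g)
#' fid[1, 1, 1]  # cosine-cosine channel at t = 0: equals the amplitude
#' @export
simulateFid <- function(params, grid) {
  validObject(params)
  n <- grid@nDims
  stopifnot(ncol(params@frequency) == n)
  Tn <- grid@points
  nc <- 2L^n
  out <- matrix(0, prod(Tn), nc)
  J <- nPeaks(params)
  phase <- params@phase * pi / 180
  for (j in seq_len(J)) {
    trig <- vector("list", n) # per dim: list(cos vector, sin vector)
    for (k in seq_len(n)) {
      t <- 0:(Tn[k] - 1)
      env <- exp(-t / params@relaxation[j, k])
      arg <- 2 * pi * params@frequency[j, k] * t + phase[j, k]
      trig[[k]] <- list(env * cos(arg), env * sin(arg))
    }
    amp <- params@sign[j] * params@amplitude[j]
    for (cc in seq_len(nc)) {
      bits <- bitwAnd(cc - 1L, 2L^(seq_len(n) - 1L)) > 0L
      term <- Reduce(`%o%`, lapply(seq_len(n), function(k) trig[[k]][[bits[k] + 1L]]))
      out[, cc] <- out[, cc] + amp * as.numeric(term)
    }
  }
  array(out, dim = c(Tn, nc))
}

# Apply f(z) -> z (complex matrix op along first dim) over dimension k of a
# hypercomplex component array, pairing cos/sin components of dimension k.
# f maps a (len x m) complex matrix to a (newLen x m) complex matrix.
hcApplyDim <- function(comp, k, f, newLen = NULL) {
  d <- dim(comp)
  n <- length(d) - 1L
  nc <- d[n + 1L]
  bit <- 2L^(k - 1L)
  perm <- c(k, seq_len(n + 1L)[-k])
  x <- aperm(comp, perm)
  dp <- dim(x)
  x <- matrix(x, nrow = d[k])
  m <- ncol(x) / nc
  if (is.null(newLen)) newLen <- d[k]
  outm <- matrix(0, newLen, ncol(x))
  for (cc in seq_len(nc)) {
    if (bitwAnd(cc - 1L, bit) > 0L) next
    cols0 <- (cc - 1L) * m + seq_len(m)
    cols1 <- (cc - 1L + bit) * m + seq_len(m)
    z <- f(x[, cols0, drop = FALSE] + 1i * x[, cols1, drop = FALSE])
    outm[, cols0] <- Re(z)
    outm[, cols1] <- Im(z)
  }
  dp[1] <- newLen
  out <- array(outm, dim = dp)
  aperm(out, order(perm))
}

# Forward/inverse hypercomplex DFT over the given dims (no window/zero fill,
# no shift) -- the linear transform pair used inside CS-IST.
hcFFT <- function(comp, dims = seq_len(length(dim(comp)) - 1L)) {
  for (k in dims) comp <- hcApplyDim(comp, k, function(z) stats::mvfft(z))
  comp
}

hcIFFT <- function(comp, dims = seq_len(length(dim(comp)) - 1L)) {
  for (k in dims)
    comp <- hcApplyDim(comp, k, function(z) stats::mvfft(z, inverse = TRUE) / nrow(z))
  comp
}

#' Process a hypercomplex FID to a frequency-domain spectrum
#'
#' Standard nD processing: apodization, zero filling (factor >= 2), Fourier
#' transform and frequency-axis shift, performed dimension at a time on the
#' hypercomplex components. All quadrature components are retained for
#' downstream use (exact time-domain regeneration, Fisher-information work).
#'
#' @param fid numeric array from [simulateFid()] (dim \code{c(points, 2^n)}).
#' @param grid the matching [AcqGrid-class]; every zero-fill factor must be
#'   >= 2.
#' @param sigmaNoise optional known noise sigma to record on the spectrum.
#' @return An [NMRSpectrum-class].
#' @export
processSpectrum <- function(fid, grid, sigmaNoise = NA_real_) {
  if (any(grid@zeroFill < 2L))
    stop("zero-fill factor must be >= 2 in every dimension")
  d <- dim(fid)
  n <- grid@nDims
  if (length(d) != n + 1L || !all(d[seq_len(n)] == grid@points) || d[n + 1L] != 2L^n)
    stop("fid shape does not match the acquisition grid")
  comp <- fid
  for (k in seq_len(n)) {
    Tk <- grid@points[k]
    Nk <- Tk * grid@zeroFill[k]
    # halve the first increment: removes the DC baseline offset of the
    # one-sided DFT (standard first-point scaling)
    w <- apodWindow(Tk, grid@apod) * c(0.5, rep(1, Tk - 1L))
    sh <- shiftIndex(Nk)
    comp <- hcApplyDim(comp, k, function(z) {
      z <- z * w
      z <- rbind(z, matrix(0, Nk - Tk, ncol(z)))
      stats::mvfft(z)[sh, , drop = FALSE]
    }, newLen = Nk)
  }
  newSpectrum(comp, grid, sigmaNoise)
}

#' On-resonance peak height response of the processing chain
#'
#' For a unit time-domain amplitude, the absorption-mode height of a peak at
#' an exact grid frequency is \eqn{\prod_n \sum_t w(t) e^{-t/\tau_n}}. Used to
#' express amplitudes in spectral signal-to-noise units.
#'
#' @param grid an [AcqGrid-class].
#' @param relaxation J x n matrix (or length-n vector) of relaxation times.
#' @return numeric vector of height factors, one per row.
#' @export
peakHeightFactor <- function(grid, relaxation) {
  if (is.null(dim(relaxation))) relaxation <- matrix(relaxation, nrow = 1)
  apply(relaxation, 1L, function(tau) {
    prod(vapply(seq_len(grid@nDims), function(k) {
      Tk <- grid@points[k]
      t <- 0:(Tk - 1)
      w <- apodWindow(Tk, grid@apod) * c(0.5, rep(1, Tk - 1L))
      sum(w * exp(-t / tau[k]))
    }, 1.0))
  })
}

#' @describeIn peakHeightFactor frequency-domain noise sigma produced by unit
#'   time-domain Gaussian noise under the same processing chain,
#'   \eqn{\sqrt{\prod_n \sum_t w(t)^2}}.
#' @export
noiseSigmaFactor <- function(grid) {
  sqrt(prod(vapply(seq_len(grid@nDims), function(k) {
    Tk <- grid@points[k]
    w <- apodWindow(Tk, grid@apod) * c(0.5, rep(1, Tk - 1L))
    sum(w^2)
  }, 1.0)))
}

#' Ground-truth label mask for peak maxima
#'
#' Marks the grid index nearest to each theoretical peak maximum with 1. When
#' the fractional position falls 0.25 to 0.75 units from both neighbouring
#' indices in a dimension, both are marked (dual labeling); a dual partner
#' falling outside the grid is dropped.
#'
#' @param params the ground-truth [SignalParams-class].
#' @param spectrum the processed [NMRSpectrum-class] (defines the grid).
#' @return A [LabelMask-class].
#' @export
makeLabelMask <- function(params, spectrum) {
  n <- spectrumDims(spectrum)
  N <- specSize(spectrum@grid)
  mask <- array(0, dim = N)
  for (j in seq_len(nPeaks(params))) {
    sets <- lapply(seq_len(n), function(k) {
      u <- freqToIndex(params@frequency[j, k], N[k])
      lo <- floor(u); frac <- u - lo
      cand <- if (frac >= 0.25 && frac <= 0.75) c(lo, lo + 1) else round(u)
      unique(pmin(pmax(cand, 0), N[k] - 1)) + 1L # clip edge partners, to 1-based
    })
    sub <- as.matrix(expand.grid(sets))
    mask[subToLinear(sub, N)] <- 1
  }
  new("LabelMask", data = mask)
}

#' Skyline projection of a spectrum
#'
#' Element-wise maximum of the absorption part over one axis, the standard
#' skyline convention for reducing a 3D spectrum to its orthogonal 2D
#' projections.
#'
#' @param spectrum an [NMRSpectrum-class] with >= 2 dimensions.
#' @param droppedAxis which axis to project out (1-based).
#' @return An (n-1)-dimensional [NMRSpectrum-class] holding the absorption
#'   part only.
#' @export
skylineProject <- function(spectrum, droppedAxis) {
  n <- spectrumDims(spectrum)
  if (n < 2L) stop("projection needs >= 2 dimensions")
  if (!(droppedAxis %in% seq_len(n))) stop("invalid axis index: ", droppedAxis)
  keep <- setdiff(seq_len(n), droppedAxis)
  proj <- apply(intensity(spectrum), keep, max)
  g <- spectrum@grid
  grid2 <- acqGrid(g@points[keep], g@zeroFill[keep], g@apod)
  newSpectrum(array(proj, dim = c(dim(proj), 1L)), grid2, NA_real_)
}

#' Default parameter ranges for synthetic spectra
#'
#' Amplitudes are log-uniform over a 1:200 dynamic range in spectral
#' sigma-noise units (weakest peaks down to one sigma), relaxation times
#' log-uniform in dwell units, frequencies uniform inside the Nyquist band
#' with an edge margin, phases uniform in a narrow band (degrees).
#'
#' @param ampRange,tauRange,phaseRange two-element min/max vectors.
#' @param freqMargin margin (cycles/dwell) kept clear of the band edges.
#' @return list of ranges consumed by [sampleSpectrumParams()].
#' @export
spectrumParamRanges <- function(ampRange = c(1, 200), tauRange = c(8, 128),
                                phaseRange = c(-5, 5), freqMargin = 0.05) {
  for (r in list(ampRange, tauRange, phaseRange))
    if (length(r) != 2L || r[1] > r[2]) stop("empty or inverted parameter range")
  list(ampRange = ampRange, tauRange = tauRange, phaseRange = phaseRange,
       freqMargin = freqMargin)
}

#' Draw random peak parameters
#'
#' @param ranges from [spectrumParamRanges()].
#' @param nPeaks number of peaks to draw.
#' @param nDims spectrum dimensionality.
#' @param seed optional seed for reproducible draws.
#' @return A [SignalParams-class] with amplitudes in sigma-noise units.
#' @export
sampleSpectrumParams <- function(ranges = spectrumParamRanges(), nPeaks, nDims = 2L,
                                 seed = NULL) {
  draw <- function() {
    J <- nPeaks
    lim <- 0.5 - ranges$freqMargin
    signalParams(
      amplitude = exp(stats::runif(J, log(ranges$ampRange[1]), log(ranges$ampRange[2]))),
      frequency = matrix(stats::runif(J * nDims, -lim, lim), J, nDims),
      relaxation = matrix(exp(stats::runif(J * nDims, log(ranges$tauRange[1]),
                                           log(ranges$tauRange[2]))), J, nDims),
      phase = matrix(stats::runif(J * nDims, ranges$phaseRange[1],
                                  ranges$phaseRange[2]), J, nDims)
    )
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Synthesize a noisy spectrum in sigma-noise units
#'
#' Rescales the drawn amplitudes (interpreted as spectral signal-to-noise)
#' to time-domain amplitudes via the processing height response, simulates
#' and processes the FID, and adds frequency-normalized noise with
#' target sigma 1, so that an amplitude of A corresponds to a spectral peak
#' height of A sigma-noise.
#'
#' @param params [SignalParams-class] with amplitudes in sigma units.
#' @param grid an [AcqGrid-class].
#' @param noise a noise specification from [noiseSpec()], or NULL for a
#'   noise-free spectrum.
#' @param seed optional seed for the noise draw.
#' @return list with elements \code{spectrum} ([NMRSpectrum-class], sigmaNoise
#'   set to 1 when noise is added), \code{labels} ([LabelMask-class]) and
#'   \code{params}.
#' @export
synthesizeSpectrum <- function(params, grid, noise = noiseSpec("gaussian"),
                               seed = NULL) {
  p <- params
  if (nPeaks(p) > 0)
    p@amplitude <- p@amplitude / peakHeightFactor(grid, p@relaxation)
  fid <- simulateFid(p, grid)
  spec <- processSpectrum(fid, grid)
  if (!is.null(noise)) {
    nz <- makeNoise(noise, grid, seed = seed)
    spec@components <- spec@components + nz
    spec@sigmaNoise <- noise$targetSigma
  } else {
    spec@sigmaNoise <- NA_real_
  }
  list(spectrum = spec, labels = makeLabelMask(params, spec), params = params)
}
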