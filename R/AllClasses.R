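#' @import methods
NULL

#' Acquisition grid for a hypercomplex nD NMR experiment
#'
#' Describes the time-domain sampling of an n-dimensional (n = 2, 3)
#' quadrature-detected experiment: complex-point counts per dimension,
#' zero-fill factors and the apodization window applied before the
#' Fourier transform. Evolution times are the integer series
#' 0, 1, ..., T_n - 1 in dwell-time units, so frequencies are expressed
#' in cycles per dwell and must stay inside the Nyquist band (-0.5, 0.5).
#'
#' @slot nDims number of dimensions (2 or 3); dimension 1 is the direct one.
#' @slot points integer vector of complex points T_n per dimension.
#' @slot zeroFill integer zero-fill factors per dimension (>= 2 for processing).
#' @slot apod apodization window name: "cos2" (cosine squared) or "none".
#' @export
setClass("AcqGrid", representation(
  nDims = "integer", points = "integer", zeroFill = "integer",
  apod = "character"
))

setValidity("AcqGrid", function(object) {
  msg <- NULL
  if (!(object@nDims %in% c(1L, 2L, 3L))) msg <- c(msg, "nDims must be 1, 2 or 3")
  if (length(object@points) != object@nDims) msg <- c(msg, "points length != nDims")
  if (any(object@points < 2L)) msg <- c(msg, "need >= 2 complex points per dimension")
  if (length(object@zeroFill) != object@nDims) msg <- c(msg, "zeroFill length != nDims")
  if (any(object@zeroFill < 1L)) msg <- c(msg, "zeroFill factors must be >= 1")
  if (!object@apod %in% c("cos2", "none")) msg <- c(msg, "unknown apodization window")
  if (is.null(msg)) TRUE else msg
})

#' Construct an acquisition grid
#'
#' @param points complex-point counts per dimension (direct dimension first).
#' @param zeroFill zero-fill factor(s), recycled over dimensions. Must be >= 2
#'   for spectral processing: a non-decaying signal has to be zero-padded to at
#'   least twice its length before the discrete Fourier transform.
#' @param apod apodization window, `"cos2"` (default) or `"none"`.
#' @return An [AcqGrid-class] object.
#' @examples
#' acqGrid(c(128, 64))
#' @export
acqGrid <- function(points, zeroFill = 2L, apod = "cos2") {
  n <- length(points)
  new("AcqGrid", nDims = as.integer(n), points = as.integer(points),
      zeroFill = as.integer(rep_len(zeroFill, n)), apod = apod)
}

#' @describeIn acqGrid spectrum sizes after zero filling, per dimension.
#' @param grid an `AcqGrid`.
#' @export
specSize <- function(grid) grid@points * grid@zeroFill

setMethod("show", "AcqGrid", function(object) {
  cat(sprintf("AcqGrid: %dD, %s complex points, zero fill %s, apod '%s'\n",
              object@nDims, paste(object@points, collapse = " x "),
              paste(object@zeroFill, collapse = "/"), object@apod))
})

#' Per-peak signal parameters of the exponential FID model
#'
#' Parameter set of the damped complex-exponential model: each peak j has an
#' amplitude A_j, and per dimension a frequency (cycles/dwell), a relaxation
#' time (dwell units), and a phase (degrees). `sign` carries the +/-1 signs
#' used when spectra are combined into positive/negative groups for 3D
#' training. Amplitudes are interpreted in units of the spectral noise sigma
#' by the spectrum synthesizers; [simulateFid()] treats them literally as
#' time-domain amplitudes.
#'
#' @slot amplitude positive numeric vector (length J).
#' @slot frequency J x n matrix, |omega| < 0.5 cycles/dwell.
#' @slot relaxation J x n matrix of positive relaxation times (dwell units).
#' @slot phase J x n matrix of phases in degrees.
#' @slot sign numeric vector of +1/-1.
#' @export
setClass("SignalParams", representation(
  amplitude = "numeric", frequency = "matrix", relaxation = "matrix",
  phase = "matrix", sign = "numeric"
))

setValidity("SignalParams", function(object) {
  J <- length(object@amplitude)
  msg <- NULL
  if (J > 0 && any(object@amplitude <= 0)) msg <- c(msg, "amplitudes must be > 0")
  for (s in c("frequency", "relaxation", "phase"))
    if (nrow(slot(object, s)) != J) msg <- c(msg, sprintf("%s rows != J", s))
  if (J > 0 && any(abs(object@frequency) >= 0.5))
    msg <- c(msg, "frequencies must lie strictly inside the Nyquist band (|omega| < 0.5)")
  if (J > 0 && any(object@relaxation <= 0)) msg <- c(msg, "relaxation times must be > 0")
  if (length(object@sign) != J || (J > 0 && !all(object@sign %in% c(-1, 1))))
    msg <- c(msg, "sign must be +1/-1 per peak")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignalParams object
#'
#' @param amplitude numeric vector of peak amplitudes (length J).
#' @param frequency,relaxation,phase J x n matrices (or vectors for J = 1).
#' @param sign optional +/-1 per peak (default +1).
#' @return A [SignalParams-class] object.
#' @export
signalParams <- function(amplitude, frequency, relaxation, phase = NULL, sign = NULL) {
  J <- length(amplitude)
  asMat <- function(x, what) {
    if (is.null(dim(x))) x <- matrix(x, nrow = J, byrow = J == 1L)
    if (J == 1L && nrow(x) != 1L) x <- matrix(as.numeric(x), nrow = 1L)
    storage.mode(x) <- "double"
    x
  }
  frequency <- asMat(frequency)
  relaxation <- asMat(relaxation)
  if (is.null(phase)) phase <- matrix(0, J, ncol(frequency))
  phase <- asMat(phase)
  if (is.null(sign)) sign <- rep(1, J)
  new("SignalParams", amplitude = as.numeric(amplitude), frequency = frequency,
      relaxation = relaxation, phase = phase, sign = as.numeric(sign))
}

#' @describeIn signalParams number of peaks.
#' @param params a `SignalParams`.
#' @export
nPeaks <- function(params) length(params@amplitude)

setMethod("show", "SignalParams", function(object) {
  cat(sprintf("SignalParams: %d peak(s), %d dimension(s)\n",
              nPeaks(object), ncol(object@frequency)))
  if (nPeaks(object) > 0)
    cat(sprintf("  amplitude range [%.3g, %.3g]\n",
                min(object@amplitude), max(object@amplitude)))
})

#' Processed frequency-domain spectrum with retained quadrature
#'
#' Holds all 2^n real quadrature components of a processed nD spectrum on the
#' zero-filled grid. Component 1 is the absorption spectrum; component
#' 1 + sum(bit_k 2^(k-1)) holds the part that is "imaginary" (sine) in every
#' dimension k with bit_k = 1. The frequency axis convention, used everywhere
#' in the package, is: 0-based index j corresponds to frequency
#' (j - N/2) / N cycles/dwell, i.e. index 0 is -Nyquist and omega = 0 maps to
#' index N/2.
#'
#' @slot components numeric array with dim c(N_1, ..., N_n, nComp); nComp is
#'   2^n when all quadrature parts are retained, 1 for absorption-only data
#'   (e.g. skyline projections).
#' @slot grid the [AcqGrid-class] the data were processed from.
#' @slot sigmaNoise robust noise sigma of the absorption part (NA if unset).
#' @export
setClass("NMRSpectrum", representation(
  components = "array", grid = "AcqGrid", sigmaNoise = "numeric"
))

setValidity("NMRSpectrum", function(object) {
  d <- dim(object@components)
  n <- object@grid@nDims
  msg <- NULL
  if (length(d) != n + 1L) msg <- c(msg, "components must have nDims + 1 array dimensions")
  else {
    if (!all(d[seq_len(n)] == specSize(object@grid)))
      msg <- c(msg, "array shape must equal the post-zero-fill sizes")
    if (!d[n + 1L] %in% c(1L, 2L^n)) msg <- c(msg, "need 1 or 2^n quadrature components")
  }
  if (length(object@sigmaNoise) != 1L || (!is.na(object@sigmaNoise) && object@sigmaNoise < 0))
    msg <- c(msg, "sigmaNoise must be a single nonnegative value or NA")
  if (is.null(msg)) TRUE else msg
})

newSpectrum <- function(components, grid, sigmaNoise = NA_real_) {
  new("NMRSpectrum", components = components, grid = grid,
      sigmaNoise = as.numeric(sigmaNoise))
}

#' @describeIn intensity number of spectral dimensions.
#' @export
spectrumDims <- function(spectrum) spectrum@grid@nDims

#' Absorption part of a spectrum
#'
#' @param spectrum an [NMRSpectrum-class].
#' @return The real absorption-mode array (first quadrature component).
#' @export
intensity <- function(spectrum) {
  d <- dim(spectrum@components)
  n <- length(d) - 1L
  idx <- c(lapply(d[seq_len(n)], seq_len), list(1L))
  array(do.call(`[`, c(list(spectrum@components), idx)), dim = d[seq_len(n)])
}

#' @describeIn intensity noise sigma, estimated robustly if unset.
#' @export
sigmaNoise <- function(spectrum) {
  if (is.na(spectrum@sigmaNoise)) robustSigma(intensity(spectrum)) else spectrum@sigmaNoise
}

setMethod("show", "NMRSpectrum", function(object) {
  d <- dim(object@components)
  n <- length(d) - 1L
  cat(sprintf("NMRSpectrum: %dD, %s points, %d quadrature component(s)\n",
              n, paste(d[seq_len(n)], collapse = " x "), d[n + 1L]))
  cat(sprintf("  sigmaNoise: %s; intensity range [%.4g, %.4g]\n",
              ifelse(is.na(object@sigmaNoise), "unset",
                     sprintf("%.4g", object@sigmaNoise)),
              min(intensity(object)), max(intensity(object))))
})

#' Binary peak-maximum label mask
#'
#' A 0/1 array on the spectral grid marking ground-truth peak-maximum
#' positions, including the dual labels assigned when a maximum falls between
#' grid points (fractional offset in the 0.25-0.75 band from each neighbour).
#'
#' @slot data binary array, same shape as the source spectrum.
#' @export
setClass("LabelMask", representation(data = "array"))

setValidity("LabelMask", function(object) {
  if (!all(object@data %in% c(0, 1))) "label values must be 0 or 1" else TRUE
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %s grid, %d positive point(s)\n",
              paste(dim(object@data), collapse = " x "), sum(object@data)))
})

#' Peak probability presentation map
#'
#' Per-point probabilities, on the same grid as the source spectrum, that a
#' grid point is a peak maximum. Values lie in [0, 1]; points outside a
#' region of interest are exactly 0.
#'
#' @slot data probability array.
#' @slot provenance list describing models, ROI threshold and support spectra
#'   used to produce the map.
#' @export
setClass("P3Map", representation(data = "array", provenance = "list"))

setValidity("P3Map", function(object) {
  if (any(object@data < 0 | object@data > 1)) "probabilities must lie in [0, 1]" else TRUE
})

newP3Map <- function(data, provenance = list()) {
  new("P3Map", data = data, provenance = provenance)
}

setMethod("show", "P3Map", function(object) {
  cat(sprintf("P3Map: %s grid, max probability %.3f, %d point(s) > 0.5\n",
              paste(dim(object@data), collapse = " x "),
              max(object@data), sum(object@data > 0.5)))
})

#' Non-uniform sampling schedule
#'
#' Set of retained indirect-dimension time increments. Indices are 0-based
#' tuples over the indirect grid; the first increment (t = 0 in every
#' indirect dimension) is always kept.
#'
#' @slot indices integer matrix, one 0-based tuple per row.
#' @slot fraction sampled fraction of the full indirect grid.
#' @slot kind "uniform_random" or "poisson_gap".
#' @slot gridPoints indirect-dimension sizes the schedule refers to.
#' @export
setClass("SamplingSchedule", representation(
  indices = "matrix", fraction = "numeric", kind = "character",
  gridPoints = "integer"
))

setValidity("SamplingSchedule", function(object) {
  msg <- NULL
  idx <- object@indices
  if (ncol(idx) != length(object@gridPoints)) msg <- c(msg, "index arity != #indirect dims")
  if (any(idx < 0) || any(sweep(idx, 2, object@gridPoints, `>=`)))
    msg <- c(msg, "indices out of grid")
  if (anyDuplicated(idx)) msg <- c(msg, "duplicate increments")
  if (!any(rowSums(idx != 0) == 0)) msg <- c(msg, "the t = 0 increment must be kept")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SamplingSchedule", function(object) {
  cat(sprintf("SamplingSchedule: %s, %d/%d increments (%.1f%%)\n", object@kind,
              nrow(object@indices), prod(object@gridPoints), 100 * object@fraction))
})

#' Trained or initialized MR-Ai network
#'
#' Gated convolutional network mapping per-dimension 64-point cross sections
#' of a spectrum to the probability that the central point is a peak maximum.
#'
#' @slot nDims input dimensionality (2 or 3).
#' @slot par named list of weight matrices/vectors.
#' @slot config training configuration actually used (list).
#' @slot history training/validation loss curves (list of numeric vectors).
#' @slot negKeepFraction fraction of majority-class (background) points kept
#'   when the training set was resampled; used to restore calibrated
#'   full-grid probabilities at prediction time (1 = no resampling).
#' @export
setClass("MRAiModel", representation(
  nDims = "integer", par = "list", config = "list", history = "list",
  negKeepFraction = "numeric"
))

setMethod("show", "MRAiModel", function(object) {
  np <- sum(vapply(object@par, length, 1L))
  cat(sprintf("MRAiModel: %dD cross-objective, %d trainable parameters%s\n",
              object@nDims, np,
              if (length(object@history)) sprintf(", trained %d epoch(s)",
                length(object@history$train)) else " (untrained)"))
})
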