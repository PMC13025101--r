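# The three noise families used for training and testing: time-domain
# Gaussian noise processed like a spectrum, a NUS-fraction-dependent
# Cauchy-Gaussian mixture emulating CS-IST reconstruction residuals, and a
# bimodal double Gaussian emulating the noise of 2D skyline projections.

#' Noise specification
#'
#' @param kind "gaussian", "cauchy_gauss_mix" or "bimodal".
#' @param nusFraction sampled fraction in (0, 1]; sets the Cauchy/Gaussian
#'   mixture weights ("cauchy_gauss_mix" only).
#' @param bimodalSeparation separation between the two Gaussian means, in
#'   units of the component SD, in [0, 5] ("bimodal" only). A separation of 0
#'   reproduces plain Gaussian noise (the conventional 2D case).
#' @param targetSigma robust sigma the frequency-domain noise is normalized
#'   to; the convention throughout the package is targetSigma = 1 = the
#'   weakest allowed peak amplitude.
#' @return list of class "noiseSpec".
#' @export
noiseSpec <- function(kind = c("gaussian", "cauchy_gauss_mix", "bimodal"),
                      nusFraction = 1, bimodalSeparation = 0, targetSigma = 1) {
  kind <- match.arg(kind)
  if (targetSigma <= 0) stop("targetSigma must be positive")
  if (kind == "cauchy_gauss_mix" && (nusFraction <= 0 || nusFraction > 1))
    stop("nusFraction must lie in (0, 1]")
  if (kind == "bimodal" && (bimodalSeparation < 0 || bimodalSeparation > 5))
    stop("bimodalSeparation must lie in [0, 5]")
  structure(list(kind = kind, nusFraction = nusFraction,
                 bimodalSeparation = bimodalSeparation,
                 targetSigma = targetSigma), class = "noiseSpec")
}

#' Cauchy/Gaussian mixture weights as a function of the NUS fraction
#'
#' The mixture interpolates linearly between purely Gaussian noise for fully
#' sampled data (fraction 1) and purely Cauchy noise for sampling levels at
#' or below 5 percent, the border of the training domain.
#'
#' @param nusFraction sampled fraction in (0, 1].
#' @return named numeric vector \code{c(cauchy =, gaussian =)} summing to 1.
#' @examples
#' mixtureWeights(1)      # c(0, 1)
#' mixtureWeights(0.04)   # c(1, 0)
#' @export
mixtureWeights <- function(nusFraction) {
  if (nusFraction <= 0 || nusFraction > 1) stop("nusFraction must lie in (0, 1]")
  wc <- if (nusFraction <= 0.05) 1 else (1 - nusFraction) / (1 - 0.05)
  c(cauchy = wc, gaussian = 1 - wc)
}

#' Bimodal (double Gaussian) noise sample
#'
#' Symmetric equal-weight mixture of two Gaussians with means
#' \code{+/- separation * sigma / 2} and common SD \code{sigma}.
#'
#' @param separation normalized separation of the means, in [0, 5] SD units.
#' @param sigma component SD.
#' @param n sample size.
#' @param seed optional seed.
#' @return numeric vector of length n.
#' @export
bimodalNoise <- function(separation, sigma = 1, n, seed = NULL) {
  if (separation < 0) stop("separation must be nonnegative")
  draw <- function() {
    s <- sample(c(-1, 1), n, replace = TRUE)
    stats::rnorm(n, mean = s * separation * sigma / 2, sd = sigma)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Generate spectrum-shaped noise
#'
#' Gaussian noise is drawn in the time domain on all quadrature components
#' and processed to the frequency domain with the same chain as the signal;
#' Cauchy and bimodal components are drawn directly in the frequency domain
#' (where CS-IST residuals and projection noise live). The result is
#' normalized so the robust sigma (1.4826 MAD) of the absorption component
#' equals \code{spec$targetSigma}; the Cauchy scale is matched to the
#' Gaussian component's interquartile range before mixing so the robust scale
#' stays stable across the mixture schedule.
#'
#' @param spec a [noiseSpec()].
#' @param grid an [AcqGrid-class]; the output matches the processed spectrum
#'   shape, all 2^n components.
#' @param seed optional seed.
#' @return numeric array with dim \code{c(specSize(grid), 2^n)}.
#' @export
makeNoise <- function(spec, grid, seed = NULL) {
  stopifnot(inherits(spec, "noiseSpec"))
  draw <- function() {
    n <- grid@nDims
    nc <- 2L^n
    N <- specSize(grid)
    m <- prod(N) * nc
    gaussFreq <- function() {
      tn <- array(stats::rnorm(prod(grid@points) * nc), dim = c(grid@points, nc))
      processSpectrum(tn, grid)@components
    }
    out <- switch(spec$kind,
      gaussian = gaussFreq(),
      cauchy_gauss_mix = {
        w <- mixtureWeights(spec$nusFraction)
        g <- gaussFreq()
        # Cauchy scale matched to the Gaussian IQR: IQR(N(0,s)) = 1.349 s,
        # IQR(Cauchy(g)) = 2 g  =>  g = 0.6745 s.
        s <- stats::IQR(g) / 1.349
        cy <- array(stats::rcauchy(m, scale = 0.6745 * s), dim = dim(g))
        w["cauchy"] * cy + w["gaussian"] * g
      },
      bimodal = array(bimodalNoise(spec$bimodalSeparation, 1, m), dim = c(N, nc))
    )
    sc <- robustSigma(array(out, dim = c(prod(N), nc))[, 1L])
    out * (spec$targetSigma / sc)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}
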