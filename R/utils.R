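# Small numeric helpers shared across modules.

#' Robust noise sigma (1.4826 x median absolute deviation)
#'
#' Used everywhere a noise scale is needed: Cauchy-tailed noise makes the
#' sample SD unstable, while the MAD-based estimate stays finite.
#'
#' @param x numeric array or vector.
#' @return scalar robust sigma estimate.
#' @export
robustSigma <- function(x) 1.4826 * stats::median(abs(x - stats::median(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

# fftshift along one dimension: 0-based index j <-> frequency (j - N/2)/N.
shiftIndex <- function(N) c((N / 2 + 1):N, 1:(N / 2))

# Map a frequency in cycles/dwell to the 0-based fractional index on an
# N-point axis under the package convention (index 0 = -Nyquist).
freqToIndex <- function(omega, N) N * (omega + 0.5)

indexToFreq <- function(j, N) j / N - 0.5

# Apodization window over T acquired points.
apodWindow <- function(T, kind = "cos2") {
  t <- 0:(T - 1)
  switch(kind,
    cos2 = cos(pi * t / (2 * T))^2,
    none = rep(1, T),
    stop("unknown apodization window: ", kind)
  )
}

# Derive a bounded sub-seed from a master seed and a stage name, so that every
# stage draws from its own stream and adding stages does not perturb others.
deriveSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Linear index into an array with 1-based subscript matrix (rows = points).
subToLinear <- function(sub, dims) {
  lin <- sub[, 1L]
  mult <- 1
  for (k in seq_along(dims)[-1L]) {
    mult <- mult * dims[k - 1L]
    lin <- lin + (sub[, k] - 1L) * mult
  }
  lin
}

linearToSub <- function(lin, dims) {
  n <- length(dims)
  sub <- matrix(0L, length(lin), n)
  rem <- lin - 1L
  for (k in seq_len(n)) {
    sub[, k] <- as.integer(rem %% dims[k]) + 1L
    rem <- rem %/% dims[k]
  }
  sub
}
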