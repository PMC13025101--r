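# Theoretical localization limits for 2D peaks: Fisher information and
# Cramer-Rao lower bounds for sums of damped complex exponentials observed in
# all four quadrature channels, two-peak resolvability classification, and
# Bayesian posterior uncertainties from an adaptive Metropolis sampler under
# weak or strong phase priors.
#
# The parameter vector theta concatenates, per peak:
#   (A, tau_x, tau_y, omega_x, omega_y, phi_x, phi_y)
# with frequencies in cycles/dwell and phases in radians. The four quadrature
# channels c = (qx, qy) in {cos,sin}^2 are ordered RR, RI, IR, II.

thetaFromParams <- function(params) {
  J <- nPeaks(params)
  th <- numeric(0)
  for (j in seq_len(J))
    th <- c(th, params@amplitude[j] * params@sign[j],
            params@relaxation[j, 1L], params@relaxation[j, 2L],
            params@frequency[j, 1L], params@frequency[j, 2L],
            params@phase[j, 1L] * pi / 180, params@phase[j, 2L] * pi / 180)
  th
}

#' Four-channel time-domain model of 2D damped exponentials
#'
#' Evaluates \eqn{\mu_c(t_x, t_y; \theta)} for the four quadrature channels
#' (cos cos, cos sin, sin cos, sin sin) on the acquisition grid.
#'
#' @param theta parameter vector (7 entries per peak; see above).
#' @param grid a 2D [AcqGrid-class].
#' @return array with dim \code{c(Tx, Ty, 4)}; channels ordered RR, RI, IR,
#'   II.
#' @export
modelQuadrature <- function(theta, grid) {
  stopifnot(grid@nDims == 2L, length(theta) %% 7 == 0)
  Tx <- grid@points[1L]; Ty <- grid@points[2L]
  tx <- 0:(Tx - 1); ty <- 0:(Ty - 1)
  out <- array(0, dim = c(Tx, Ty, 4L))
  for (j in seq_len(length(theta) / 7)) {
    p <- theta[(j - 1) * 7 + 1:7]
    ex <- exp(-tx / p[2L]); ey <- exp(-ty / p[3L])
    ax <- 2 * pi * p[4L] * tx + p[6L]; ay <- 2 * pi * p[5L] * ty + p[7L]
    cx <- ex * cos(ax); sx <- ex * sin(ax)
    cy <- ey * cos(ay); sy <- ey * sin(ay)
    out[, , 1L] <- out[, , 1L] + p[1L] * outer(cx, cy)
    out[, , 2L] <- out[, , 2L] + p[1L] * outer(cx, sy)
    out[, , 3L] <- out[, , 3L] + p[1L] * outer(sx, cy)
    out[, , 4L] <- out[, , 4L] + p[1L] * outer(sx, sy)
  }
  out
}

# Analytic derivatives of the four-channel model w.r.t. every theta entry.
# Returns a (Tx*Ty*4) x length(theta) matrix.
modelDerivatives <- function(theta, grid) {
  Tx <- grid@points[1L]; Ty <- grid@points[2L]
  tx <- 0:(Tx - 1); ty <- 0:(Ty - 1)
  J <- length(theta) / 7
  D <- matrix(0, Tx * Ty * 4L, length(theta))
  for (j in seq_len(J)) {
    p <- theta[(j - 1) * 7 + 1:7]
    ex <- exp(-tx / p[2L]); ey <- exp(-ty / p[3L])
    ax <- 2 * pi * p[4L] * tx + p[6L]; ay <- 2 * pi * p[5L] * ty + p[7L]
    cx <- ex * cos(ax); sx <- ex * sin(ax)
    cy <- ey * cos(ay); sy <- ey * sin(ay)
    # d/dtau: envelope factor t/tau^2; d/domega: 2 pi t swaps cos<->sin;
    # d/dphi swaps cos<->sin.
    dcx_tau <- cx * tx / p[2L]^2; dsx_tau <- sx * tx / p[2L]^2
    dcy_tau <- cy * ty / p[3L]^2; dsy_tau <- sy * ty / p[3L]^2
    dcx_om <- -2 * pi * tx * sx; dsx_om <- 2 * pi * tx * cx
    dcy_om <- -2 * pi * ty * sy; dsy_om <- 2 * pi * ty * cy
    dcx_ph <- -sx; dsx_ph <- cx
    dcy_ph <- -sy; dsy_ph <- cy
    stack <- function(xc, xs, yc, ys, amp)
      c(amp * outer(xc, yc), amp * outer(xc, ys),
        amp * outer(xs, yc), amp * outer(xs, ys))
    cols <- (j - 1) * 7
    D[, cols + 1L] <- stack(cx, sx, cy, sy, 1)
    D[, cols + 2L] <- stack(dcx_tau, dsx_tau, cy, sy, p[1L])
    D[, cols + 3L] <- stack(cx, sx, dcy_tau, dsy_tau, p[1L])
    D[, cols + 4L] <- stack(dcx_om, dsx_om, cy, sy, p[1L])
    D[, cols + 5L] <- stack(cx, sx, dcy_om, dsy_om, p[1L])
    D[, cols + 6L] <- stack(dcx_ph, dsx_ph, cy, sy, p[1L])
    D[, cols + 7L] <- stack(cx, sx, dcy_ph, dsy_ph, p[1L])
  }
  D
}

#' Fisher information matrix for 2D peak parameters
#'
#' \eqn{F_{pq} = \sigma^{-2} \sum_{t_x,t_y,c}
#' \partial_p \mu_c \, \partial_q \mu_c} from the analytic derivatives of
#' the four-channel model, summed over all sampled time points.
#'
#' @param theta parameter vector (7 per peak).
#' @param sigma time-domain noise SD per channel point (> 0).
#' @param grid a 2D [AcqGrid-class].
#' @return list with `fisher` (symmetric PSD matrix), `theta`, `sigma`.
#' @export
fisherMatrix <- function(theta, sigma, grid) {
  stopifnot(sigma > 0)
  D <- modelDerivatives(theta, grid)
  F <- crossprod(D) / sigma^2
  list(fisher = (F + t(F)) / 2, theta = theta, sigma = sigma, grid = grid)
}

#' Cramer-Rao lower bounds
#'
#' Square roots of the diagonal of the inverse Fisher matrix; frequency
#' entries additionally converted to pixel units via the post-zero-fill grid
#' sizes (pixel spacing = 1/N cycles/dwell).
#'
#' @param theta parameter vector (7 per peak).
#' @param sigma time-domain noise SD per channel point.
#' @param grid a 2D [AcqGrid-class].
#' @return list with `crlbTheta` (per-parameter sigma bounds), `freqPixels`
#'   (J x 2 matrix of frequency bounds in pixels), and `flagged` (TRUE when
#'   the Fisher matrix is singular or near-singular; bounds are Inf then).
#' @export
crlb <- function(theta, sigma, grid) {
  fr <- fisherMatrix(theta, sigma, grid)
  J <- length(theta) / 7
  N <- specSize(grid)
  flagged <- FALSE
  inv <- tryCatch(solve(fr$fisher), error = function(e) NULL)
  if (is.null(inv) || kappa(fr$fisher, exact = FALSE) > 1e12 ||
      any(diag(inv) < 0)) {
    flagged <- TRUE
    bounds <- rep(Inf, length(theta))
  } else bounds <- sqrt(diag(inv))
  fp <- matrix(Inf, J, 2L)
  if (!flagged)
    for (j in seq_len(J)) {
      fp[j, 1L] <- bounds[(j - 1) * 7 + 4L] * N[1L]
      fp[j, 2L] <- bounds[(j - 1) * 7 + 5L] * N[2L]
    }
  list(crlbTheta = bounds, freqPixels = fp, flagged = flagged)
}

#' Two-peak theoretical resolvability
#'
#' A two-peak configuration is theoretically resolvable when the Euclidean
#' interpeak separation (in pixels) strictly exceeds 3 times the reference
#' (first) peak's combined frequency CRLB, computed from the full two-peak
#' Fisher matrix.
#'
#' @param theta 14-entry two-peak parameter vector.
#' @param sigma time-domain noise SD.
#' @param grid a 2D [AcqGrid-class].
#' @return list with `resolvable`, `separationPixels`, `sigmaCrlb` and
#'   `margin` (separation - 3 sigma).
#' @export
resolvable <- function(theta, sigma, grid) {
  stopifnot(length(theta) == 14L)
  N <- specSize(grid)
  sep <- sqrt(sum((((theta[4:5] - theta[11:12]) * N))^2))
  cb <- crlb(theta, sigma, grid)
  sCrlb <- sqrt(sum(cb$freqPixels[1L, ]^2))
  list(resolvable = is.finite(sCrlb) && sep > 3 * sCrlb,
       separationPixels = sep, sigmaCrlb = sCrlb, margin = sep - 3 * sCrlb)
}

#' Monte Carlo priors for the Bayesian localization model
#'
#' Half-normal priors for amplitude, relaxation times and the noise SD
#' (scales default to 3x the ground truth); normal frequency priors centred
#' at the ground truth with SD = 3x the digital resolution (1/N cycles per
#' dwell on the zero-filled grid); normal phase priors centred at 0 with SD
#' 30 degrees (weak, MCW) or 4 degrees (strong, MCS).
#'
#' @param truth single-peak [SignalParams-class] (sigma-unit amplitude not
#'   required; pass the time-domain theta instead via `theta`).
#' @param theta 7-entry ground-truth parameter vector.
#' @param grid a 2D [AcqGrid-class].
#' @param phaseSigmaDeg phase prior SD in degrees (30 = MCW, 4 = MCS).
#' @param sigmaTrue true noise SD (sets the half-normal scale).
#' @param priorScale multiple of the ground truth used for half-normal
#'   scales.
#' @return list of prior hyperparameters.
#' @export
mcPriors <- function(theta, grid, phaseSigmaDeg = 30, sigmaTrue,
                     priorScale = 3) {
  N <- specSize(grid)
  list(ampScale = priorScale * abs(theta[1L]),
       tauScale = priorScale * theta[2:3],
       freqMean = theta[4:5],
       freqSd = 3 / N, # 3x digital resolution, cycles/dwell
       phaseSd = phaseSigmaDeg * pi / 180,
       sigmaScale = priorScale * sigmaTrue)
}

# Log-posterior of (theta, log sigma) given the four-channel data. The
# single-peak sum of squares factorizes over dimensions, so it is computed
# from four matrix-vector products against the data channels instead of
# forming the full model array:
#   ||d - mu||^2 = ||d||^2 - 2 A (cx' Drr cy + cx' Dri sy + sx' Dir cy
#                  + sx' Dii sy) + A^2 (sum ex^2)(sum ey^2).
mcLogPost <- function(x, data, grid, priors, pre) {
  th <- x[1:7]; lsig <- x[8L]
  if (th[1L] <= 0 || th[2L] <= 0 || th[3L] <= 0) return(-Inf)
  if (abs(th[4L]) >= 0.5 || abs(th[5L]) >= 0.5) return(-Inf)
  sig <- exp(lsig)
  ex <- exp(-pre$tx / th[2L]); ey <- exp(-pre$ty / th[3L])
  ax <- 2 * pi * th[4L] * pre$tx + th[6L]
  ay <- 2 * pi * th[5L] * pre$ty + th[7L]
  cx <- ex * cos(ax); sx <- ex * sin(ax)
  cy <- ey * cos(ay); sy <- ey * sin(ay)
  cross <- sum(crossprod(cx, pre$Drr) * cy) + sum(crossprod(cx, pre$Dri) * sy) +
    sum(crossprod(sx, pre$Dir) * cy) + sum(crossprod(sx, pre$Dii) * sy)
  ss <- pre$dd - 2 * th[1L] * cross + th[1L]^2 * sum(ex^2) * sum(ey^2)
  M <- pre$M
  ll <- -M * lsig - ss / (2 * sig^2)
  lp <- -th[1L]^2 / (2 * priors$ampScale^2) -
    th[2L]^2 / (2 * priors$tauScale[1L]^2) -
    th[3L]^2 / (2 * priors$tauScale[2L]^2) -
    sum((th[4:5] - priors$freqMean)^2 / (2 * priors$freqSd^2)) -
    sum(th[6:7]^2) / (2 * priors$phaseSd^2) -
    sig^2 / (2 * priors$sigmaScale^2) + lsig # half-normal on sigma + Jacobian
  ll + lp
}

splitRhat <- function(chains) {
  # chains: list of numeric vectors (equal length)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, 1.0)
  vars <- vapply(halves, stats::var, 1.0)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian posterior localization uncertainty
#'
#' Samples the posterior of the single-peak four-channel model with an
#' adaptive random-walk Metropolis sampler (joint Gaussian proposal whose
#' covariance is adapted during burn-in), the gradient-free fallback
#' prescribed when no NUTS implementation is available. Reports the
#' posterior SDs of the two frequencies in pixel units and split-Rhat
#' convergence diagnostics; results are flagged when Rhat > 1.05.
#'
#' @param data four-channel time-domain array (signal + noise), as from
#'   [modelQuadrature()] plus noise.
#' @param theta ground-truth 7-entry parameter vector (sampler
#'   initialization and prior centring).
#' @param grid a 2D [AcqGrid-class].
#' @param sigmaTrue true noise SD.
#' @param phaseSigmaDeg 30 (MCW) or 4 (MCS).
#' @param nBurn,nDraws burn-in and retained draws per chain.
#' @param nChains number of chains.
#' @param seed seed.
#' @return list with `freqSdPixels` (posterior SDs, pixels), `rhat`,
#'   `accept`, `flagged`.
#' @export
mcPosterior <- function(data, theta, grid, sigmaTrue, phaseSigmaDeg = 30,
                        nBurn = 4000, nDraws = 8000, nChains = 2, seed = 1) {
  priors <- mcPriors(theta, grid, phaseSigmaDeg, sigmaTrue)
  N <- specSize(grid)
  pre <- list(tx = 0:(grid@points[1L] - 1), ty = 0:(grid@points[2L] - 1),
              Drr = data[, , 1L], Dri = data[, , 2L],
              Dir = data[, , 3L], Dii = data[, , 4L],
              dd = sum(data^2), M = length(data))
  x0 <- c(theta, log(sigmaTrue))
  scale0 <- abs(c(0.03 * theta[1L] + 1e-3, 0.05 * theta[2:3],
                  rep(0.3 / N, length.out = 2),
                  rep(min(0.5 * phaseSigmaDeg * pi / 180, 0.02), 2), 0.02))
  chains <- vector("list", nChains)
  accepts <- numeric(nChains)
  for (ch in seq_len(nChains)) {
    set.seed(deriveSeed(seed, paste0("mc-chain-", ch)))
    x <- x0 * exp(stats::rnorm(8, 0, 0.001))
    lp <- mcLogPost(x, data, grid, priors, pre)
    d <- length(x)
    cf <- chol(diag(scale0^2))
    draws <- matrix(0, nDraws, d)
    histX <- matrix(0, nBurn, d)
    nAcc <- 0; nAccWin <- 0; sc <- 1
    for (it in seq_len(nBurn + nDraws)) {
      prop <- x + sc * drop(stats::rnorm(d) %*% cf)
      lpP <- mcLogPost(prop, data, grid, priors, pre)
      if (log(stats::runif(1)) < lpP - lp) {
        x <- prop; lp <- lpP; nAcc <- nAcc + 1; nAccWin <- nAccWin + 1
      }
      if (it <= nBurn) {
        histX[it, ] <- x
        if (it %% 200 == 0) {
          if (it >= 600) { # recondition on the latter half of the history
            use <- histX[(it %/% 2):it, , drop = FALSE]
            emp <- 2.38^2 / d * (stats::cov(use) + diag(1e-14, d))
            cf <- tryCatch(chol(emp), error = function(e) cf)
          }
          sc <- sc * exp((nAccWin / 200 - 0.234))
          nAccWin <- 0
        }
      } else draws[it - nBurn, ] <- x
    }
    chains[[ch]] <- draws
    accepts[ch] <- nAcc / (nBurn + nDraws)
  }
  all <- do.call(rbind, chains)
  freqSd <- c(stats::sd(all[, 4L]) * N[1L], stats::sd(all[, 5L]) * N[2L])
  rh <- c(splitRhat(lapply(chains, function(m) m[, 4L])),
          splitRhat(lapply(chains, function(m) m[, 5L])))
  list(freqSdPixels = freqSd, rhat = rh, accept = accepts,
       flagged = any(rh > 1.05))
}
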