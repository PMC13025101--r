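# The MR-Ai network: per-dimension gated convolutional branches over 64-point
# cross sections (stride-2, kernel-2, 10 gated channels, no padding; five
# layers take 64 -> 2 positions, flattened to 20 features per dimension),
# a gated dense head (hidden sizes 20 and 10) and a single sigmoid output.
# Forward pass, backpropagation and Adam are implemented here directly with
# BLAS-backed matrix operations; no deep-learning framework is used.

.CROSS_LEN <- 64L
.N_CHAN <- 10L
.N_LAYERS <- 5L # forced by 64 -> 32 -> 16 -> 8 -> 4 -> 2 with stride 2, kernel 2

#' Closed-form trainable-parameter count of the MR-Ai architecture
#'
#' Each gated layer holds two parallel weight sets (tanh and sigmoid branch),
#' i.e. 20 convolution filters collapsing into 10 gated channels per
#' convolutional layer. Used as the oracle the built model must match.
#'
#' @param nDims input dimensionality (2 or 3).
#' @return integer parameter count (about 8000 for nDims = 3).
#' @export
mraiParameterCount <- function(nDims) {
  convLayer <- function(cin) 2L * (2L * cin * .N_CHAN + .N_CHAN)
  branch <- convLayer(1L) + (.N_LAYERS - 1L) * convLayer(.N_CHAN)
  feat <- 2L * .N_CHAN * nDims
  head <- 2L * (feat * 20L + 20L) + 2L * (20L * 10L + 10L) + (10L + 1L)
  nDims * branch + head
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an initialized MR-Ai model
#'
#' Gated blocks compute \code{tanh(conv_a(x)) * sigmoid(conv_b(x))} per
#' layer; the dense head is gated the same way and the output unit is a
#' sigmoid. Weights are Glorot-uniform initialized.
#'
#' @param nDims 2 or 3 (one 64-point cross-section branch per dimension).
#' @param seed seed for the weight initialization.
#' @return An [MRAiModel-class].
#' @export
buildModel <- function(nDims, seed = 1L) {
  stopifnot(nDims %in% c(2L, 3L))
  par <- withSeed(seed, {
    p <- list()
    for (b in seq_len(nDims)) {
      cin <- 1L
      for (l in seq_len(.N_LAYERS)) {
        key <- sprintf("b%d.l%d", b, l)
        p[[paste0(key, ".Wt")]] <- glorot(2L * cin, .N_CHAN)
        p[[paste0(key, ".bt")]] <- numeric(.N_CHAN)
        p[[paste0(key, ".Ws")]] <- glorot(2L * cin, .N_CHAN)
        p[[paste0(key, ".bs")]] <- numeric(.N_CHAN)
        cin <- .N_CHAN
      }
    }
    feat <- 2L * .N_CHAN * nDims
    p$h1.Wt <- glorot(feat, 20L); p$h1.bt <- numeric(20L)
    p$h1.Ws <- glorot(feat, 20L); p$h1.bs <- numeric(20L)
    p$h2.Wt <- glorot(20L, 10L); p$h2.bt <- numeric(10L)
    p$h2.Ws <- glorot(20L, 10L); p$h2.bs <- numeric(10L)
    p$out.w <- glorot(10L, 1L); p$out.b <- 0
    p
  })
  new("MRAiModel", nDims = as.integer(nDims), par = par, config = list(),
      history = list(), negKeepFraction = 1)
}

#' @describeIn buildModel actual parameter count of a built model.
#' @param model an [MRAiModel-class].
#' @export
nParameters <- function(model) sum(vapply(model@par, length, 1L))

# Reference (pure-R) forward pass, kept as the independent oracle for the
# compiled kernel. X: list of nDims matrices (N x 64). Returns list(p, z)
# and, if cache = TRUE, the intermediates needed for backprop.
mraiForward <- function(par, X, nDims, cache = FALSE) {
  N <- nrow(X[[1L]])
  caches <- if (cache) vector("list", nDims)
  feats <- vector("list", nDims)
  for (b in seq_len(nDims)) {
    H <- array(X[[b]], dim = c(N, .CROSS_LEN, 1L))
    layerCache <- if (cache) vector("list", .N_LAYERS)
    for (l in seq_len(.N_LAYERS)) {
      d <- dim(H); L <- d[2L]; Cin <- d[3L]; L2 <- L %/% 2L
      M <- cbind(matrix(H[, seq(1L, L, 2L), , drop = FALSE], N * L2, Cin),
                 matrix(H[, seq(2L, L, 2L), , drop = FALSE], N * L2, Cin))
      key <- sprintf("b%d.l%d", b, l)
      A <- tanh(sweep(M %*% par[[paste0(key, ".Wt")]], 2L, par[[paste0(key, ".bt")]], `+`))
      B <- sigmoid(sweep(M %*% par[[paste0(key, ".Ws")]], 2L, par[[paste0(key, ".bs")]], `+`))
      if (cache) layerCache[[l]] <- list(M = M, A = A, B = B, L = L, Cin = Cin)
      H <- array(A * B, dim = c(N, L2, .N_CHAN))
    }
    feats[[b]] <- matrix(H, N, 2L * .N_CHAN)
    if (cache) caches[[b]] <- layerCache
  }
  X0 <- do.call(cbind, feats)
  A1 <- tanh(sweep(X0 %*% par$h1.Wt, 2L, par$h1.bt, `+`))
  B1 <- sigmoid(sweep(X0 %*% par$h1.Ws, 2L, par$h1.bs, `+`))
  H1 <- A1 * B1
  A2 <- tanh(sweep(H1 %*% par$h2.Wt, 2L, par$h2.bt, `+`))
  B2 <- sigmoid(sweep(H1 %*% par$h2.Ws, 2L, par$h2.bs, `+`))
  H2 <- A2 * B2
  z <- drop(H2 %*% par$out.w) + par$out.b
  out <- list(p = sigmoid(z), z = z)
  if (cache)
    out$cache <- list(branches = caches, X0 = X0, A1 = A1, B1 = B1, H1 = H1,
                      A2 = A2, B2 = B2, H2 = H2, N = N)
  out
}

gatedDenseBackward <- function(X, A, B, dH, Wt, Ws) {
  dZt <- dH * B * (1 - A * A)
  dZs <- dH * A * B * (1 - B)
  list(dWt = crossprod(X, dZt), dbt = colSums(dZt),
       dWs = crossprod(X, dZs), dbs = colSums(dZs),
       dX = dZt %*% t(Wt) + dZs %*% t(Ws))
}

# Backprop of the mean-BCE loss; dz = (p - y)/N at the output logit.
mraiBackward <- function(par, fw, y, nDims) {
  cc <- fw$cache
  N <- cc$N
  g <- list()
  dz <- matrix((fw$p - y) / N, ncol = 1L)
  g$out.w <- crossprod(cc$H2, dz)
  g$out.b <- sum(dz)
  dH2 <- dz %*% t(par$out.w)
  bk <- gatedDenseBackward(cc$H1, cc$A2, cc$B2, dH2, par$h2.Wt, par$h2.Ws)
  g$h2.Wt <- bk$dWt; g$h2.bt <- bk$dbt; g$h2.Ws <- bk$dWs; g$h2.bs <- bk$dbs
  bk <- gatedDenseBackward(cc$X0, cc$A1, cc$B1, bk$dX, par$h1.Wt, par$h1.Ws)
  g$h1.Wt <- bk$dWt; g$h1.bt <- bk$dbt; g$h1.Ws <- bk$dWs; g$h1.bs <- bk$dbs
  dX0 <- bk$dX
  for (b in seq_len(nDims)) {
    cols <- (b - 1L) * 2L * .N_CHAN + seq_len(2L * .N_CHAN)
    dH <- array(dX0[, cols, drop = FALSE], dim = c(N, 2L, .N_CHAN))
    for (l in rev(seq_len(.N_LAYERS))) {
      lc <- cc$branches[[b]][[l]]
      key <- sprintf("b%d.l%d", b, l)
      L2 <- lc$L %/% 2L
      dHm <- matrix(dH, N * L2, .N_CHAN)
      bk <- gatedDenseBackward(lc$M, lc$A, lc$B, dHm,
                               par[[paste0(key, ".Wt")]], par[[paste0(key, ".Ws")]])
      g[[paste0(key, ".Wt")]] <- bk$dWt; g[[paste0(key, ".bt")]] <- bk$dbt
      g[[paste0(key, ".Ws")]] <- bk$dWs; g[[paste0(key, ".bs")]] <- bk$dbs
      dM <- bk$dX
      dHprev <- array(0, dim = c(N, lc$L, lc$Cin))
      dHprev[, seq(1L, lc$L, 2L), ] <- array(dM[, seq_len(lc$Cin), drop = FALSE],
                                             dim = c(N, L2, lc$Cin))
      dHprev[, seq(2L, lc$L, 2L), ] <- array(dM[, lc$Cin + seq_len(lc$Cin), drop = FALSE],
                                             dim = c(N, L2, lc$Cin))
      dH <- dHprev
    }
  }
  g
}

bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Undersample background points to balance the classes
#'
#' Keeps every positive (peak-maximum) point and a uniform subsample of the
#' background, targeting the given positive:negative ratio. Negatives are
#' never oversampled: if fewer are available than the ratio demands, all are
#' kept.
#'
#' @param mask a [LabelMask-class].
#' @param ratio target positives/negatives ratio (default 0.01, i.e. 1:100).
#' @param nNegatives optional explicit negative count, overriding `ratio`.
#' @param seed optional seed.
#' @return list with `indices` (1-based subscript matrix), `labels` (0/1),
#'   and `negKeepFraction`, the fraction of available background points kept
#'   (the quantity needed to undo the induced base-rate shift at prediction
#'   time).
#' @export
resampleTrainingPoints <- function(mask, ratio = 0.01, nNegatives = NULL, seed = NULL) {
  m <- mask@data
  pos <- which(m == 1)
  if (length(pos) == 0L) stop("label mask contains no positive points")
  neg <- which(m == 0)
  want <- if (is.null(nNegatives)) round(length(pos) / ratio) else nNegatives
  want <- min(want, length(neg))
  negKeep <- if (is.null(seed)) sample(neg, want) else withSeed(seed, sample(neg, want))
  idx <- c(pos, negKeep)
  list(indices = linearToSub(idx, dim(m)),
       labels = c(rep(1, length(pos)), rep(0, want)),
       negKeepFraction = want / length(neg))
}

#' Extract the cross-objective at a spectral point
#'
#' One 64-point 1D section per spectral dimension through the probed point,
#' which sits at the centre (0-based position 32). Intensities are divided by
#' the spectrum's noise sigma so the network always sees sigma-units;
#' positions outside the grid are zero-filled (the baseline value of
#' noise-free regions after scaling).
#'
#' @param spectrum an [NMRSpectrum-class] with a known or estimable noise
#'   sigma.
#' @param index integer vector, 1-based grid subscript of the probed point.
#' @return list of length nDims of 64-point numeric vectors.
#' @export
extractCross <- function(spectrum, index) {
  X <- extractCrossBatch(spectrum, matrix(as.integer(index), nrow = 1L))
  lapply(X, drop)
}

# Vectorized cross extraction: indices is an (N x nDims) 1-based matrix.
# Returns a list of nDims (N x 64) matrices.
extractCrossBatch <- function(spectrum, indices, sigma = NULL) {
  a <- intensity(spectrum)
  dims <- dim(a)
  n <- length(dims)
  if (is.null(sigma)) sigma <- sigmaNoise(spectrum)
  if (!is.finite(sigma) || sigma <= 0)
    stop("spectrum needs a positive noise sigma for cross extraction")
  N <- nrow(indices)
  off <- -32:31
  strides <- cumprod(c(1L, dims[-n]))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    # linear index of the probed point with dim-k subscript zeroed out
    base <- 1
    for (d in seq_len(n)) if (d != k) base <- base + (indices[, d] - 1) * strides[d]
    X <- matrix(0, N, length(off))
    for (j in seq_along(off)) {
      pos <- indices[, k] + off[j]
      ok <- pos >= 1L & pos <= dims[k]
      lin <- base + (pos - 1) * strides[k]
      v <- numeric(N)
      v[ok] <- a[lin[ok]]
      X[, j] <- v
    }
    out[[k]] <- X / sigma
  }
  out
}

adamInit <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0), t = 0)
}

adamStep <- function(par, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(par)) {
    g <- grad[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    par[[k]] <- par[[k]] - lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  list(par = par, st = st)
}

#' Training configuration
#'
#' Defaults follow the training protocol: Adam with learning rate 0.001,
#' mini-batch size 2^16, at most 2^10 epochs with early stopping on the
#' validation BCE (patience 32 epochs), 4:1 train/validation split, binary
#' cross-entropy loss.
#'
#' @param lr learning rate.
#' @param batchSize mini-batch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param valFraction held-out validation fraction (default 1/5).
#' @param seed shuffling/initialization seed.
#' @return list of class "trainConfig".
#' @export
trainConfig <- function(lr = 1e-3, batchSize = 2L^16L, epochs = 2L^10L,
                        patience = 32L, valFraction = 0.2, seed = 1L) {
  stopifnot(lr > 0, batchSize >= 1, epochs >= 1, valFraction > 0, valFraction < 1)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 valFraction = valFraction, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Train an MR-Ai model
#'
#' Minimizes the mean binary cross-entropy over (cross-objective, label)
#' pairs with Adam. The data are split 4:1 into training and validation
#' parts; training stops after `epochs` epochs or earlier once the
#' validation BCE has not improved for `patience` epochs, and the weights
#' from the best validation epoch are kept.
#'
#' @param model an [MRAiModel-class] from [buildModel()].
#' @param X list of nDims matrices (N x 64) of cross sections.
#' @param y numeric 0/1 labels of length N; both classes must be present.
#' @param config a [trainConfig()].
#' @param negKeepFraction background-undersampling fraction of the training
#'   set (recorded on the model for calibrated full-grid prediction).
#' @param verbose print per-epoch losses.
#' @return the trained [MRAiModel-class] with `history` filled in.
#' @export
trainModel <- function(model, X, y, config = trainConfig(), negKeepFraction = 1,
                       verbose = FALSE) {
  N <- length(y)
  stopifnot(nrow(X[[1L]]) == N)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  n <- model@nDims
  par <- model@par
  set.seed(config$seed)
  ord <- sample.int(N)
  nVal <- max(1L, round(config$valFraction * N))
  valIdx <- ord[seq_len(nVal)]
  trIdx <- ord[-seq_len(nVal)]
  Xtr <- lapply(X, function(m) m[trIdx, , drop = FALSE])
  Xval <- lapply(X, function(m) m[valIdx, , drop = FALSE])
  ytr <- y[trIdx]; yval <- y[valIdx]
  st <- adamInit(par)
  hist <- list(train = numeric(0), val = numeric(0))
  best <- list(par = par, val = Inf, epoch = 0L)
  nTr <- length(ytr)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(nTr)
    losses <- numeric(0)
    for (start in seq(1L, nTr, by = config$batchSize)) {
      bi <- perm[start:min(start + config$batchSize - 1L, nTr)]
      Xb <- lapply(Xtr, function(m) m[bi, , drop = FALSE])
      fb <- .mraiFwdBwdCpp(par, Xb, ytr[bi], n)
      losses <- c(losses, fb$loss)
      up <- adamStep(par, fb$grads, st, lr = config$lr)
      par <- up$par; st <- up$st
    }
    vl <- bce(.mraiForwardCpp(par, Xval, n), yval)
    hist$train <- c(hist$train, mean(losses))
    hist$val <- c(hist$val, vl)
    if (verbose)
      message(sprintf("epoch %3d  train BCE %.5f  val BCE %.5f", ep, mean(losses), vl))
    if (vl < best$val) best <- list(par = par, val = vl, epoch = ep)
    if (ep - best$epoch >= config$patience) break
  }
  model@par <- best$par
  model@config <- unclass(config)
  model@history <- hist
  model@negKeepFraction <- negKeepFraction
  model
}

#' Predict a probability value for a batch of cross-objectives
#'
#' @param model a trained [MRAiModel-class].
#' @param X list of nDims (N x 64) matrices.
#' @param priorCorrect undo the training-time background undersampling
#'   (multiply the predicted odds by the recorded negative-keep fraction) so
#'   probabilities are calibrated at the full-grid base rate.
#' @param engine "cpp" (compiled kernel) or "R" (reference implementation).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, X, priorCorrect = TRUE, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  p <- if (engine == "cpp") .mraiForwardCpp(model@par, X, model@nDims)
       else mraiForward(model@par, X, model@nDims)$p
  beta <- model@negKeepFraction
  if (priorCorrect && beta < 1)
    p <- (p * beta) / (p * beta + 1 - p)
  p
}

#' Predict the probability map of a spectrum
#'
#' Applies the model to every grid point (or to the points of a region of
#' interest, all others reported as exactly 0) and returns the resulting
#' probability map.
#'
#' @param model a trained [MRAiModel-class] whose dimensionality matches the
#'   spectrum.
#' @param spectrum an [NMRSpectrum-class].
#' @param roiMask optional logical/0-1 array on the spectrum grid.
#' @param batchSize points evaluated per forward pass.
#' @param priorCorrect see [predictProb()].
#' @return A [P3Map-class].
#' @export
predictMap <- function(model, spectrum, roiMask = NULL, batchSize = 2L^14L,
                       priorCorrect = TRUE) {
  n <- spectrumDims(spectrum)
  if (n != model@nDims)
    stop(sprintf("model is %dD but spectrum is %dD", model@nDims, n))
  dims <- dim(intensity(spectrum))
  pts <- if (is.null(roiMask)) seq_len(prod(dims)) else which(roiMask != 0)
  out <- array(0, dim = dims)
  sigma <- sigmaNoise(spectrum)
  for (start in seq(1L, length(pts), by = batchSize)) {
    ii <- pts[start:min(start + batchSize - 1L, length(pts))]
    sub <- linearToSub(ii, dims)
    X <- extractCrossBatch(spectrum, sub, sigma = sigma)
    out[ii] <- predictProb(model, X, priorCorrect = priorCorrect)
  }
  newP3Map(out, provenance = list(model = "MRAiModel", nDims = n,
                                  roi = !is.null(roiMask),
                                  priorCorrect = priorCorrect))
}

#' Save / load an MR-Ai model
#'
#' Weights go to a little-endian float64 binary file, everything needed to
#' rebuild the model (shapes, config, history, resampling fraction) to a JSON
#' sidecar `<path>.json`.
#'
#' @param model an [MRAiModel-class].
#' @param path file stem for the two files.
#' @return `readModel` returns the restored [MRAiModel-class].
#' @export
writeModel <- function(model, path) {
  shapes <- lapply(model@par, function(x) if (is.null(dim(x))) length(x) else dim(x))
  meta <- list(nDims = model@nDims, shapes = shapes, config = model@config,
               history = model@history, negKeepFraction = model@negKeepFraction)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (x in model@par) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  par <- list()
  for (k in names(meta$shapes)) {
    sh <- unlist(meta$shapes[[k]])
    x <- readBin(con, "double", n = prod(sh), size = 8L, endian = "little")
    par[[k]] <- if (length(sh) == 2L) matrix(x, sh[1L], sh[2L]) else x
  }
  new("MRAiModel", nDims = as.integer(meta$nDims), par = par,
      config = as.list(meta$config),
      history = lapply(meta$history, as.numeric),
      negKeepFraction = as.numeric(meta$negKeepFraction))
}
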