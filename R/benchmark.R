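# Benchmark-suite generators, the training-corpus builder, the end-to-end
# pipeline runner and run configuration. All randomness flows from a single
# seed via named sub-streams (deriveSeed), so adding a stage never perturbs
# the draws of earlier stages.

#' Default acceptance-scale 2D acquisition grid
#'
#' 128 x 64 complex points, zero fill 2, cosine-squared apodization: the
#' reduced grid used by the bundled training/evaluation protocol (a quarter
#' of the full production default of 512 x 128).
#'
#' @param full use the full-size production grid instead.
#' @return An [AcqGrid-class].
#' @export
defaultGrid2D <- function(full = FALSE) {
  if (full) acqGrid(c(512L, 128L)) else acqGrid(c(128L, 64L))
}

#' @describeIn defaultGrid2D 3D grid (64^3 complex full scale, 16^3 reduced).
#' @export
defaultGrid3D <- function(full = FALSE) {
  if (full) acqGrid(c(64L, 64L, 64L)) else acqGrid(c(16L, 16L, 16L))
}

#' Single-peak localization experiment
#'
#' Draws one peak with random frequencies (uniform, 0.1 cycles/dwell edge
#' margin), relaxation times (log-uniform [8, 128] dwell) and phases
#' (uniform +/- 5 degrees) at the requested spectral SNR, adds complex
#' Gaussian time-domain noise scaled so the processed spectrum has
#' sigma-noise 1, and returns everything the localization studies need: the
#' processed noisy spectrum, the four-channel noisy FID (quadrature order
#' RR, RI, IR, II), the ground-truth theta vector and the time-domain noise
#' SD.
#'
#' @param snr spectral signal-to-noise of the peak.
#' @param grid a 2D [AcqGrid-class].
#' @param seed seed.
#' @param phaseRange phase band in degrees.
#' @return list with `spectrum`, `fidQuad`, `theta`, `sigmaT`, `params`,
#'   `truthIndex` (0-based fractional peak position on the spectral grid).
#' @export
singlePeakExperiment <- function(snr, grid = defaultGrid2D(), seed = 1,
                                 phaseRange = c(-5, 5)) {
  ranges <- spectrumParamRanges(ampRange = c(snr, snr), phaseRange = phaseRange,
                                freqMargin = 0.1)
  params <- sampleSpectrumParams(ranges, nPeaks = 1L, nDims = 2L,
                                 seed = deriveSeed(seed, "single-peak-params"))
  sigmaT <- 1 / noiseSigmaFactor(grid)
  aTime <- snr / peakHeightFactor(grid, params@relaxation)
  pTime <- params
  pTime@amplitude <- aTime
  fid <- simulateFid(pTime, grid)
  noise <- withSeed(deriveSeed(seed, "single-peak-noise"),
                    array(stats::rnorm(length(fid), sd = sigmaT), dim = dim(fid)))
  fidN <- fid + noise
  spectrum <- processSpectrum(fidN, grid, sigmaNoise = 1)
  theta <- c(aTime, params@relaxation[1L, ], params@frequency[1L, ],
             params@phase[1L, ] * pi / 180)
  # simulateFid component order (cc, sc, cs, ss) -> quadrature (RR, RI, IR, II)
  fidQuad <- fidN[, , c(1L, 3L, 2L, 4L)]
  list(spectrum = spectrum, fidQuad = fidQuad, theta = theta, sigmaT = sigmaT,
       params = params,
       truthIndex = freqToIndex(params@frequency[1L, ], specSize(grid)))
}

#' Two-peak resolution experiment
#'
#' A reference peak at the requested SNR plus a second peak of twice the
#' intensity at the given pixel separations in the direct and indirect
#' dimensions; noise as in [singlePeakExperiment()].
#'
#' @param snr reference-peak spectral SNR (the interfering peak has 2x).
#' @param sepPixels length-2 separation (direct, indirect) in pixels of the
#'   zero-filled grid.
#' @param grid a 2D [AcqGrid-class].
#' @param seed seed.
#' @param phaseRange phase band in degrees.
#' @return list like [singlePeakExperiment()] plus `theta` of length 14
#'   (reference peak first) and `truthIndex` as a 2 x 2 matrix (row per
#'   peak).
#' @export
pairPeakExperiment <- function(snr, sepPixels, grid = defaultGrid2D(), seed = 1,
                               phaseRange = c(-5, 5)) {
  N <- specSize(grid)
  ranges <- spectrumParamRanges(ampRange = c(snr, snr), phaseRange = phaseRange,
                                freqMargin = 0.15)
  p1 <- sampleSpectrumParams(ranges, nPeaks = 1L, nDims = 2L,
                             seed = deriveSeed(seed, "pair-params"))
  p2 <- sampleSpectrumParams(ranges, nPeaks = 1L, nDims = 2L,
                             seed = deriveSeed(seed, "pair-params-2"))
  freq2 <- p1@frequency[1L, ] + sepPixels / N
  if (any(abs(freq2) >= 0.45)) freq2 <- p1@frequency[1L, ] - sepPixels / N
  params <- signalParams(c(snr, 2 * snr),
                         rbind(p1@frequency[1L, ], freq2),
                         rbind(p1@relaxation[1L, ], p2@relaxation[1L, ]),
                         rbind(p1@phase[1L, ], p2@phase[1L, ]))
  sigmaT <- 1 / noiseSigmaFactor(grid)
  pTime <- params
  pTime@amplitude <- params@amplitude / peakHeightFactor(grid, params@relaxation)
  fid <- simulateFid(pTime, grid)
  noise <- withSeed(deriveSeed(seed, "pair-noise"),
                    array(stats::rnorm(length(fid), sd = sigmaT), dim = dim(fid)))
  fidN <- fid + noise
  spectrum <- processSpectrum(fidN, grid, sigmaNoise = 1)
  theta <- c(pTime@amplitude[1L], params@relaxation[1L, ], params@frequency[1L, ],
             params@phase[1L, ] * pi / 180,
             pTime@amplitude[2L], params@relaxation[2L, ], params@frequency[2L, ],
             params@phase[2L, ] * pi / 180)
  list(spectrum = spectrum, fidQuad = fidN[, , c(1L, 3L, 2L, 4L)],
       theta = theta, sigmaT = sigmaT, params = params,
       truthIndex = rbind(freqToIndex(params@frequency[1L, ], N),
                          freqToIndex(params@frequency[2L, ], N)))
}

#' Build a resampled training corpus of cross-objectives
#'
#' Generates `nSpectra` synthetic noisy spectra (256 peaks each by default,
#' amplitudes log-uniform over 1:200 sigma), extracts the cross-objectives of
#' every positive (peak-maximum) point and of a uniform background subsample
#' sized to reach `targetPoints` in total, and returns the pooled design.
#'
#' @param nSpectra number of spectra.
#' @param grid an [AcqGrid-class].
#' @param nPeaks peaks per spectrum.
#' @param noise a [noiseSpec()] (Gaussian, sigma 1, by default).
#' @param targetPoints approximate total number of cross-objectives.
#' @param ranges parameter ranges ([spectrumParamRanges()]).
#' @param signGroups for 3D training: combine groups of this many spectra
#'   with alternating +,+,-,- signs (0 = off).
#' @param seed master seed.
#' @return list with `X` (list of nDims (N x 64) matrices), `y` (0/1),
#'   `negKeepFraction`, and `heldOut` function generating further spectra
#'   from the same distribution.
#' @export
makeTrainingData <- function(nSpectra, grid = defaultGrid2D(), nPeaks = 256L,
                             noise = noiseSpec("gaussian"),
                             targetPoints = 2e5, ranges = spectrumParamRanges(),
                             signGroups = 0L, seed = 1) {
  n <- grid@nDims
  perSpec <- vector("list", nSpectra)
  nPosTot <- 0
  specs <- vector("list", nSpectra)
  for (i in seq_len(nSpectra)) {
    specs[[i]] <- makeBenchmarkSpectrum(grid, nPeaks, noise, ranges, signGroups,
                                        seed = deriveSeed(seed, paste0("train-spec-", i)))
    nPosTot <- nPosTot + sum(specs[[i]]$labels@data)
  }
  gridSize <- prod(specSize(grid))
  negPerSpec <- max(1L, round((targetPoints - nPosTot) / nSpectra))
  Xs <- NULL; ys <- NULL
  for (i in seq_len(nSpectra)) {
    rs <- resampleTrainingPoints(specs[[i]]$labels, nNegatives = negPerSpec,
                                 seed = deriveSeed(seed, paste0("resample-", i)))
    Xi <- extractCrossBatch(specs[[i]]$spectrum, rs$indices, sigma = 1)
    if (is.null(Xs)) Xs <- Xi
    else for (k in seq_len(n)) Xs[[k]] <- rbind(Xs[[k]], Xi[[k]])
    ys <- c(ys, rs$labels)
  }
  negKeep <- negPerSpec / (gridSize - nPosTot / nSpectra)
  list(X = Xs, y = ys, negKeepFraction = negKeep, nPositives = nPosTot)
}

# One synthetic benchmark spectrum (with optional sign-group summation for
# the 3D construction: groups of `signGroups` spectra added with signs
# +,+,-,-). Returns list(spectrum, labels, params).
makeBenchmarkSpectrum <- function(grid, nPeaks, noise, ranges = spectrumParamRanges(),
                                  signGroups = 0L, seed = 1) {
  n <- grid@nDims
  if (signGroups > 1L) {
    signs <- rep_len(c(1, 1, -1, -1), signGroups)
    parts <- lapply(seq_len(signGroups), function(g)
      sampleSpectrumParams(ranges, nPeaks, n, seed = deriveSeed(seed, paste0("part-", g))))
    amp <- unlist(lapply(parts, slot, "amplitude"))
    params <- signalParams(
      amp,
      do.call(rbind, lapply(parts, slot, "frequency")),
      do.call(rbind, lapply(parts, slot, "relaxation")),
      do.call(rbind, lapply(parts, slot, "phase")),
      rep(signs, each = nPeaks))
  } else {
    params <- sampleSpectrumParams(ranges, nPeaks, n,
                                   seed = deriveSeed(seed, "params"))
  }
  synthesizeSpectrum(params, grid, noise, seed = deriveSeed(seed, "noise"))
}

#' Generate a benchmark dataset on disk
#'
#' Reproducible synthetic suites mirroring the validation studies:
#' \describe{
#'   \item{fig4}{20 spectra x 256 peaks for detection-score statistics.}
#'   \item{fig7_single}{single-peak spectra at SNR 5/10/15/20 for the
#'     localization study (1000 per SNR at scale 1).}
#'   \item{fig8_pair}{two-peak spectra over a separation grid at SNR 10.}
#'   \item{fig9_ta}{a 3D FID + truth for targeted-acquisition build-up.}
#' }
#' `scale` multiplies the per-condition replicate counts (use < 1 for desk
#' scale). Spectra go to the portable container format, truth tables to TSV.
#'
#' @param kind one of "fig4", "fig7_single", "fig8_pair", "fig9_ta".
#' @param dir output directory (created).
#' @param scale replicate multiplier.
#' @param seed master seed.
#' @param grid acquisition grid (defaults to the acceptance-scale 2D/3D
#'   grid).
#' @return invisibly, the manifest data.frame written to `dir/manifest.tsv`.
#' @export
generateBenchmarkSuite <- function(kind = c("fig4", "fig7_single", "fig8_pair",
                                            "fig9_ta"),
                                   dir, scale = 1, seed = 1, grid = NULL) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  if (kind == "fig4") {
    if (is.null(grid)) grid <- defaultGrid2D()
    nSpec <- max(1L, round(20 * scale))
    for (i in seq_len(nSpec)) {
      sy <- makeBenchmarkSpectrum(grid, 256L, noiseSpec("gaussian"),
                                  seed = deriveSeed(seed, paste0("fig4-", i)))
      stem <- file.path(dir, sprintf("fig4_%03d", i))
      exportSpectrum(sy$spectrum, stem)
      writeParamsTable(sy$params, paste0(stem, "_truth.tsv"))
      addRow(file = basename(stem), nPeaks = nPeaks(sy$params))
    }
  } else if (kind == "fig7_single") {
    if (is.null(grid)) grid <- defaultGrid2D()
    nRep <- max(1L, round(1000 * scale))
    for (snr in c(5, 10, 15, 20)) for (r in seq_len(nRep)) {
      ex <- singlePeakExperiment(snr, grid,
                                 seed = deriveSeed(seed, sprintf("fig7-%g-%d", snr, r)))
      stem <- file.path(dir, sprintf("fig7_snr%02d_%04d", snr, r))
      exportSpectrum(ex$spectrum, stem)
      writeParamsTable(ex$params, paste0(stem, "_truth.tsv"))
      addRow(file = basename(stem), snr = snr, rep = r)
    }
  } else if (kind == "fig8_pair") {
    if (is.null(grid)) grid <- defaultGrid2D()
    nRep <- max(1L, round(1000 * scale))
    seps <- expand.grid(dd = c(0, 1, 2, 4, 8), id = c(0, 1, 2, 4, 8))
    for (s in seq_len(nrow(seps))) for (r in seq_len(nRep)) {
      ex <- pairPeakExperiment(10, c(seps$dd[s], seps$id[s]), grid,
                               seed = deriveSeed(seed, sprintf("fig8-%d-%d", s, r)))
      stem <- file.path(dir, sprintf("fig8_s%02d_%04d", s, r))
      exportSpectrum(ex$spectrum, stem)
      writeParamsTable(ex$params, paste0(stem, "_truth.tsv"))
      addRow(file = basename(stem), sepDirect = seps$dd[s],
             sepIndirect = seps$id[s], rep = r)
    }
  } else { # fig9_ta
    if (is.null(grid)) grid <- defaultGrid3D()
    nPeaks3 <- max(8L, round(128 * scale))
    sy <- makeBenchmarkSpectrum(grid, nPeaks3, noiseSpec("gaussian"),
                                seed = deriveSeed(seed, "fig9"))
    stem <- file.path(dir, "fig9_us3d")
    exportSpectrum(sy$spectrum, stem)
    writeParamsTable(sy$params, paste0(stem, "_truth.tsv"))
    addRow(file = basename(stem), nPeaks = nPeaks(sy$params))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

writeParamsTable <- function(params, path) {
  n <- ncol(params@frequency)
  df <- data.frame(amplitude = params@amplitude, sign = params@sign)
  for (k in seq_len(n)) {
    df[[paste0("omega", k)]] <- params@frequency[, k]
    df[[paste0("tau", k)]] <- params@relaxation[, k]
    df[[paste0("phi", k)]] <- params@phase[, k]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

readParamsTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- sum(grepl("^omega", names(df)))
  signalParams(df$amplitude,
               as.matrix(df[paste0("omega", seq_len(n))]),
               as.matrix(df[paste0("tau", seq_len(n))]),
               as.matrix(df[paste0("phi", seq_len(n))]),
               df$sign)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param grid acquisition grid.
#' @param nPeaks peaks per spectrum.
#' @param nSpectra number of evaluation spectra.
#' @param cutoff P5 probability cutoff.
#' @param seed master seed.
#' @param outDir output directory.
#' @param train training settings: either NULL (a model must be supplied to
#'   [runPipeline()]) or a list with `nSpectra` and `config` entries.
#' @return list of class "runConfig".
#' @export
runConfig <- function(grid = defaultGrid2D(), nPeaks = 64L, nSpectra = 2L,
                      cutoff = 0.5, seed = 1, outDir = tempfile("p3run"),
                      train = NULL) {
  structure(list(grid = grid, nPeaks = as.integer(nPeaks),
                 nSpectra = as.integer(nSpectra), cutoff = cutoff,
                 seed = seed, outDir = outDir, train = train),
            class = "runConfig")
}

#' Run the synthetic evaluation pipeline
#'
#' simulate -> predict P3 -> pick peaks (P5) -> score, writing per-spectrum
#' peak lists, a score table and the resolved configuration to the output
#' directory. With `dryRun = TRUE` the configuration is validated and
#' echoed without any computation.
#'
#' @param config a [runConfig()].
#' @param model a trained 2D [MRAiModel-class]; required unless
#'   `config$train` describes a training run.
#' @param dryRun validate only.
#' @return data.frame of per-spectrum scores (invisibly the output dir as
#'   attribute "outDir").
#' @export
runPipeline <- function(config, model = NULL, dryRun = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(model) && is.null(config$train))
    stop("no trained model supplied and config$train is missing")
  if (dryRun) return(invisible(config))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(list(nPeaks = config$nPeaks, nSpectra = config$nSpectra,
                            cutoff = config$cutoff, seed = config$seed,
                            points = config$grid@points,
                            zeroFill = config$grid@zeroFill,
                            apod = config$grid@apod),
                       cfgPath, auto_unbox = TRUE, digits = NA)
  if (is.null(model)) {
    td <- makeTrainingData(config$train$nSpectra, config$grid,
                           seed = deriveSeed(config$seed, "train"))
    model <- trainModel(buildModel(2L, seed = deriveSeed(config$seed, "init")),
                        td$X, td$y, config$train$config,
                        negKeepFraction = td$negKeepFraction)
  }
  rows <- list()
  for (i in seq_len(config$nSpectra)) {
    sy <- makeBenchmarkSpectrum(config$grid, config$nPeaks, noiseSpec("gaussian"),
                                seed = deriveSeed(config$seed, paste0("eval-", i)))
    p3 <- p3For2D(sy$spectrum, model)
    peaks <- pickPeaks(p3, cutoff = config$cutoff)
    writePeakList(peaks, file.path(config$outDir, sprintf("peaks_%03d.tsv", i)))
    truth <- detectablePixels(sy$params, sy$spectrum)
    sc <- detectionScores(p3, truth, evalConfig(threshold = config$cutoff))
    cal <- brierBce(as.numeric(p3@data), as.numeric(sy$labels@data))
    rows[[i]] <- data.frame(spectrum = i, recall = sc$recall,
                            precision = sc$precision, f1 = sc$f1,
                            bss = cal$bss, bceSS = cal$bceSS)
  }
  scores <- do.call(rbind, rows)
  utils::write.table(scores, file.path(config$outDir, "scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  attr(scores, "outDir") <- config$outDir
  scores
}

#' Single-peak localization study
#'
#' For each repetition: draw a single-peak spectrum at the given SNR
#' ([singlePeakExperiment()]), predict the probability map in a window
#' around the true position, pick the strongest peak with sub-pixel
#' refinement, and record the localization error together with the
#' per-spectrum theoretical uncertainties (frequency CRLB and, optionally,
#' Bayesian posterior SDs under the weak and/or strong phase prior).
#'
#' @param nRep repetitions.
#' @param snr spectral signal-to-noise.
#' @param model trained 2D [MRAiModel-class].
#' @param grid 2D acquisition grid.
#' @param seed master seed.
#' @param mc "none", "mcw", "mcs" or "both": which Bayesian samplers to run.
#' @param window half-width (pixels) of the prediction window around the
#'   true position.
#' @param cutoff peak-picking probability cutoff.
#' @param mcBurn,mcDraws sampler lengths per chain.
#' @return data.frame with one row per repetition and dimension (columns
#'   `rep`, `dim`, `error`, `crlb`, `mcw`, `mcs`, `found`, `prob`).
#' @export
localizationStudy <- function(nRep, snr, model, grid = defaultGrid2D(),
                              seed = 1, mc = c("none", "mcw", "mcs", "both"),
                              window = 8L, cutoff = 0.05,
                              mcBurn = 3000, mcDraws = 6000) {
  mc <- match.arg(mc)
  rows <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    ex <- singlePeakExperiment(snr, grid, seed = deriveSeed(seed, paste0("loc-", r)))
    dims <- specSize(grid)
    ctr <- round(ex$truthIndex) + 1L
    roi <- array(FALSE, dim = dims)
    i1 <- pmax(1L, ctr[1] - window):pmin(dims[1], ctr[1] + window)
    i2 <- pmax(1L, ctr[2] - window):pmin(dims[2], ctr[2] + window)
    roi[i1, i2] <- TRUE
    p3 <- predictMap(model, ex$spectrum, roiMask = roi)
    pk <- pickPeaks(p3, cutoff = cutoff)
    cb <- crlb(ex$theta, ex$sigmaT, grid)
    mcw <- mcs <- c(NA_real_, NA_real_)
    if (mc %in% c("mcw", "both"))
      mcw <- mcPosterior(ex$fidQuad, ex$theta, grid, ex$sigmaT, 30,
                         nBurn = mcBurn, nDraws = mcDraws,
                         seed = deriveSeed(seed, paste0("mcw-", r)))$freqSdPixels
    if (mc %in% c("mcs", "both"))
      mcs <- mcPosterior(ex$fidQuad, ex$theta, grid, ex$sigmaT, 4,
                         nBurn = mcBurn, nDraws = mcDraws,
                         seed = deriveSeed(seed, paste0("mcs-", r)))$freqSdPixels
    if (nrow(pk) == 0L) {
      err <- c(NA_real_, NA_real_); prob <- NA_real_; found <- FALSE
    } else {
      pos <- unlist(pk[1L, c("dim1", "dim2")])
      err <- pos - ex$truthIndex
      prob <- pk$probability[1L]
      found <- TRUE
    }
    rows[[r]] <- data.frame(rep = r, dim = 1:2, error = err,
                            crlb = cb$freqPixels[1L, ], mcw = mcw, mcs = mcs,
                            found = found, prob = prob)
  }
  do.call(rbind, rows)
}

#' Two-peak integrated-probability study
#'
#' For each repetition, generates a two-peak spectrum (reference peak at the
#' given SNR, interferer at twice the intensity and the stated pixel
#' separation), predicts the probability map over the cluster window and
#' integrates it. The integral approximates the number of peaks in the
#' cluster.
#'
#' @param nRep repetitions.
#' @param sepPixels length-2 pixel separation (direct, indirect).
#' @param model trained 2D model.
#' @param grid 2D grid.
#' @param snr reference-peak SNR.
#' @param seed master seed.
#' @param window half-width of the cluster box around each true position.
#' @param floor probability floor defining the cluster: points below it are
#'   not part of the integrated region (removes the box-size-dependent
#'   background contribution of a calibrated map, ~0.005 per pixel).
#' @return data.frame with columns `rep` and `integral`.
#' @export
integratedProbabilityStudy <- function(nRep, sepPixels, model,
                                       grid = defaultGrid2D(), snr = 10,
                                       seed = 1, window = 8L, floor = 0.05) {
  out <- numeric(nRep)
  dims <- specSize(grid)
  for (r in seq_len(nRep)) {
    ex <- pairPeakExperiment(snr, sepPixels, grid,
                             seed = deriveSeed(seed, paste0("pair-", r)))
    roi <- array(FALSE, dim = dims)
    for (j in 1:2) {
      ctr <- round(ex$truthIndex[j, ]) + 1L
      i1 <- pmax(1L, ctr[1] - window):pmin(dims[1], ctr[1] + window)
      i2 <- pmax(1L, ctr[2] - window):pmin(dims[2], ctr[2] + window)
      roi[i1, i2] <- TRUE
    }
    p3 <- predictMap(model, ex$spectrum, roiMask = roi)
    out[r] <- sum(p3@data[p3@data >= floor])
  }
  data.frame(rep = seq_len(nRep), integral = out)
}
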