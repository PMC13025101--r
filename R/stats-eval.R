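# Evaluation statistics: detectability thresholds, detection scores with
# vicinity matching, Brier/BCE skill scores, reliability (calibration)
# curves, peak overlap scores, and integrated probability.

#' Evaluation configuration
#'
#' @param vicinityRadius matching radius in pixels (Euclidean; default 2,
#'   consistent with the one-to-two-point localization precision of the
#'   probability maps).
#' @param threshold probability threshold above which a pixel counts as
#'   detected.
#' @param detectabilityMultiplier base detectability threshold in sigma-noise
#'   units for fully sampled spectra (default 2).
#' @param nusScaling how the detectability threshold grows as the sampling
#'   fraction f shrinks: "sqrt" (2 sigma / sqrt(f); reproduces the printed
#'   5 sigma and 9 sigma thresholds at 15% and 5%) or "linear"
#'   (2 sigma / f).
#' @param bins calibration bin edges partitioning [0, 1].
#' @return list of class "evalConfig".
#' @export
evalConfig <- function(vicinityRadius = 2, threshold = 0.5,
                       detectabilityMultiplier = 2,
                       nusScaling = c("sqrt", "linear"),
                       bins = seq(0, 1, by = 0.1)) {
  stopifnot(vicinityRadius >= 0, bins[1] == 0, bins[length(bins)] == 1)
  structure(list(vicinityRadius = vicinityRadius, threshold = threshold,
                 detectabilityMultiplier = detectabilityMultiplier,
                 nusScaling = match.arg(nusScaling), bins = bins),
            class = "evalConfig")
}

#' Detectability threshold in sigma-noise units
#'
#' @param nusFraction sampling fraction in (0, 1].
#' @param config an [evalConfig()].
#' @return scalar threshold: 2 sigma for fully sampled data, growing as the
#'   fraction shrinks (about 5 sigma at 15% and 9 sigma at 5% under the
#'   default square-root scaling).
#' @export
detectabilityThreshold <- function(nusFraction = 1, config = evalConfig()) {
  if (nusFraction <= 0 || nusFraction > 1) stop("nusFraction must lie in (0, 1]")
  m <- config$detectabilityMultiplier
  if (config$nusScaling == "sqrt") m / sqrt(nusFraction) else m / nusFraction
}

#' Pixels of detectable ground-truth peaks
#'
#' A peak is detectable when its amplitude (in sigma-noise units of the
#' uniformly sampled spectrum) strictly exceeds the detectability threshold;
#' the detectable pixels are its label-mask pixels.
#'
#' @param params ground-truth [SignalParams-class] (amplitudes in sigma
#'   units).
#' @param spectrum the processed [NMRSpectrum-class].
#' @param nusFraction sampling fraction the spectrum was (re)constructed from.
#' @param config an [evalConfig()].
#' @return integer matrix of 1-based detectable pixel subscripts.
#' @export
detectablePixels <- function(params, spectrum, nusFraction = 1,
                             config = evalConfig()) {
  thr <- detectabilityThreshold(nusFraction, config)
  keep <- params@amplitude > thr
  sub <- signalParams(params@amplitude[keep],
                      params@frequency[keep, , drop = FALSE],
                      params@relaxation[keep, , drop = FALSE],
                      params@phase[keep, , drop = FALSE],
                      params@sign[keep])
  if (nPeaks(sub) == 0L) return(matrix(integer(0), 0L, spectrumDims(spectrum)))
  m <- makeLabelMask(sub, spectrum)@data
  linearToSub(which(m == 1), dim(m))
}

#' Detection scores with vicinity matching
#'
#' A pixel is detected when its probability is at or above the threshold;
#' a detected pixel is correct when it lies within the vicinity radius
#' (Euclidean, in pixels) of a detectable ground-truth pixel. Recall is the
#' fraction of detectable pixels with at least one detected pixel in their
#' vicinity; precision the fraction of detected pixels that are correct; F1
#' their harmonic mean. Zero denominators yield a 0 score with a flag.
#'
#' @param p3 a [P3Map-class] or probability array.
#' @param truthPixels matrix of detectable pixel subscripts (1-based), e.g.
#'   from [detectablePixels()].
#' @param config an [evalConfig()].
#' @return list with recall, precision, f1, counts, and `flagged`.
#' @export
detectionScores <- function(p3, truthPixels, config = evalConfig()) {
  a <- if (is(p3, "P3Map")) p3@data else p3
  dims <- dim(a)
  det <- linearToSub(which(a >= config$threshold), dims)
  r2 <- config$vicinityRadius^2
  nearAny <- function(pts, ref) {
    # for each row of pts: any ref point within radius?
    if (nrow(ref) == 0L || nrow(pts) == 0L) return(rep(FALSE, nrow(pts)))
    apply(pts, 1L, function(p) {
      d2 <- rowSums(sweep(ref, 2L, p, `-`)^2)
      any(d2 <= r2)
    })
  }
  flagged <- FALSE
  if (nrow(truthPixels) == 0L) { recall <- 0; flagged <- TRUE }
  else recall <- mean(nearAny(truthPixels, det))
  if (nrow(det) == 0L) { precision <- 0; flagged <- TRUE }
  else precision <- mean(nearAny(det, truthPixels))
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f1 = f1,
       nDetected = nrow(det), nDetectable = nrow(truthPixels), flagged = flagged)
}

#' Brier and binary cross-entropy scores with their skill scores
#'
#' Computes the Brier score BS = mean((y - p)^2), the binary cross-entropy,
#' the base rate pi = mean(y), the reference scores of the constant
#' base-rate predictor (BS_ref = pi (1 - pi),
#' BCE_ref = -[pi log pi + (1 - pi) log(1 - pi)]) and the skill scores
#' Skill = 1 - S / S_ref. A skill of 1 is a perfect predictor; values of
#' 0.5 and above indicate a very good model.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels 0/1 ground-truth labels.
#' @return list with bs, bce, pi, bsRef, bceRef, bss, bceSS, and `flagged`
#'   (TRUE when the labels are single-class and the skills are undefined).
#' @export
brierBce <- function(probs, labels) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  bs <- mean((labels - probs)^2)
  bceVal <- bce(probs, labels)
  pi0 <- mean(labels)
  if (pi0 == 0 || pi0 == 1) {
    return(list(bs = bs, bce = bceVal, pi = pi0, bsRef = 0, bceRef = 0,
                bss = NA_real_, bceSS = NA_real_, flagged = TRUE))
  }
  bsRef <- pi0 * (1 - pi0)
  bceRef <- -(pi0 * log(pi0) + (1 - pi0) * log(1 - pi0))
  list(bs = bs, bce = bceVal, pi = pi0, bsRef = bsRef, bceRef = bceRef,
       bss = 1 - bs / bsRef, bceSS = 1 - bceVal / bceRef, flagged = FALSE)
}

#' Reliability (calibration) curve
#'
#' Bins the predicted probabilities, and reports per non-empty bin the mean
#' predicted probability, the observed positive fraction and the count. The
#' ideal calibration curve is the diagonal.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels.
#' @param bins bin edges (default 0, 0.1, ..., 1).
#' @return data.frame with columns `meanPredicted`, `observedFraction`,
#'   `count`; empty bins are omitted.
#' @export
calibrationCurve <- function(probs, labels, bins = seq(0, 1, by = 0.1)) {
  bin <- cut(probs, bins, include.lowest = TRUE)
  keep <- !is.na(bin)
  agg <- lapply(split(seq_along(probs)[keep], bin[keep], drop = TRUE), function(ii)
    c(mean(probs[ii]), mean(labels[ii]), length(ii)))
  out <- do.call(rbind, agg)
  data.frame(meanPredicted = out[, 1L], observedFraction = out[, 2L],
             count = as.integer(out[, 3L]), row.names = NULL)
}

#' Peak overlap score
#'
#' For peak j with intensity I0, the overlap score is
#' \eqn{\sum_i I_i / (I_0 d_i^2)} over neighbouring peaks within 16 pixels
#' (Euclidean distance on the post-zero-fill grid). An isolated peak scores
#' 0; coincident peaks (d = 0) are excluded with a flag.
#'
#' @param j index of the peak being scored.
#' @param positions J x n matrix of peak positions in pixel units.
#' @param intensities length-J intensities.
#' @param maxDist neighbourhood radius in pixels (default 16).
#' @return scalar score; attribute "flagged" marks excluded coincident peaks.
#' @export
overlapScore <- function(j, positions, intensities, maxDist = 16) {
  d <- sqrt(rowSums(sweep(positions, 2L, positions[j, ], `-`)^2))
  d[j] <- Inf
  coincident <- d == 0
  use <- d < maxDist & !coincident
  s <- sum(intensities[use] / (intensities[j] * d[use]^2))
  attr(s, "flagged") <- any(coincident)
  s
}

#' Integrated probability over a region
#'
#' The sum of map probabilities over a cluster region is a proxy for the
#' number of peaks in the cluster (close to 1 for a single peak, close to 2
#' for a resolved pair).
#'
#' @param p3 a [P3Map-class] or probability array.
#' @param region logical array, index vector, or subscript matrix selecting
#'   the cluster region.
#' @return scalar integrated probability.
#' @export
integratedProbability <- function(p3, region) {
  a <- if (is(p3, "P3Map")) p3@data else p3
  if (is.matrix(region) && ncol(region) == length(dim(a)) && nrow(region) > 0)
    region <- subToLinear(region, dim(a))
  sum(a[region])
}
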