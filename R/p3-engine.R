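# End-to-end P3 inference: direct 2D prediction, 3D region-of-interest
# selection from skyline-projection probabilities, hyperdimensional
# coprocessing with support spectra, and targeted-acquisition build-up
# counting.

# Engine operations accept either a trained MRAiModel or a plain function
# mapping an NMRSpectrum to a probability array -- the latter keeps the
# engine logic testable with deterministic probability oracles.
applyP3Model <- function(model, spectrum, roiMask = NULL) {
  if (is.function(model)) {
    a <- model(spectrum)
    if (is(a, "P3Map")) a <- a@data
    if (!is.null(roiMask)) a[roiMask == 0] <- 0
    return(a)
  }
  predictMap(model, spectrum, roiMask = roiMask)@data
}

#' P3 map of a 2D spectrum
#'
#' Applies the trained 2D model directly to every point of the spectrum.
#' Optionally the spectrum is zero-filled further before prediction (the
#' production protocol zero-fills the input twice before map generation for
#' finer peak sampling); by default the spectrum is used on its native grid,
#' which is the grid the bundled training protocol matches.
#'
#' @param spectrum a 2D [NMRSpectrum-class].
#' @param model a trained 2D [MRAiModel-class] (or oracle function).
#' @param extraZeroFill integer factor applied via [rezeroFill()] before
#'   prediction (1 = off).
#' @return A [P3Map-class] on the (possibly re-zero-filled) grid.
#' @export
p3For2D <- function(spectrum, model, extraZeroFill = 1L) {
  if (spectrumDims(spectrum) != 2L) stop("p3For2D expects a 2D spectrum")
  if (extraZeroFill > 1L) spectrum <- rezeroFill(spectrum, extraZeroFill)
  a <- applyP3Model(model, spectrum)
  newP3Map(a, provenance = list(stage = "p3-2d", extraZeroFill = extraZeroFill))
}

# P3 maps of the three orthogonal skyline projections of a 3D spectrum,
# optionally replacing projections by support-spectrum maps. Returns a list
# indexed by dropped axis: list(map = 2D prob array, axes = kept axes).
projectionP3 <- function(spectrum3d, projectionModels, support = NULL) {
  n <- spectrumDims(spectrum3d)
  stopifnot(n == 3L)
  out <- vector("list", 3L)
  for (k in 1:3) {
    keep <- setdiff(1:3, k)
    sup <- NULL
    if (!is.null(support))
      for (s in support)
        if (all(sort(s$axes) == keep)) sup <- s
    if (!is.null(sup)) {
      pm <- if (!is.null(sup$p3)) {
        if (is(sup$p3, "P3Map")) sup$p3@data else sup$p3
      } else {
        spec2 <- sup$spectrum
        if (!all(dim(intensity(spec2)) == dim(intensity(spectrum3d))[keep]))
          stop("support spectrum axes do not match the 3D projection grid")
        applyP3Model(sup$model, spec2)
      }
      out[[k]] <- list(map = pm, axes = keep, source = "support")
    } else {
      proj <- skylineProject(spectrum3d, k)
      mdl <- if (length(projectionModels) >= k && !is.null(projectionModels[[k]]))
        projectionModels[[k]] else projectionModels[[1L]]
      out[[k]] <- list(map = applyP3Model(mdl, proj), axes = keep,
                       source = "skyline")
    }
  }
  out
}

#' Region of interest of a 3D spectrum from projected probabilities
#'
#' Each 3D point receives a preliminary score: the product of the P3 values
#' of its images in the used orthogonal 2D projections. The ROI keeps the
#' points whose geometric probability mean (the k-th root of the product
#' over k projections) exceeds the threshold, 2.5% by default -- a
#' compromise between projection recall and a class balance narrow enough
#' for the sensitive 3D model.
#'
#' @param spectrum3d a 3D [NMRSpectrum-class].
#' @param projectionModels list of up to 3 trained 2D models (recycled), one
#'   per skyline projection (dropped axis 1, 2, 3); entries may be oracle
#'   functions.
#' @param support optional list of support entries, each
#'   \code{list(axes = c(i, j), spectrum =, model =)} or
#'   \code{list(axes =, p3 =)}; a support replaces the matching skyline
#'   projection.
#' @param threshold geometric-mean probability threshold (default 0.025).
#' @param useAxes which projections to use (default all three).
#' @return logical 3D array (the ROI mask) with attribute "threshold".
#' @export
roi3D <- function(spectrum3d, projectionModels, support = NULL,
                  threshold = 0.025, useAxes = 1:3) {
  if (length(useAxes) < 1L) stop("at least one projection is required")
  pp <- projectionP3(spectrum3d, projectionModels, support)
  dims <- dim(intensity(spectrum3d))
  score <- array(1, dim = dims)
  for (k in useAxes) {
    m <- pp[[k]]$map
    keep <- pp[[k]]$axes
    # broadcast the 2D map over the dropped axis
    perm <- order(c(keep, setdiff(1:3, keep)))
    big <- aperm(array(m, dim = c(dim(m), dims[setdiff(1:3, keep)])), perm)
    score <- score * big
  }
  roi <- score^(1 / length(useAxes)) > threshold
  attr(roi, "threshold") <- threshold
  attr(roi, "sources") <- vapply(pp, `[[`, "", "source")
  roi
}

#' P3 map of a 3D spectrum within a region of interest
#'
#' Evaluates the sensitive 3D model on the ROI points only; all other points
#' are exactly 0. An empty ROI yields an all-zero map with a warning.
#'
#' @param spectrum3d a 3D [NMRSpectrum-class].
#' @param roi logical ROI mask from [roi3D()] (or full-grid TRUE mask).
#' @param model3d trained 3D [MRAiModel-class] (or oracle function).
#' @return A [P3Map-class].
#' @export
p33D <- function(spectrum3d, roi, model3d) {
  if (sum(roi) == 0) {
    warning("empty region of interest; returning an all-zero map")
    return(newP3Map(array(0, dim = dim(intensity(spectrum3d))),
                    provenance = list(stage = "p3-3d", roiPoints = 0L)))
  }
  a <- applyP3Model(model3d, spectrum3d, roiMask = roi)
  newP3Map(a, provenance = list(stage = "p3-3d", roiPoints = sum(roi),
                                roiThreshold = attr(roi, "threshold")))
}

#' Targeted-acquisition build-up of peak counts
#'
#' Emulates incremental NUS acquisition: for each sampling fraction the FID
#' is subsampled, reconstructed with CS-IST, converted to a P3 map (3D route
#' with projection ROI, optionally coprocessed with a support spectrum), and
#' peaks are counted above a conservative probability cutoff (20% by
#' default, the level used for robust real-time monitoring).
#'
#' @param fid full hypercomplex 3D FID array.
#' @param grid the [AcqGrid-class].
#' @param fractions increasing NUS fractions to evaluate.
#' @param projectionModels,support,model3d as in [roi3D()] / [p33D()].
#' @param cutoff P5 probability cutoff (default 0.2).
#' @param roiThreshold geometric-mean ROI threshold.
#' @param scheduleKind,nIterations schedule and CS-IST settings.
#' @param seed seed for the schedules.
#' @return data.frame with columns `fraction` and `count` (one row per
#'   requested fraction, no silent skips).
#' @export
taBuildup <- function(fid, grid, fractions, projectionModels, model3d,
                      support = NULL, cutoff = 0.2, roiThreshold = 0.025,
                      scheduleKind = "poisson_gap", nIterations = 50,
                      seed = 1) {
  if (is.unsorted(fractions, strictly = FALSE))
    stop("fractions must be sorted increasing")
  counts <- integer(length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    sp <- if (f >= 1) {
      processSpectrum(fid, grid)
    } else {
      sched <- makeSchedule(grid, f, scheduleKind,
                            seed = deriveSeed(seed, paste0("ta-", f)))
      suppressWarnings(csIstReconstruct(subsampleFid(fid, sched), grid,
                                        nIterations = nIterations))
    }
    roi <- roi3D(sp, projectionModels, support = support,
                 threshold = roiThreshold)
    p3 <- p33D(sp, roi, model3d)
    counts[i] <- nrow(pickPeaks(p3, cutoff = cutoff))
  }
  data.frame(fraction = fractions, count = counts)
}
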