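# Engine-logic tests use deterministic probability oracles in place of
# trained networks, so ROI composition, thresholds and counting are checked
# independently of model quality; trained-model behavior is covered in the
# acceptance suite.

test_that("p3For2D produces bounded maps and respects dimensionality", {
  g <- smallGrid2D()
  sy <- synthesizeSpectrum(onePeak2D(amp = 30), g, noiseSpec("gaussian"), seed = 2)
  p3 <- p3For2D(sy$spectrum, oracleModelFor(sy$labels))
  expect_s4_class(p3, "P3Map")
  expect_true(all(p3@data >= 0 & p3@data <= 1))
  g3 <- smallGrid3D()
  sp3 <- processSpectrum(simulateFid(signalParams(1, matrix(c(0, 0, 0), 1),
                                                  matrix(5, 1, 3)), g3), g3)
  expect_error(p3For2D(sp3, oracleModelFor(sy$labels)), "2D")
})

test_that("ROI selection composes projection probabilities geometrically", {
  g3 <- smallGrid3D()
  p <- signalParams(20, matrix(c(0.1, -0.2, 0.25), 1), matrix(8, 1, 3))
  sy <- synthesizeSpectrum(p, g3, noiseSpec("gaussian"), seed = 3)
  sp3 <- sy$spectrum
  dims <- dim(intensity(sp3))
  # oracle per projection: probability 0.5 at the projected truth, 0 elsewhere
  mkProjOracle <- function() function(spec2) {
    a2 <- intensity(spec2)
    m <- array(0, dim = dim(a2))
    mx <- which(a2 == max(a2), arr.ind = TRUE)[1, ]
    m[mx[1], mx[2]] <- 0.5
    m
  }
  models <- list(mkProjOracle(), mkProjOracle(), mkProjOracle())
  roi <- roi3D(sp3, models, threshold = 0.025)
  # geometric mean 0.5 > 0.025 at the peak: the true maximum is inside
  mx3 <- which(intensity(sp3) == max(intensity(sp3)), arr.ind = TRUE)[1, ]
  expect_true(roi[mx3[1], mx3[2], mx3[3]])
  # ROI much smaller than the grid
  expect_lt(sum(roi) / prod(dims), 0.05)
  # any projection probability 0 excludes the point: only the one crossing
  # line of sight of all three projections survives
  expect_true(all(which(roi, arr.ind = TRUE)[, 1] == mx3[1]))
  # threshold monotonicity: ROI shrinks as the threshold grows
  roiLo <- roi3D(sp3, models, threshold = 0.001)
  roiHi <- roi3D(sp3, models, threshold = 0.4)
  expect_true(all(roi[roiHi]))       # high-threshold ROI nested in default
  expect_true(all(roiLo[roi]))       # default nested in low-threshold
  expect_lte(sum(roiHi), sum(roi))
  expect_lte(sum(roi), sum(roiLo))
  expect_error(roi3D(sp3, models, useAxes = integer(0)), "at least one")
})

test_that("geometric-mean arithmetic matches the stated 2.5% rule", {
  # projected probabilities (0.5, 0.5, 0.5): geometric mean 0.5 -> in ROI
  expect_gt((0.5 * 0.5 * 0.5)^(1 / 3), 0.025)
  # a zero projection forces exclusion
  expect_equal((0.5 * 0 * 0.5)^(1 / 3), 0)
})

test_that("p33D evaluates only the ROI and reproduces full-grid prediction", {
  g3 <- smallGrid3D()
  p <- signalParams(20, matrix(c(0.1, -0.2, 0.25), 1), matrix(8, 1, 3))
  sy <- synthesizeSpectrum(p, g3, noiseSpec("gaussian"), seed = 4)
  oracle <- oracleModelFor(sy$labels)
  dims <- dim(intensity(sy$spectrum))
  roi <- array(FALSE, dims); roi[1:4, , ] <- TRUE
  p3 <- p33D(sy$spectrum, roi, oracle)
  expect_true(all(p3@data[!roi] == 0))
  # full-grid ROI reproduces the unrestricted map
  full <- p33D(sy$spectrum, array(TRUE, dims), oracle)
  expect_equal(full@data, applyP3ModelForTest(oracle, sy$spectrum))
  expect_warning(pe <- p33D(sy$spectrum, array(FALSE, dims), oracle), "empty")
  expect_true(all(pe@data == 0))
})

test_that("support spectra replace skyline projections in the ROI", {
  g3 <- smallGrid3D()
  p <- signalParams(20, matrix(c(0.1, -0.2, 0.25), 1), matrix(8, 1, 3))
  sy <- synthesizeSpectrum(p, g3, noiseSpec("gaussian"), seed = 5)
  sp3 <- sy$spectrum
  projOracle <- function(spec2) {
    a2 <- intensity(spec2)
    m <- array(0, dim = dim(a2))
    mx <- which(a2 == max(a2), arr.ind = TRUE)[1, ]
    m[mx[1], mx[2]] <- 0.5
    m
  }
  models <- list(projOracle, projOracle, projOracle)
  roiPlain <- roi3D(sp3, models)
  # support identical to the skyline projection: identical ROI
  skyl <- skylineProject(sp3, 3)
  roiSup <- roi3D(sp3, models,
                  support = list(list(axes = c(1, 2), p3 = projOracle(skyl))))
  expect_equal(array(roiSup, dim = dim(roiSup)), array(roiPlain, dim = dim(roiPlain)))
  expect_equal(attr(roiSup, "sources")[3], "support")
  # all-zero support probability empties the ROI
  zeroP3 <- array(0, dim = dim(intensity(skyl)))
  roiZero <- roi3D(sp3, models, support = list(list(axes = c(1, 2), p3 = zeroP3)))
  expect_equal(sum(roiZero), 0L)
})

test_that("TA build-up counts every fraction and responds to peak number", {
  g3 <- smallGrid3D()
  # two well-separated strong peaks; oracle projections from the truth
  p <- signalParams(c(40, 40), rbind(c(-0.25, -0.25, -0.25), c(0.2, 0.2, 0.2)),
                    matrix(6, 2, 3))
  sy <- synthesizeSpectrum(p, g3, noiseSpec("gaussian"), seed = 6)
  fid <- toTimeDomain(sy$spectrum)
  labProj <- function(k) {
    keep <- setdiff(1:3, k)
    apply(sy$labels@data, keep, max) * 0.9
  }
  models <- lapply(1:3, function(k) { f <- labProj(k); function(s) f })
  oracle3 <- oracleModelFor(sy$labels)
  tb <- taBuildup(fid, g3, c(0.3, 0.6, 1), models, oracle3, nIterations = 30)
  expect_equal(tb$fraction, c(0.3, 0.6, 1))
  expect_equal(nrow(tb), 3L)               # no silent skips
  expect_true(all(tb$count >= 0))
  # the full-sampling count sees both peaks with the truth oracle
  expect_equal(tb$count[3], 2L)
  expect_error(taBuildup(fid, g3, c(0.5, 0.1), models, oracle3), "sorted")
})
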