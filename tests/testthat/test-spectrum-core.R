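test_that("simulateFid matches the exponential model at t = 0 and rejects bad input", {
  g <- smallGrid2D()
  # non-decaying on-resonance peak: cosine-cosine channel is 1 everywhere
  fid <- simulateFid(signalParams(1, c(0, 0), c(1e6, 1e6)), g)
  expect_equal(max(abs(fid[, , 1] - 1)), 0, tolerance = 1e-4)
  expect_equal(max(abs(fid[, , 2])), 0, tolerance = 1e-4)
  # zero peaks -> all-zero array
  empty <- signalParams(numeric(0), matrix(0, 0, 2), matrix(0, 0, 2))
  expect_true(all(simulateFid(empty, g) == 0))
  # two peaks, phases 0: t = 0 cosine-cosine value is A1 + A2
  fid2 <- simulateFid(signalParams(c(2, 3), matrix(c(0.1, -0.2, 0.3, 0.1), 2),
                                   matrix(20, 2, 2)), g)
  expect_equal(fid2[1, 1, 1], 5)
  # invariant violations are rejected
  expect_error(signalParams(1, c(0.6, 0), c(10, 10)), "Nyquist")
  expect_error(signalParams(-1, c(0, 0), c(10, 10)), "> 0")
  expect_error(signalParams(1, c(0, 0), c(-1, 10)), "relaxation")
})

test_that("processing places peaks at the stated frequency-axis convention", {
  g <- smallGrid2D()
  N <- specSize(g)
  # single peak at omega = 0.25: maximum within 1 pixel of N (0.25 + 0.5)
  sp <- processSpectrum(simulateFid(onePeak2D(omega = c(0.25, 0)), g), g)
  mx <- which(intensity(sp) == max(intensity(sp)), arr.ind = TRUE)
  expect_lte(abs((mx[1] - 1) - N[1] * 0.75), 1)
  expect_lte(abs((mx[2] - 1) - N[2] * 0.5), 1)
  # all-zero input -> all-zero spectrum
  z <- array(0, dim = c(g@points, 4L))
  expect_true(all(processSpectrum(z, g)@components == 0))
  # zero-fill factor below 2 is rejected
  g1 <- acqGrid(c(32, 32), zeroFill = 1L)
  expect_error(processSpectrum(simulateFid(onePeak2D(), g1), g1), "zero-fill")
})

test_that("a non-decaying, apodized, zero-filled peak spans at most 3 grid points", {
  g <- smallGrid2D()
  sp <- processSpectrum(simulateFid(signalParams(1, c(0, 0), c(1e6, 1e6)), g), g)
  a <- intensity(sp)
  mx <- which(a == max(a), arr.ind = TRUE)
  row <- a[, mx[2]]
  expect_lte(sum(row > max(row) / 2), 3)
  col <- a[mx[1], ]
  expect_lte(sum(col > max(col) / 2), 3)
})

test_that("spectra are linear in the peak set", {
  g <- smallGrid2D()
  pa <- sampleSpectrumParams(nPeaks = 3, seed = 1)
  pb <- sampleSpectrumParams(nPeaks = 2, seed = 2)
  pc <- signalParams(c(pa@amplitude, pb@amplitude),
                     rbind(pa@frequency, pb@frequency),
                     rbind(pa@relaxation, pb@relaxation),
                     rbind(pa@phase, pb@phase))
  sAB <- intensity(processSpectrum(simulateFid(pc, g), g))
  sA <- intensity(processSpectrum(simulateFid(pa, g), g))
  sB <- intensity(processSpectrum(simulateFid(pb, g), g))
  expect_equal(sAB, sA + sB, tolerance = 1e-10)
})

test_that("label masks follow the 0.25-0.75 dual-labeling rule", {
  g <- smallGrid2D()
  N <- specSize(g)
  mkMask <- function(u1) {
    om <- indexToFreq(u1, N[1])
    p <- signalParams(5, c(om, 0), c(30, 30))
    makeLabelMask(p, processSpectrum(simulateFid(p, g), g))
  }
  # fractional index 10.5 -> both 10 and 11 labeled (in dimension 1)
  m <- mkMask(10.5)@data
  expect_equal(which(rowSums(m) > 0) - 1L, c(10L, 11L))
  # exact index 10.0 -> only 10
  expect_equal(which(rowSums(mkMask(10)@data) > 0) - 1L, 10L)
  # fractional 10.8 -> only 11 (0.2 from index 11 is outside the dual band)
  expect_equal(which(rowSums(mkMask(10.8)@data) > 0) - 1L, 11L)
  # boundary of the band: 10.25 and 10.75 both dual-label
  expect_equal(which(rowSums(mkMask(10.25)@data) > 0) - 1L, c(10L, 11L))
  expect_equal(which(rowSums(mkMask(10.75)@data) > 0) - 1L, c(10L, 11L))
})

test_that("label-mask positions coincide with spectrum maxima for isolated peaks", {
  g <- smallGrid2D()
  hits <- 0L
  nRep <- 60L
  for (r in seq_len(nRep)) {
    p <- sampleSpectrumParams(spectrumParamRanges(ampRange = c(50, 50),
                                                  phaseRange = c(0, 0),
                                                  freqMargin = 0.1),
                              nPeaks = 1, seed = r)
    sy <- synthesizeSpectrum(p, g, noise = NULL)
    a <- intensity(sy$spectrum)
    mx <- which(a == max(a), arr.ind = TRUE)[1, ]
    lab <- linearToSub(which(sy$labels@data == 1), dim(a))
    near <- any(apply(lab, 1, function(lp) all(abs(lp - mx) <= 0)))
    hits <- hits + near
  }
  expect_gte(hits / nRep, 0.99)
})

test_that("skyline projection takes element-wise maxima and commutes with scaling", {
  g <- smallGrid3D()
  p <- signalParams(c(5, 3), matrix(c(0.1, 0.1, -0.2, -0.2, 0.05, 0.3), 2),
                    matrix(10, 2, 3))
  sp <- processSpectrum(simulateFid(p, g), g)
  # all-zero spectrum projects to all-zero
  z <- newSpectrum(array(0, dim = c(specSize(g), 1L)), g)
  expect_true(all(intensity(skylineProject(z, 3))  == 0))
  # single-peak maximum is projection-invariant
  p1 <- signalParams(5, matrix(c(0.1, -0.2, 0.05), 1), matrix(10, 1, 3))
  sp1 <- processSpectrum(simulateFid(p1, g), g)
  expect_equal(max(intensity(skylineProject(sp1, 2))), max(intensity(sp1)))
  # two peaks sharing (x, y): merged projected peak keeps the larger height
  proj <- skylineProject(sp, 3)
  expect_equal(max(intensity(proj)), max(intensity(sp)))
  # commutes with positive scaling
  spScaled <- newSpectrum(sp@components * 3.7, g, NA_real_)
  expect_equal(intensity(skylineProject(spScaled, 1)),
               3.7 * intensity(skylineProject(sp, 1)), tolerance = 1e-12)
  expect_error(skylineProject(sp, 4), "axis")
})

test_that("sampled parameters respect the configured ranges and seed determinism", {
  r <- spectrumParamRanges()
  p <- sampleSpectrumParams(r, nPeaks = 256, seed = 3)
  expect_lte(max(p@amplitude) / min(p@amplitude), 200)
  expect_gte(min(p@amplitude), 1)
  expect_lt(min(p@amplitude), 1.2) # weakest peaks reach down to ~1 sigma
  expect_true(all(abs(p@frequency) <= 0.45))
  expect_true(all(p@relaxation >= 8 & p@relaxation <= 128))
  expect_true(all(abs(p@phase) <= 5))
  p2 <- sampleSpectrumParams(r, nPeaks = 256, seed = 3)
  expect_identical(p, p2)
  # configurable narrow phase band
  p3 <- sampleSpectrumParams(spectrumParamRanges(phaseRange = c(-5, 5)),
                             nPeaks = 50, seed = 4)
  expect_true(all(p3@phase >= -5 & p3@phase <= 5))
  expect_error(spectrumParamRanges(ampRange = c(10, 1)), "range")
})

test_that("synthesizeSpectrum calibrates peak height and noise to sigma units", {
  g <- smallGrid2D()
  p <- signalParams(10, c(0.125, 0.125), c(30, 30))
  # noise-free: the height equals the sigma-unit amplitude exactly
  a0 <- intensity(synthesizeSpectrum(p, g, noise = NULL)$spectrum)
  expect_equal(max(a0), 10, tolerance = 1e-9)
  # with sigma-1 noise: height at the peak index within 4 sigma of nominal
  sy <- synthesizeSpectrum(p, g, noiseSpec("gaussian"), seed = 5)
  a <- intensity(sy$spectrum)
  ix <- which(a0 == max(a0), arr.ind = TRUE)[1, ]
  expect_lt(abs(a[ix[1], ix[2]] - 10), 4)
  expect_equal(robustSigma(a), 1, tolerance = 0.1) # noise sigma = 1
})
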