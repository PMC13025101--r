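test_that("schedules honor their invariants", {
  g <- acqGrid(c(32, 128))
  # fraction 1 keeps everything
  s1 <- makeSchedule(g, 1, "uniform_random")
  expect_equal(nrow(s1@indices), 128L)
  # count = round(fraction x grid): 0.15 x 128 -> 19
  s <- makeSchedule(g, 0.15, "poisson_gap", seed = 11)
  expect_equal(nrow(s@indices), 19L)
  expect_true(any(s@indices == 0L))          # t = 0 kept
  expect_false(anyDuplicated(s@indices) > 0)
  # determinism under a fixed seed
  expect_identical(s@indices, makeSchedule(g, 0.15, "poisson_gap", seed = 11)@indices)
  expect_error(makeSchedule(g, 0.001, "uniform_random"), "zero sampled")
  # 3D: product poisson-gap schedule hits the exact joint count
  g3 <- acqGrid(c(16, 16, 16))
  s3 <- makeSchedule(g3, 0.25, "poisson_gap", seed = 2)
  expect_equal(nrow(s3@indices), round(0.25 * 256))
  expect_equal(ncol(s3@indices), 2L)
})

test_that("subsampling marks absent increments and keeps measured ones", {
  g <- acqGrid(c(16, 32))
  fid <- simulateFid(onePeak2D(), g)
  s <- makeSchedule(g, 0.25, "uniform_random", seed = 3)
  sub <- subsampleFid(fid, s)
  m <- attr(sub, "sampledMask")
  expect_equal(sum(m), 8L)
  expect_equal(sum(!m), round((1 - 0.25) * 32))
  # measured increments intact, absent ones zero
  expect_equal(sub[, m, ], fid[, m, ])
  expect_true(all(sub[, !m, ] == 0))
  # full schedule is the identity
  subFull <- subsampleFid(fid, makeSchedule(g, 1, "uniform_random"))
  expect_equal(as.numeric(subFull), as.numeric(fid))
  sBad <- makeSchedule(acqGrid(c(16, 64)), 0.5, "uniform_random", seed = 1)
  expect_error(subsampleFid(fid, sBad), "fit")
})

test_that("CS-IST is exact at 100% sampling and clean on all-zero input", {
  g <- acqGrid(c(16, 32))
  fid <- simulateFid(sampleSpectrumParams(nPeaks = 3, seed = 5), g)
  ref <- processSpectrum(fid, g)
  rec <- csIstReconstruct(subsampleFid(fid, makeSchedule(g, 1, "uniform_random")),
                          g, nIterations = 10)
  expect_lt(max(abs(intensity(rec) - intensity(ref))) / max(abs(intensity(ref))), 1e-6)
  z <- array(0, dim = c(g@points, 4L))
  zr <- csIstReconstruct(subsampleFid(z, makeSchedule(g, 0.5, "uniform_random", seed = 1)),
                         g, nIterations = 10)
  expect_true(all(intensity(zr) == 0))
})

test_that("CS-IST recovers an isolated peak position exactly at 30% sampling", {
  g <- smallGrid2D()
  sy <- synthesizeSpectrum(signalParams(50, c(0.1, -0.2), c(20, 20)), g,
                           noiseSpec("gaussian"), seed = 2)
  fid <- toTimeDomain(sy$spectrum)
  at <- intensity(sy$spectrum)
  s <- makeSchedule(g, 0.3, "uniform_random", seed = 4)
  rec <- suppressWarnings(csIstReconstruct(subsampleFid(fid, s), g, nIterations = 150))
  a <- intensity(rec)
  expect_equal(which(a == max(a), arr.ind = TRUE),
               which(at == max(at), arr.ind = TRUE))
  # amplitude bias of threshold-only IST on truncated lineshapes (no virtual
  # echo): moderate underestimate, bounded at 30%
  expect_lt(abs(max(a) - max(at)) / max(at), 0.3)
})

test_that("reconstruction error shrinks with the sampling fraction", {
  g <- smallGrid2D()
  sy <- synthesizeSpectrum(sampleSpectrumParams(
    spectrumParamRanges(ampRange = c(20, 100)), nPeaks = 5, seed = 9), g,
    noiseSpec("gaussian"), seed = 9)
  fid <- toTimeDomain(sy$spectrum)
  ref <- intensity(sy$spectrum)
  rmse <- vapply(c(0.15, 0.4, 0.8), function(f) {
    s <- makeSchedule(g, f, "uniform_random", seed = 31)
    a <- intensity(suppressWarnings(
      csIstReconstruct(subsampleFid(fid, s), g, nIterations = 100)))
    sqrt(mean((a - ref)^2))
  }, 1.0)
  expect_true(all(diff(rmse) < 0))
})

test_that("time-domain regeneration inverts the processing chain", {
  g <- smallGrid2D()
  fid <- simulateFid(sampleSpectrumParams(nPeaks = 3, seed = 7), g)
  sp <- processSpectrum(fid, g)
  # exact route (full quadrature retained)
  fid2 <- toTimeDomain(sp)
  expect_lt(max(abs(fid2 - fid)) / max(abs(fid)), 1e-9)
  sp2 <- processSpectrum(fid2, g)
  expect_lt(max(abs(intensity(sp2) - intensity(sp))) / max(abs(intensity(sp))), 1e-9)
  # all-zero spectrum regenerates an all-zero fid
  z <- newSpectrum(array(0, dim = c(specSize(g), 4L)), g)
  expect_true(all(toTimeDomain(z) == 0))
  # Hilbert route from the absorption part alone (zero-phase signal)
  p0 <- signalParams(c(2, 1), matrix(c(0.1, -0.2, 0.3, 0.05), 2),
                     matrix(c(20, 10, 15, 30), 2))
  f0 <- simulateFid(p0, g)
  spA <- newSpectrum(array(intensity(processSpectrum(f0, g)),
                           dim = c(specSize(g), 1L)), g)
  fidH <- toTimeDomain(spA)
  expect_lt(max(abs(fidH - f0)) / max(abs(f0)), 1e-6)
  g1 <- acqGrid(c(32, 32), zeroFill = 1L)
  expect_error(toTimeDomain(newSpectrum(array(0, c(32, 32, 1)), g1)), "zero-fill")
})

test_that("the Hilbert transform reproduces the analytic dispersion lineshape", {
  # 1D check through the 2D machinery: single decaying peak, phase 0
  g <- acqGrid(c(64, 16))
  p <- signalParams(1, c(0.1, 0), c(12, 1e5))
  sp <- processSpectrum(simulateFid(p, g), g)
  spA <- newSpectrum(array(intensity(sp), dim = c(dim(intensity(sp)), 1L)), g)
  fidH <- toTimeDomain(spA)
  # regenerated sine component against the simulated ground truth
  fid0 <- simulateFid(p, g)
  rms <- sqrt(mean((fidH[, , 2] - fid0[, , 2])^2)) / sqrt(mean(fid0[, , 2]^2))
  expect_lt(rms, 0.01)
})

test_that("schedule files round-trip through the plain-text format", {
  g <- acqGrid(c(16, 16, 16))
  s <- makeSchedule(g, 0.2, "poisson_gap", seed = 6)
  f <- tempfile(fileext = ".txt")
  writeSchedule(s, f)
  s2 <- readSchedule(f, gridPoints = s@gridPoints, fraction = s@fraction,
                     kind = s@kind)
  expect_identical(s2@indices, s@indices)
})
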