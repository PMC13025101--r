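test_that("detectability thresholds reproduce the 2/5/9 sigma triple", {
  cfg <- evalConfig()
  expect_equal(detectabilityThreshold(1, cfg), 2)
  expect_equal(detectabilityThreshold(0.15, cfg), 2 / sqrt(0.15)) # ~5.16
  expect_equal(detectabilityThreshold(0.05, cfg), 2 / sqrt(0.05)) # ~8.94
  expect_equal(round(detectabilityThreshold(0.15, cfg)), 5)
  expect_equal(round(detectabilityThreshold(0.05, cfg)), 9)
  # the literal 2 sigma / fraction form stays available via config
  cfgLin <- evalConfig(nusScaling = "linear")
  expect_equal(detectabilityThreshold(0.1, cfgLin), 20)
  expect_error(detectabilityThreshold(0, cfg), "0, 1")
})

test_that("detectable pixels exclude peaks at or below the threshold", {
  g <- smallGrid2D()
  p <- signalParams(c(1.5, 2, 30), matrix(c(-0.3, 0, 0.3, 0.1, 0.1, 0.1), 3),
                    matrix(30, 3, 2))
  sp <- processSpectrum(simulateFid(p, g), g)
  px <- detectablePixels(p, sp)
  # strict inequality: the 2-sigma peak is excluded, only the 30-sigma one stays
  labOnly3 <- makeLabelMask(signalParams(30, c(0.3, 0.1), c(30, 30)), sp)@data
  expect_equal(nrow(px), sum(labOnly3))
  # at 15% NUS (threshold ~5.2 sigma) nothing survives but the 30-sigma peak
  px15 <- detectablePixels(p, sp, nusFraction = 0.15)
  expect_equal(nrow(px15), sum(labOnly3))
})

test_that("detection scores implement vicinity matching and the F1 formula", {
  a <- array(0, c(20, 20))
  truth <- rbind(c(5L, 5L), c(15L, 15L))
  # perfect: detections exactly on the truth pixels
  a[5, 5] <- 1; a[15, 15] <- 1
  sc <- detectionScores(a, truth, evalConfig(threshold = 0.5))
  expect_equal(c(sc$recall, sc$precision, sc$f1), c(1, 1, 1))
  # one detection 2 px away still matches (radius 2); the other truth missed
  b <- array(0, c(20, 20)); b[7, 5] <- 1
  sc2 <- detectionScores(b, truth, evalConfig(threshold = 0.5))
  expect_equal(sc2$recall, 0.5)
  expect_equal(sc2$precision, 1)
  expect_equal(sc2$f1, 2 * 0.5 * 1 / 1.5)
  # P = 1, R = 1/3 -> F1 = 0.5
  expect_equal(2 * 1 * (1 / 3) / (1 + 1 / 3), 0.5)
  # a detection outside every vicinity costs precision
  cmap <- array(0, c(20, 20)); cmap[5, 5] <- 1; cmap[12, 3] <- 1
  sc3 <- detectionScores(cmap, truth, evalConfig(threshold = 0.5))
  expect_equal(sc3$precision, 0.5)
  # zero denominators flag and score 0
  sc4 <- detectionScores(array(0, c(4, 4)), matrix(integer(0), 0, 2))
  expect_true(sc4$flagged)
  expect_equal(sc4$f1, 0)
})

test_that("Brier/BCE skill scores match the closed forms", {
  # pi = 0.5 -> BS_ref = 0.25
  y <- rep(c(0, 1), 50)
  r <- brierBce(rep(0.5, 100), y)
  expect_equal(r$bsRef, 0.25)
  expect_equal(r$pi, 0.5)
  # perfect predictor: zero scores, unit skills
  rp <- brierBce(y, y)
  expect_equal(rp$bs, 0)
  expect_equal(rp$bss, 1)
  expect_equal(rp$bceSS, 1, tolerance = 1e-6)
  # constant base-rate predictor: BS = BS_ref exactly, zero skill
  y2 <- c(rep(1, 20), rep(0, 80))
  rc <- brierBce(rep(0.2, 100), y2)
  expect_equal(rc$bs, rc$bsRef, tolerance = 1e-12)
  expect_equal(rc$bss, 0, tolerance = 1e-12)
  expect_equal(rc$bceSS, 0, tolerance = 1e-12)
  # bounds: 0 <= BS <= 1, skills <= 1
  set.seed(2)
  pr <- runif(200); yr <- rbinom(200, 1, 0.3)
  rr <- brierBce(pr, yr)
  expect_true(rr$bs >= 0 && rr$bs <= 1 && rr$bss <= 1 && rr$bceSS <= 1)
  # single-class labels: flagged, skills undefined
  rf <- brierBce(rep(0.1, 10), rep(0, 10))
  expect_true(rf$flagged)
  expect_true(is.na(rf$bss))
  # invariance under relabeling of pixel order
  o <- sample.int(200)
  expect_equal(brierBce(pr[o], yr[o])$bs, rr$bs)
})

test_that("calibration curves bin correctly and drop empty bins", {
  # perfectly calibrated draws: observed fraction tracks the predicted mean
  set.seed(4)
  p <- runif(2e4)
  y <- rbinom(2e4, 1, p)
  cc <- calibrationCurve(p, y)
  expect_equal(nrow(cc), 10L)
  se <- sqrt(cc$meanPredicted * (1 - cc$meanPredicted) / cc$count)
  expect_true(all(abs(cc$observedFraction - cc$meanPredicted) <= pmax(3 * se, 0.01)))
  # all labels 1, all probs 1: single bin at (1, 1)
  c1 <- calibrationCurve(rep(1, 5), rep(1, 5))
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$meanPredicted, c1$observedFraction), c(1, 1))
  # empty bins absent
  c2 <- calibrationCurve(c(0.05, 0.95, 0.92), c(0, 1, 1))
  expect_equal(nrow(c2), 2L)
  expect_equal(sum(c2$count), 3L)
})

test_that("overlap scores follow the inverse-square intensity formula", {
  pos <- rbind(c(0, 0), c(4, 0), c(0, 50))
  I <- c(2, 2, 5)
  # isolated peak (only far neighbours): 0
  expect_equal(as.numeric(overlapScore(3, pos, I)), 0)
  # one neighbour, equal intensity, d = 4: 1/16
  expect_equal(as.numeric(overlapScore(1, pos, I)), 1 / 16)
  # two identical neighbours at equal distance double the score
  pos2 <- rbind(c(0, 0), c(4, 0), c(-4, 0))
  expect_equal(as.numeric(overlapScore(1, pos2, c(2, 2, 2))), 2 / 16)
  # coincident peaks are excluded and flagged
  s <- overlapScore(1, rbind(c(0, 0), c(0, 0)), c(1, 1))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "flagged"))
})

test_that("integrated probability is additive over disjoint regions", {
  a <- array(0, c(10, 10))
  a[3, 3] <- 1
  expect_equal(integratedProbability(a, a == 1), 1)
  expect_equal(integratedProbability(a, array(FALSE, c(10, 10))), 0)
  a[7, 7] <- 0.5
  A <- array(FALSE, c(10, 10)); A[1:5, ] <- TRUE
  B <- !A
  expect_equal(integratedProbability(a, A) + integratedProbability(a, B),
               integratedProbability(a, array(TRUE, c(10, 10))))
})
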