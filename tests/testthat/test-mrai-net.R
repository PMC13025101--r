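test_that("the architecture's parameter count matches the closed-form oracle", {
  # closed form: per dimension, 5 gated conv layers (two parallel 10-filter
  # kernel-2 convolutions each); head of gated dense layers 20 and 10 plus
  # one sigmoid unit
  convLayer <- function(cin) 2 * (2 * cin * 10 + 10)
  branch <- convLayer(1) + 4 * convLayer(10)
  countFor <- function(n) n * branch +
    2 * (20 * n * 20 + 20) + 2 * (20 * 10 + 10) + 11
  expect_equal(mraiParameterCount(2L), countFor(2))
  expect_equal(mraiParameterCount(3L), countFor(3))
  expect_equal(nParameters(buildModel(2L)), mraiParameterCount(2L))
  expect_equal(nParameters(buildModel(3L)), mraiParameterCount(3L))
  # the printed "about 8000" for the 3D network
  expect_lt(abs(mraiParameterCount(3L) - 8000), 200)
  # WNN shape arithmetic: 64 halves five times to 2, flattened to 20
  expect_equal(64 / 2^5 * 10, 20)
})

test_that("compiled forward/backward agree with the pure-R reference", {
  set.seed(42)
  N <- 9L
  X <- list(matrix(rnorm(N * 64), N), matrix(rnorm(N * 64), N))
  y <- c(1, 0, 0, 1, 0, 1, 0, 0, 1)
  m <- buildModel(2L, seed = 3)
  pR <- p3nmr:::mraiForward(m@par, X, 2L)$p
  pC <- p3nmr:::.mraiForwardCpp(m@par, X, 2L)
  expect_equal(pC, pR, tolerance = 1e-12)
  fb <- p3nmr:::.mraiFwdBwdCpp(m@par, X, y, 2L)
  fw <- p3nmr:::mraiForward(m@par, X, 2L, cache = TRUE)
  gR <- p3nmr:::mraiBackward(m@par, fw, y, 2L)
  for (k in names(gR))
    expect_equal(as.numeric(fb$grads[[k]]), as.numeric(gR[[k]]), tolerance = 1e-12)
  expect_equal(fb$loss, p3nmr:::bce(pR, y), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  N <- 6L
  X <- list(matrix(rnorm(N * 64), N), matrix(rnorm(N * 64), N))
  y <- c(1, 0, 1, 0, 0, 1)
  m <- buildModel(2L, seed = 11)
  fw <- p3nmr:::mraiForward(m@par, X, 2L, cache = TRUE)
  gr <- p3nmr:::mraiBackward(m@par, fw, y, 2L)
  lossAt <- function(p) p3nmr:::bce(p3nmr:::mraiForward(p, X, 2L)$p, y)
  for (k in c("b1.l1.Wt", "b2.l3.Ws", "b1.l5.bt", "h1.Wt", "h2.bs", "out.w")) {
    i <- 1L
    h <- 1e-5
    p1 <- m@par; p1[[k]][i] <- p1[[k]][i] + h
    p2 <- m@par; p2[[k]][i] <- p2[[k]][i] - h
    fd <- (lossAt(p1) - lossAt(p2)) / (2 * h)
    expect_equal(gr[[k]][i], fd, tolerance = 1e-5)
  }
})

test_that("cross extraction centres the probed point and zero-pads edges", {
  g <- smallGrid2D()
  # constant spectrum: all cross vectors constant (sigma given explicitly);
  # the probed point must sit >= 32 points from the low edge to stay in-grid
  const <- newSpectrum(array(3, dim = c(specSize(g), 1L)), g, sigmaNoise = 1)
  X <- extractCross(const, c(33L, 33L))
  expect_true(all(vapply(X, function(v) all(v == 3), TRUE)))
  # corner point: out-of-grid positions are zero-filled
  Xc <- extractCross(const, c(1L, 1L))
  expect_true(all(Xc[[1]][1:32] == 0))
  expect_true(all(Xc[[1]][33:64] == 3))
  # centre element (0-based 32) is the probed point, the maximum on a peak
  sy <- synthesizeSpectrum(onePeak2D(amp = 50), g, noiseSpec("gaussian"), seed = 1)
  mx <- which(intensity(sy$spectrum) == max(intensity(sy$spectrum)), arr.ind = TRUE)[1, ]
  Xp <- extractCross(sy$spectrum, mx)
  expect_equal(which.max(Xp[[1]]), 33L)
  expect_equal(which.max(Xp[[2]]), 33L)
  # sigma scaling: intensities arrive in sigma units
  expect_equal(max(Xp[[1]]), max(intensity(sy$spectrum)) / sigmaNoise(sy$spectrum))
  noSigma <- newSpectrum(array(0, dim = c(specSize(g), 1L)), g)
  expect_error(extractCross(noSigma, c(5L, 5L)), "sigma")
})

test_that("background resampling keeps positives and the stated class ratio", {
  m <- array(0, dim = c(200, 100))
  m[sample.int(2e4, 100)] <- 1
  mask <- new("LabelMask", data = m)
  rs <- resampleTrainingPoints(mask, ratio = 0.01, seed = 1)
  expect_equal(sum(rs$labels), 100)
  expect_equal(length(rs$labels), 100 + 100 / 0.01) # 100 positives + 1e4 negatives
  expect_equal(rs$negKeepFraction, 1e4 / (2e4 - 100))
  # ratio 1:1 -> equal counts
  rs1 <- resampleTrainingPoints(mask, ratio = 1, seed = 2)
  expect_equal(sum(rs1$labels == 0), 100)
  # negatives never oversampled
  dense <- array(1, dim = c(10, 10)); dense[1:50] <- 0
  rsD <- resampleTrainingPoints(new("LabelMask", data = dense), ratio = 0.01)
  expect_equal(sum(rsD$labels == 0), 50)
  none <- new("LabelMask", data = array(0, dim = c(4, 4)))
  expect_error(resampleTrainingPoints(none), "no positive")
})

test_that("training learns a separable toy problem and reports curves", {
  set.seed(31)
  N <- 1200
  lab <- rbinom(N, 1, 0.5)
  bump <- exp(-((1:64) - 32.5)^2 / 8)
  mk <- function() matrix(rnorm(N * 64, sd = 0.5), N) + outer(lab, bump) * 3
  X <- list(mk(), mk())
  m <- trainModel(buildModel(2L, seed = 3), X, lab,
                  trainConfig(batchSize = 256L, epochs = 40L, patience = 40L,
                              seed = 9))
  acc <- mean((predictProb(m, X) > 0.5) == lab)
  expect_gte(acc, 0.99)
  expect_lte(utils::tail(m@history$val, 1), m@history$val[1])
  # training requires both classes
  expect_error(trainModel(buildModel(2L), X, rep(1, N), trainConfig(epochs = 1)),
               "both classes")
})

test_that("predictions stay in (0,1) and perfect predictions give zero BCE", {
  set.seed(5)
  X <- list(matrix(rnorm(5 * 64), 5), matrix(rnorm(5 * 64), 5))
  p <- predictProb(buildModel(2L, seed = 1), X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p3nmr:::bce(c(0, 1, 1), c(0, 1, 1)), 0, tolerance = 1e-10)
  # constant predictor p = pi scores the base-rate entropy
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(p3nmr:::bce(rep(0.3, 10), y),
               -(0.3 * log(0.3) + 0.7 * log(0.7)), tolerance = 1e-12)
})

test_that("predictMap honours ROIs, bounds, scale invariance and the prior correction", {
  g <- smallGrid2D()
  m <- tinyModel2D()
  sy <- synthesizeSpectrum(onePeak2D(amp = 30), g, noiseSpec("gaussian"), seed = 8)
  p3 <- predictMap(m, sy$spectrum)
  expect_true(all(p3@data >= 0 & p3@data <= 1))
  # ROI restriction: zeros outside, matching values inside
  roi <- array(FALSE, dim = dim(p3@data)); roi[30:40, 30:40] <- TRUE
  p3r <- predictMap(m, sy$spectrum, roiMask = roi)
  expect_true(all(p3r@data[!roi] == 0))
  expect_equal(p3r@data[roi], p3@data[roi])
  # sigma-normalization makes inference invariant to positive rescaling
  spScaled <- sy$spectrum
  spScaled@components <- spScaled@components * 40
  spScaled@sigmaNoise <- sy$spectrum@sigmaNoise * 40
  p3s <- predictMap(m, spScaled)
  expect_equal(p3s@data, p3@data, tolerance = 1e-9)
  # prior correction shrinks probabilities monotonically (beta < 1)
  pU <- predictMap(m, sy$spectrum, priorCorrect = FALSE)
  expect_true(all(p3@data <= pU@data + 1e-12))
  expect_error(predictMap(buildModel(3L), sy$spectrum), "3D")
})

test_that("models round-trip through the checkpoint files", {
  m <- tinyModel2D()
  stem <- file.path(tempdir(), "ckpt")
  writeModel(m, stem)
  m2 <- readModel(stem)
  expect_identical(m2@par, m@par)
  expect_equal(m2@negKeepFraction, m@negKeepFraction)
  X <- list(matrix(0.5, 2, 64), matrix(0.1, 2, 64))
  expect_equal(predictProb(m2, X), predictProb(m, X))
})
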