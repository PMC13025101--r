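# Shared fixtures: small grids, deterministic parameter sets, probability
# oracles standing in for trained models where only engine logic is under
# test, and a lazily trained miniature model cached for the session.

smallGrid2D <- function() acqGrid(c(32L, 32L))
smallGrid3D <- function() acqGrid(c(8L, 8L, 8L))

onePeak2D <- function(amp = 10, omega = c(0.1, -0.2), tau = c(20, 20),
                      phase = c(0, 0)) {
  signalParams(amp, omega, tau, phase)
}

# Probability oracle: "ideal" model that returns the ground-truth label mask
# as probabilities (optionally blurred to a plateau-free bump).
oracleModelFor <- function(labels, peakProb = 0.9) {
  force(labels); force(peakProb)
  function(spectrum) {
    a <- labels@data * peakProb
    # tiny deterministic jitter removes exact plateaus without adding maxima
    a + 1e-6 * array(seq_along(a) %% 7, dim = dim(a)) / 7e5
  }
}

applyP3ModelForTest <- function(model, spectrum) {
  p3nmr:::applyP3Model(model, spectrum)
}

# A miniature trained 2D model (8 spectra, small grid); cached per session.
.fixtureEnv <- new.env(parent = emptyenv())

tinyModel2D <- function() {
  if (!is.null(.fixtureEnv$tiny2d)) return(.fixtureEnv$tiny2d)
  g <- smallGrid2D()
  td <- makeTrainingData(8, g, nPeaks = 24L, targetPoints = 1.5e4, seed = 42)
  m <- trainModel(buildModel(2L, seed = 42), td$X, td$y,
                  trainConfig(lr = 1.5e-3, batchSize = 512L, epochs = 10L,
                              patience = 32L, seed = 42),
                  negKeepFraction = td$negKeepFraction)
  .fixtureEnv$tiny2d <- m
  m
}
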