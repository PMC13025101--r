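# p3nmr

Probabilistic peak detection for multidimensional protein NMR spectra.

Crowded 2D/3D correlation spectra (¹H-¹⁵N HSQC/TROSY, triple-resonance
backbone experiments) are limited by the resolution of the discrete Fourier
transform, by noise, and by peak overlap. `p3nmr` converts the traditional
intensity presentation of a spectrum into a **peak probability
presentation (P³)**: an array on the same grid whose value at each point is
the probability that a peak maximum is located there. The mapping is done
by **MR-Ai**, a compact gated convolutional network (≈8000 parameters for
3D) that looks at each spectral point through a cross-shaped field of view
— one centred 64-point 1D section per dimension — and is trained entirely
on synthetic spectra simulated from the damped complex-exponential signal
model

S(t₁,…,tₙ) = Σⱼ Aⱼ Πₖ exp(−tₖ/τₖⱼ) · exp(i(2π ωₖⱼ tₖ + φₖⱼ)).

Peak lists are produced from P³ maps by **P⁵**, a probability-based peak
picker (local maxima above a cutoff, three-point quadratic sub-pixel
refinement). The package is aimed at method developers and spectroscopists
who want a self-contained, fully synthetic test bed for probabilistic peak
detection, including:

* hypercomplex FID simulation, standard processing (apodization, zero
  filling, FT), ground-truth label masks, skyline projections;
* the three training noise families: Gaussian, Cauchy–Gaussian mixtures
  (NUS-reconstruction residuals), bimodal noise (skyline projections);
* Poisson-gap / uniform NUS schedules, CS-IST compressed-sensing
  reconstruction, exact and Hilbert-based time-domain regeneration;
* the MR-Ai network with training (BCE + Adam, majority-class
  undersampling with exact base-rate correction at prediction time) —
  forward/backward passes implemented in C++ (RcppArmadillo), no deep
  learning framework required;
* 3D inference via regions of interest from skyline-projection
  probabilities, support-spectrum coprocessing, targeted-acquisition
  build-up curves;
* evaluation statistics: recall/precision/F1 with vicinity matching,
  Brier and binary-cross-entropy skill scores, reliability diagrams,
  overlap scores, integrated probability;
* theoretical localization limits: Fisher information / Cramér-Rao lower
  bounds for 2D damped exponentials over all four quadrature channels, and
  Bayesian posterior uncertainties under weak (σ_φ = 30°) and strong
  (σ_φ = 4°) phase priors via an adaptive Metropolis sampler.

See the methods vignette (`vignettes/p3nmr-methods.Rmd`) for the models,
conventions, parameter defaults and design decisions.

## Worked example

Simulate a 2D spectrum with 256 peaks over a 1:200 dynamic range, train a
small model, map it to probabilities, and pick peaks:

```r
library(p3nmr)
g  <- defaultGrid2D()                              # 128 x 64 complex, zf 2

## training corpus: 16 spectra, ~6e4 cross-objectives (small demo)
td <- makeTrainingData(16, g, targetPoints = 6e4, seed = 11)
m  <- trainModel(buildModel(2L, seed = 5), td$X, td$y,
                 trainConfig(lr = 1.5e-3, batchSize = 256, epochs = 16),
                 negKeepFraction = td$negKeepFraction)

## a held-out spectrum with known ground truth
sy <- p3nmr:::makeBenchmarkSpectrum(g, 256, noiseSpec("gaussian"), seed = 999)
p3 <- p3For2D(sy$spectrum, m)
peaks <- pickPeaks(p3, cutoff = 0.5)
head(peaks, 3)
#>         dim1      dim2 seed1 seed2 probability
#> 91  178.0825  85.46391   178    85   0.9109611
#> 73  159.2602  72.60091   159    73   0.9062197
#> 126 164.1008 111.06024   164   111   0.9032678

truth <- detectablePixels(sy$params, sy$spectrum)
unlist(detectionScores(p3, truth)[c("recall", "precision", "f1")])
#>    recall precision        f1
#> 0.6796537 0.9911504 0.8063651
```

Each peak-list row is a sub-pixel position (0-based fractional grid
indices), its integer seed index, and the probability that this point is a
true peak maximum. With the probability cutoff at 50%, this deliberately
small demo model recovers 68% of the theoretically detectable pixels
(ground-truth peaks above 2 sigma-noise) at 99% precision; the bundled
acceptance protocol (64 spectra, ~2e5 training points) does substantially
better. Theoretical context for localization accuracy:

```r
ex <- singlePeakExperiment(snr = 20, g, seed = 7)
crlb(ex$theta, ex$sigmaT, g)$freqPixels   # lower bound, in pixels
#>            [,1]       [,2]
#> [1,] 0.08560338 0.06733722
```

## Acceptance script

`scripts/acceptance.R` retrains the reduced-scale 2D model from scratch and
recomputes the package's headline numbers — held-out probability
calibration (skill scores), the spread of P⁵ localization errors relative
to the strong-prior Bayesian optimum at SNR 10, and the mean single-peak
frequency CRLB at SNR 20 — writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run takes ~15 minutes on one CPU.
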