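# Shared fixtures, built in code and memoised per test file.

.fx <- new.env(parent = emptyenv())

fxProbe <- function() ProbeModel()

fxCopper <- function() copperSpecies()

fxMuB <- function() qprmConstants()$mu_B_over_h

# small uniform-mask acquisition used by several sweep tests
fxAcq <- function(seed = NA_real_, psfSigma = 0.305 / 2.3548)
  AcquisitionConfig(seed = seed, psfSigma = psfSigma)

fxMaskUniform <- function(C0 = 0.1, n = 12)
  makeMask("uniform", nx = n, ny = n, pixelSize = 0.4, C0 = C0)

# memoised noisy combined + calibration sweeps with FOV spectra
fxSweepSpectra <- function() {
  if (!is.null(.fx$sweepSpectra)) return(.fx$sweepSpectra)
  B <- seq(400, 560, by = 10)
  mask <- fxMaskUniform()
  sw <- simulateFieldSweep(B, mask, fxProbe(), fxCopper(),
                           acq = fxAcq(), seed = 101)
  cal <- simulateFieldSweep(B, mask, fxProbe(), NULL,
                            acq = fxAcq(), seed = 201)
  .fx$sweepSpectra <- list(
    B = B,
    combined = sweepSpectrum(sw),
    calibration = sweepSpectrum(cal))
  .fx$sweepSpectra
}

# noiseless FOV spectra on the same grid (expected-count limit)
fxNoiselessSpectra <- function() {
  if (!is.null(.fx$noiseless)) return(.fx$noiseless)
  B <- seq(400, 560, by = 10)
  mask <- fxMaskUniform()
  acq <- fxAcq()
  sw <- simulateFieldSweep(B, mask, fxProbe(), fxCopper(), acq = acq,
                           noiseless = TRUE)
  cal <- simulateFieldSweep(B, mask, fxProbe(), NULL, acq = acq,
                            noiseless = TRUE)
  .fx$noiseless <- list(B = B, combined = sweepSpectrum(sw),
                        calibration = sweepSpectrum(cal))
  .fx$noiseless
}
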