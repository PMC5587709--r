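# Rate spectra: assembly, calibration subtraction, Lorentzian fits and
# per-pixel g maps.

test_that("spectra convert T1 to rates with propagated uncertainty", {
  s <- buildSpectrum(c(250, 486, 520), c(730e-6, 96e-6, 200e-6),
                     c(60e-6, 1e-6, 5e-6))
  expect_equal(gamma1(s)[fieldB0(s) == 250], 1 / 730e-6, tolerance = 1e-9)
  expect_equal(gamma1(s)[fieldB0(s) == 250], 1370, tolerance = 1e-3)
  expect_equal(gamma1(s)[fieldB0(s) == 486], 10417, tolerance = 1e-4)
  expect_equal(gammaSigma(s)[fieldB0(s) == 486], 1e-6 / 96e-6^2,
               tolerance = 1e-9)
  # a constant-T1 sweep is a flat spectrum
  f <- buildSpectrum(c(1, 2, 3), rep(1e-4, 3), rep(1e-6, 3))
  expect_true(all(gamma1(f) == 1e4))
})

test_that("duplicate fields merge by inverse-variance weighting", {
  s <- buildSpectrum(c(480, 480, 500), c(1e-4, 2e-4, 1e-4),
                     c(1e-6, 4e-6, 1e-6))
  expect_length(fieldB0(s), 2)
  g1 <- 1 / 1e-4; g2 <- 1 / 2e-4
  w1 <- 1 / (1e-6 / 1e-4^2)^2; w2 <- 1 / (4e-6 / 2e-4^2)^2
  expect_equal(gamma1(s)[1], (g1 * w1 + g2 * w2) / (w1 + w2),
               tolerance = 1e-9)
})

test_that("subtracting a spectrum from itself gives exactly zero", {
  s <- fxSweepSpectra()$combined
  d <- subtractCalibration(s, s)
  expect_true(all(gamma1(d) == 0))
  expect_identical(fieldB0(d), fieldB0(s))
})

test_that("calibration subtraction recovers the generator's
           target-only spectrum", {
  nl <- fxNoiselessSpectra()
  d <- subtractCalibration(nl$combined, nl$calibration)
  cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
  truth <- targetSpectrum(fieldB0(d), cu, fxProbe())
  # noiseless FOV rates: agreement limited only by fit/gradient effects
  expect_equal(gamma1(d), truth, tolerance = 0.03)
  # fields outside the calibration range are dropped
  wide <- buildSpectrum(c(fieldB0(nl$combined), 600),
                        c(1 / gamma1(nl$combined), 1e-4),
                        rep(1e-7, length(fieldB0(nl$combined)) + 1))
  d2 <- subtractCalibration(wide, nl$calibration)
  expect_false(600 %in% fieldB0(d2))
  shifted <- buildSpectrum(fieldB0(nl$combined) + 500,
                           1 / gamma1(nl$combined),
                           rep(1e-7, length(fieldB0(nl$combined))))
  expect_error(subtractCalibration(shifted, nl$calibration), "overlap")
})

test_that("the intrinsic spectrum fit recovers centre, width and g", {
  probe <- fxProbe()
  mask <- fxMaskUniform(0)
  # dense sampling over the narrow surface-spin peak, no gradient
  acq <- AcquisitionConfig(fieldGradient = c(0, 0))
  B <- sort(c(seq(495, 527, 2), seq(507.5, 515, 0.5)))
  cal <- simulateFieldSweep(B, mask, probe, NULL, acq = acq,
                            noiseless = TRUE)
  fit <- fitIntrinsic(sweepSpectrum(cal), probe)
  expect_true(fit$converged)
  expect_equal(fit$center, 511.3, tolerance = 1e-4)
  expect_equal(fit$halfWidthOmega, 60.4e6, tolerance = 0.02)
  expect_equal(fit$g, 2.0077, tolerance = 0.001)
  expect_equal(fit$g, 2.01, tolerance = 0.02 / 2.01)
})

test_that("a flat spectrum fits with zero Lorentzian amplitude", {
  s <- buildSpectrum(seq(480, 520, 5), rep(5e-4, 9), rep(5e-6, 9))
  fit <- fitIntrinsic(s)
  expect_true(fit$converged)
  expect_identical(fit$amplitude, 0)
  expect_equal(fit$base, 2000, tolerance = 1e-9)
})

test_that("noiseless target spectra round-trip their parameters
           exactly", {
  probe <- fxProbe()
  cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
  B <- seq(400, 576, 8)
  sp <- buildSpectrum(B, 1 / targetSpectrum(B, cu, probe),
                      rep(1e-9, length(B)))
  fit <- fitTargetSpectrum(sp, probe, concentration = 0.1)
  expect_true(fit@converged)
  expect_equal(fit@gFit, cu@gIso, tolerance = 1e-6)
  expect_equal(fit@RFit, cu@RRelax, tolerance = 1e-6)
  expect_equal(fit@b2Fit, cu@couplingB2, tolerance = 1e-6)
  expect_equal(fit@hProbeFit, probe@hProbe, tolerance = 1e-6)
  # the reported resonance field satisfies the g relation exactly
  expect_equal(gFromResonanceField(fit@BRes, probe), fit@gFit,
               tolerance = 1e-9)
})

test_that("target fits on noisy subtracted sweeps recover the
           generator parameters", {
  sx <- fxSweepSpectra()
  d <- subtractCalibration(sx$combined, sx$calibration)
  fit <- fitTargetSpectrum(d, fxProbe(), concentration = 0.1)
  expect_true(fit@converged)
  expect_equal(fit@gFit, 2.1993, tolerance = 0.01 / 2.2)
  expect_equal(fit@RFit, 1.8e9, tolerance = 0.1)
  expect_equal(fit@hProbeFit, 6.7e-9, tolerance = 0.1)
  expect_equal(fit@BRes, 486, tolerance = 0.01)   # printed 486 +/- 1 G
})

test_that("a peak at the field-range edge triggers a warning", {
  probe <- fxProbe()
  cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
  B <- seq(500, 576, 8)   # peak at 488 G lies outside
  sp <- buildSpectrum(B, 1 / targetSpectrum(B, cu, probe),
                      rep(1e-9, length(B)))
  expect_warning(fitTargetSpectrum(sp, probe), "edge")
})

test_that("per-pixel g maps centre on the species g with small
           spread", {
  probe <- fxProbe(); cu <- fxCopper()
  mask <- makeMask("uniform", nx = 8, ny = 8, pixelSize = 0.4, C0 = 0.1)
  acq <- fxAcq()
  B <- seq(410, 570, 12)
  sw <- simulateFieldSweep(B, mask, probe, cu, acq = acq, seed = 31)
  cal <- simulateFieldSweep(B, mask, probe, NULL, acq = acq, seed = 32)
  maps <- lapply(sw, fitT1Map)
  sI <- sweepSpectrum(cal)
  sT <- subtractCalibration(sweepSpectrum(sw), sI)
  fov <- fitTargetSpectrum(sT, probe)
  gm <- perPixelGMap(maps, calibration = sI, probe = probe,
                     RShared = fov@RFit)
  expect_gt(gm$n, 50)
  expect_equal(gm$mean, 2.1993, tolerance = 0.01 / 2.2)
  expect_lt(gm$sd, 0.03)
})
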