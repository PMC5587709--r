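# Generator behaviour: masks, ground truth, shot noise, determinism
# and the redox integrator.

test_that("grating masks have the requested geometry", {
  m <- makeMask("grating", nx = 60, ny = 16, pixelSize = 0.1, C0 = 0.1,
                width = 0.5, pitch = 1.0)
  conc <- concentrationMap(m)
  # columns alternate 5 on / 5 off at 0.1 um pixels
  expect_identical(unname(conc[1, 1:12] > 0),
                   rep(c(TRUE, FALSE), each = 5)[c(1:10, 1:2)])
  # occupied fraction = width/pitch within one pixel column
  expect_equal(mean(conc > 0), 0.5, tolerance = 1 / 60)
  expect_true(all(conc %in% c(0, 0.1)))
  expect_error(makeMask("grating", width = 1, pitch = 0.5), "pitch")
})

test_that("uniform masks fill the field of view", {
  expect_true(all(concentrationMap(fxMaskUniform(0.1)) == 0.1))
  expect_true(all(concentrationMap(fxMaskUniform(0)) == 0))
  expect_error(makeMask("uniform", nx = 4, ny = 4), "8x8")
})

test_that("letter masks render a nonempty binary pattern", {
  m <- makeMask("letters", nx = 64, ny = 32, pixelSize = 0.2, C0 = 0.05,
                text = "CU")
  conc <- concentrationMap(m)
  expect_gt(mean(conc > 0), 0.02)
  expect_lt(mean(conc > 0), 0.6)
  expect_true(all(conc %in% c(0, 0.05)))
})

test_that("truth maps decompose the rate into base, intrinsic and
           target parts", {
  probe <- fxProbe(); cu <- fxCopper()
  # zero concentration: target term identically zero
  tr0 <- truthFromMask(fxMaskUniform(0), probe, cu, B0 = 486)
  expect_true(all(tr0@gammaTarget == 0))
  expect_equal(1 / tr0@T1, tr0@gammaBase + tr0@gammaIntrinsic,
               tolerance = 1e-12)
  # far off resonance the T1 sits at the printed ~730 us base scale
  # (the distant Lorentzian tails still contribute a few percent)
  trOff <- truthFromMask(fxMaskUniform(0.1), probe, cu, B0 = 250)
  expect_equal(median(t1Values(trOff)), 730e-6, tolerance = 0.15)
  # with no target at all the base rate is recovered almost exactly
  trCal <- truthFromMask(fxMaskUniform(0.1), probe, NULL, B0 = 250)
  expect_equal(median(t1Values(trCal)), 730e-6, tolerance = 1e-3)
  # doubling the concentration doubles the target term exactly
  tr1 <- truthFromMask(fxMaskUniform(0.1), probe, cu, B0 = 486)
  tr2 <- truthFromMask(fxMaskUniform(0.2), probe, cu, B0 = 486)
  expect_equal(tr2@gammaTarget, 2 * tr1@gammaTarget, tolerance = 1e-12)
})

test_that("a linear field gradient perturbs the per-pixel field", {
  tr <- truthFromMask(fxMaskUniform(0.1), fxProbe(), fxCopper(),
                      B0 = 500, fieldGradient = c(0.001, 0.004))
  expect_equal(max(tr@B0map) - min(tr@B0map),
               500 * (0.001 + 0.004), tolerance = 1e-9)
  expect_equal(mean(tr@B0map), 500, tolerance = 1e-9)
})

test_that("noiseless stacks reproduce the stretched exponential", {
  probe <- fxProbe(); cu <- fxCopper()
  tr <- truthFromMask(fxMaskUniform(0.1), probe, cu, B0 = 486)
  acq <- fxAcq(psfSigma = 0)
  st <- simulateDecayStack(tr, acq, noiseless = TRUE)
  i <- 3; j <- 7
  expected <- acq@nCycles * acq@photonsPerCycle *
    ((1 - tr@contrast) +
       tr@contrast * exp(-(tauGrid(st) / tr@T1[i, j])^tr@p[i, j]))
  expect_equal(frames(st)[i, j, ], expected, tolerance = 1e-3)
})

test_that("shot noise is Poisson: variance over mean near one", {
  tr <- truthFromMask(fxMaskUniform(0.1), fxProbe(), fxCopper(),
                      B0 = 486)
  # few cycles and photons keep counts small enough that the Poisson
  # variance is measurable over replicates
  acq <- AcquisitionConfig(tauGrid = tauGridDefault(5), nCycles = 1,
                           photonsPerCycle = 50, psfSigma = 0)
  draws <- sapply(1:120, function(s)
    frames(simulateDecayStack(tr, acq, seed = s))[1:6, 1:6, 1])
  vm <- apply(draws, 1, var) / rowMeans(draws)
  expect_equal(mean(vm), 1, tolerance = 0.05)
})

test_that("identical seeds give bit-identical stacks", {
  tr <- truthFromMask(fxMaskUniform(0.1), fxProbe(), fxCopper(),
                      B0 = 486)
  a <- simulateDecayStack(tr, fxAcq(), seed = 7)
  b <- simulateDecayStack(tr, fxAcq(), seed = 7)
  d <- simulateDecayStack(tr, fxAcq(), seed = 8)
  expect_identical(frames(a), frames(b))
  expect_false(identical(frames(a), frames(d)))
})

test_that("PSF blur conserves total expected intensity", {
  tr <- truthFromMask(
    makeMask("grating", nx = 40, ny = 16, pixelSize = 0.1, C0 = 0.1),
    fxProbe(), fxCopper(), B0 = 486)
  sharp <- simulateDecayStack(tr, fxAcq(psfSigma = 0), noiseless = TRUE)
  blurred <- simulateDecayStack(tr, fxAcq(psfSigma = 0.2),
                                noiseless = TRUE)
  for (k in c(1, 5, 10))
    expect_equal(sum(frames(blurred)[, , k]), sum(frames(sharp)[, , k]),
                 tolerance = 1e-6)
})

test_that("without blur a grating truth gives pixel-sharp contrast
           edges", {
  mask <- makeMask("grating", nx = 40, ny = 16, pixelSize = 0.1,
                   C0 = 0.1)
  tr <- truthFromMask(mask, fxProbe(), fxCopper(),
                      B0 = resonanceField(fxCopper()@gIso))
  st <- simulateDecayStack(tr, fxAcq(psfSigma = 0), noiseless = TRUE)
  ci <- singleTauContrast(st, tauGrid(st)[12])
  # exactly two distinct levels, aligned with the mask columns
  row <- round(ci[8, ], 9)
  lv <- sort(unique(row))
  expect_length(lv, 2)
  expect_true(all((row == lv[1]) == (concentrationMap(mask)[8, ] > 0)))
})

test_that("field sweeps are reproducible and off-resonance fields see
           only the intrinsic background", {
  mask <- fxMaskUniform(0.1)
  sw1 <- simulateFieldSweep(c(250, 486), mask, acq = fxAcq(), seed = 3)
  sw2 <- simulateFieldSweep(c(250, 486), mask, acq = fxAcq(), seed = 3)
  expect_identical(frames(sw1[[1]]), frames(sw2[[1]]))
  # far off resonance the fitted rate matches the target-free rate
  agg <- roiAggregate(sw1[[1]])
  fOff <- fitDecay(agg$tau, agg$counts)
  expect_equal(fOff$T1, 730e-6, tolerance = 0.15)
  expect_error(simulateFieldSweep(numeric(0), mask), "nonempty")
})

test_that("redox integrator conserves copper mass and matches the
           configured time course", {
  cfg <- RedoxConfig()
  t <- seq(0, 4000, by = 4)
  sol <- solveRedoxODE(t, cfg)
  # mass balance on copper is exact by construction
  expect_equal(sol$cu2 + sol$cu1, rep(cfg@cu0, length(t)),
               tolerance = 1e-9)
  # AH2 only decreases
  expect_true(all(diff(sol$ah2) <= 1e-12))
  # the default scenario: ~60% reduced at 500 s, recovered by 4000 s
  expect_equal(1 - sol$cu2[t == 500] / cfg@cu0, 0.60, tolerance = 0.05)
  expect_gt(sol$cu2[length(t)] / cfg@cu0, 0.95)
})

test_that("kF = 0 gives a constant intensity trace up to noise", {
  tr <- simulateKinetics(RedoxConfig(kF = 0), seed = 5)
  y <- tr@ISp / tr@IRef
  half1 <- mean(y[seq_len(length(y) %/% 2)])
  half2 <- mean(y[-seq_len(length(y) %/% 2)])
  expect_equal(half1, half2, tolerance = 1e-3)
  expect_true(all(tr@truth$cu == tr@truth$cu[1]))
})

test_that("kinetics traces are seeded and carry their truth", {
  a <- simulateKinetics(seed = 9)
  b <- simulateKinetics(seed = 9)
  expect_identical(a@ISp, b@ISp)
  expect_named(a@truth, c("cu", "gammaCu", "gammaTot", "ySp", "redox",
                          "tauSp", "gammaBackground", "hProbe", "Gamma2",
                          "RRelax", "contrast"))
  # reduction of the spin-active pool raises the probe-point intensity
  y <- a@ISp / a@IRef
  base <- y[a@t <= 60]
  dip <- y[a@t > 260 & a@t < 660]
  expect_gt(mean(dip), mean(base))
})
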