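# Stretched-exponential fitting, T1 maps, ROI aggregation and
# single-tau contrast.

test_that("zero-noise decays round-trip exactly over the parameter
           range", {
  tau <- tauGridDefault()
  cases <- expand.grid(A = c(300, 5000), T1 = c(50e-6, 300e-6, 1e-3),
                       p = c(0.5, 0.8, 1, 1.6), c0 = c(0, 200))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    y <- cs$A * exp(-(tau / cs$T1)^cs$p) + cs$c0
    f <- fitDecay(tau, y)
    expect_true(f$converged)
    expect_equal(f$T1, cs$T1, tolerance = 1e-6)
    expect_equal(f$p, cs$p, tolerance = 1e-6)
    expect_equal(f$A, cs$A, tolerance = 1e-5)
  }
})

test_that("a pure single exponential is fit with p = 1 and the 1/e
           time", {
  tau <- tauGridDefault()
  y <- 800 * exp(-tau / 150e-6) + 50
  f <- fitDecay(tau, y)
  expect_equal(f$p, 1, tolerance = 1e-6)
  # T1 equals the 1/e time of (y - c)/A
  expect_equal(f$T1, 150e-6, tolerance = 1e-6)
  yn <- (y - f$offset) / f$A
  # linear interpolation on the coarse log grid is only %-accurate
  expect_equal(stats::approx(tau, yn, xout = f$T1)$y, exp(-1),
               tolerance = 0.03)
})

test_that("T1 estimates are invariant to affine count rescaling", {
  tau <- tauGridDefault()
  y <- 1200 * exp(-(tau / 96e-6)^0.8) + 150
  cfg <- FitConfig(weights = "none")
  f1 <- fitDecay(tau, y, cfg)
  f2 <- fitDecay(tau, 3.7 * y + 40, cfg)
  expect_equal(f2$T1, f1$T1, tolerance = 1e-6)
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
  expect_equal(f2$A, 3.7 * f1$A, tolerance = 1e-5)
})

test_that("noisy single-pixel T1 recovery is unbiased at measurement
           scale", {
  probe <- fxProbe()
  tr <- truthFromMask(fxMaskUniform(0.1), probe, fxCopper(), B0 = 486)
  truthT1 <- tr@T1[1, 1]
  acq <- AcquisitionConfig(seed = NA)
  est <- vapply(1:40, function(s) {
    st <- simulateDecayStack(tr, acq, seed = 3000 + s)
    fitDecay(tauGrid(st), frames(st)[1, 1, ])$T1
  }, numeric(1))
  expect_lt(abs(median(est) - truthT1) / truthT1, 0.05)
  expect_lt(stats::sd(est) / truthT1, 0.05)
})

test_that("degenerate and pathological inputs are handled", {
  tau <- tauGridDefault()
  expect_error(fitDecay(tau, rep(5, length(tau))), "constant")
  expect_error(fitDecay(tau[1:3], c(1, 2, 3)), "5")
  # pure noise: returns a flagged result or converges, never throws
  set.seed(1)
  f <- fitDecay(tau, rnorm(length(tau)))
  expect_type(f$converged, "logical")
})

test_that("T1 maps are flat for uniform truth and bimodal for a
           grating", {
  probe <- fxProbe(); cu <- fxCopper()
  acq <- fxAcq(psfSigma = 0)
  trU <- truthFromMask(
    makeMask("uniform", nx = 8, ny = 8, pixelSize = 0.4, C0 = 0.1),
    probe, cu, B0 = 486)
  mapU <- fitT1Map(simulateDecayStack(trU, acq, seed = 11))
  expect_true(all(mapU@converged))
  expect_lt(stats::sd(t1Values(mapU)) / mean(t1Values(mapU)), 0.05)

  # grating: two populations at the on/off ground-truth T1 values
  mask <- makeMask("grating", nx = 10, ny = 8, pixelSize = 0.5, C0 = 0.1,
                   width = 1.5, pitch = 2.5)
  trG <- truthFromMask(mask, probe, cu, B0 = 486)
  mapG <- fitT1Map(simulateDecayStack(trG, acq, seed = 12))
  on <- concentrationMap(mask) > 0
  expect_equal(mean(t1Values(mapG)[on]), mean(t1Values(trG)[on]),
               tolerance = 0.03)
  expect_equal(mean(t1Values(mapG)[!on]), mean(t1Values(trG)[!on]),
               tolerance = 0.03)
  expect_gt(mean(t1Values(mapG)[!on]) / mean(t1Values(mapG)[on]), 2)
})

test_that("binning preserves the mean T1 on high-SNR data", {
  tr <- truthFromMask(fxMaskUniform(0.1), fxProbe(), fxCopper(),
                      B0 = 486)
  st <- simulateDecayStack(tr, fxAcq(psfSigma = 0), seed = 13)
  m1 <- fitT1Map(st, FitConfig(binning = 1))
  m2 <- fitT1Map(st, FitConfig(binning = 2))
  expect_equal(mean(t1Values(m2)), mean(t1Values(m1)), tolerance = 0.01)
})

test_that("ROI aggregation sums counts consistently", {
  tr <- truthFromMask(fxMaskUniform(0.1), fxProbe(), fxCopper(),
                      B0 = 486)
  st <- simulateDecayStack(tr, fxAcq(), seed = 14)
  one <- roiAggregate(st, c(3, 3, 5, 5))
  expect_equal(one$counts, frames(st)[3, 5, ])
  full <- roiAggregate(st)
  expect_equal(full$counts, apply(frames(st), 3, sum))
  expect_error(roiAggregate(st, c(5, 3, 1, 2)), "roi")
  expect_error(roiAggregate(st, c(1, 100, 1, 2)), "roi")
})

test_that("single-tau contrast highlights fast-relaxing regions most
           strongly near tau = T1", {
  probe <- fxProbe(); cu <- fxCopper()
  mask <- makeMask("grating", nx = 10, ny = 8, pixelSize = 0.5, C0 = 0.1,
                   width = 1.5, pitch = 2.5)
  tr <- truthFromMask(mask, probe, cu, B0 = resonanceField(cu@gIso))
  st <- simulateDecayStack(tr, fxAcq(psfSigma = 0), noiseless = TRUE)
  on <- concentrationMap(mask) > 0
  sep <- vapply(tauGrid(st), function(ts) {
    ci <- singleTauContrast(st, ts)
    mean(ci[!on]) - mean(ci[on])
  }, numeric(1))
  tBest <- tauGrid(st)[which.max(sep)]
  # the optimum lies near the on-stripe T1 (coarse log grid: one step)
  expect_lt(abs(log(tBest / mean(tr@T1[on]))), log(3.5))
  # at the shortest tau the contrast image is ~1 everywhere
  ci0 <- singleTauContrast(st, tauGrid(st)[1])
  expect_equal(unname(as.vector(ci0)), rep(1, length(ci0)),
               tolerance = 1e-6)
  # flat truth gives a flat contrast image
  trF <- truthFromMask(fxMaskUniform(0), probe, cu, B0 = 486)
  stF <- simulateDecayStack(trF, fxAcq(psfSigma = 0), noiseless = TRUE)
  ciF <- singleTauContrast(stF, tauGrid(stF)[10])
  expect_lt(stats::sd(ciF) / mean(ciF), 1e-6)
})

test_that("the probe time for single-tau imaging is the FOV T1", {
  expect_identical(chooseTauSp(96e-6), 96e-6)
  expect_identical(chooseTauSp(124e-6), 124e-6)
  expect_error(chooseTauSp(0), "positive")
})
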