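# Closed-form spin physics: g-factor algebra, resonance geometry, the
# probe filter function and the Lorentzian target spectrum.

test_that("motional averaging of an axial g-tensor", {
  # hexaaqua-Cu2+ literature tensor -> isotropic 2.199
  expect_equal(motionalAverageG(2.400, 2.099), 2.199333, tolerance = 1e-6)
  expect_equal(signif(motionalAverageG(2.400, 2.099), 4), 2.199)
  # an isotropic tensor is a fixed point
  expect_identical(motionalAverageG(2.1, 2.1), 2.1)
  # direct arithmetic
  expect_equal(motionalAverageG(2.4, 2.0), (2.4 + 2 * 2.0) / 3,
               tolerance = 1e-12)
  expect_error(motionalAverageG(-1, 2), "positive")
})

test_that("NV transition frequencies follow the linear Zeeman law", {
  expect_equal(nvTransitionFreq(0, -1), 2.87e9)
  gammaNV <- 2.0028 * fxMuB()
  expect_equal(nvTransitionFreq(100, +1), 2.87e9 + 100 * gammaNV)
  expect_equal(nvTransitionFreq(512, -1), 2.87e9 - 512 * gammaNV,
               tolerance = 1e-12)
  expect_equal(nvTransitionFreq(512, -1) / 1e9, 1.4347, tolerance = 1e-4)
  expect_error(nvTransitionFreq(1500, -1), "1024")
  expect_error(nvTransitionFreq(-1, -1), "1024")
})

test_that("resonance fields for free electrons and Cu2+", {
  # free-electron crossing at 512 G
  expect_equal(resonanceField(2.0023), 512, tolerance = 1e-3)
  # Cu2+ crossing: printed as ~487 G, closed form within 0.3%
  Bcu <- resonanceField(motionalAverageG(2.400, 2.099))
  expect_lt(abs(Bcu - 487) / 487, 0.003)
})

test_that("resonance field and g inversion are exact inverses", {
  for (g in seq(1.5, 4, by = 0.25)) {
    B <- resonanceField(g)
    expect_equal(gFromResonanceField(B), g, tolerance = 1e-9)
  }
  # symmetric crossing: B = hD/(2 gNV muB) maps back to gNV itself
  p <- fxProbe()
  Bsym <- p@D / (2 * p@gNV * fxMuB())
  expect_equal(gFromResonanceField(Bsym), p@gNV, tolerance = 1e-12)
  expect_error(gFromResonanceField(0), "positive")
})

test_that("printed peak fields invert to the printed g-factors", {
  # Cu2+ absorption peak at 486 G -> g = 2.21 +/- 0.02
  expect_equal(gFromResonanceField(486), 2.21, tolerance = 0.02 / 2.21)
  # surface-spin calibration peak at 511.3 G -> g = 2.01 +/- 0.02
  expect_equal(gFromResonanceField(511.3), 2.01, tolerance = 0.02 / 2.01)
})

test_that("filter function has Lorentzian shape and exact area", {
  p <- fxProbe()
  b2 <- 3e12
  wNV <- 2 * pi * (p@D - p@gNV * fxMuB() * 480)
  peak <- filterFunction(wNV, 480, b2, p@Gamma2)
  expect_equal(peak, b2 / (2 * p@Gamma2))
  # half maximum one linewidth off resonance
  expect_equal(filterFunction(wNV + p@Gamma2, 480, b2, p@Gamma2),
               peak / 2)
  expect_equal(filterFunction(wNV - p@Gamma2, 480, b2, p@Gamma2),
               peak / 2)
  # quadrature equals pi b^2 / 2 (integrate in units of the linewidth)
  area <- p@Gamma2 * stats::integrate(
    function(u) filterFunction(wNV + p@Gamma2 * u, 480, b2, p@Gamma2),
    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(area, pi * b2 / 2, tolerance = 1e-6)
  expect_error(filterFunction(1, 480, b2, Gamma2 = -1), "positive")
})

test_that("target spectrum peaks at the resonance field with the
           closed-form height and width", {
  p <- fxProbe()
  cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
  Bres <- resonanceField(cu@gIso)
  W <- p@Gamma2 + cu@RRelax
  expect_equal(targetSpectrum(Bres, cu, p), cu@couplingB2 / (2 * W))
  # numeric scan: maximum at the resonance field
  B <- seq(400, 576, by = 0.05)
  s <- targetSpectrum(B, cu, p)
  expect_lt(abs(B[which.max(s)] - Bres), 0.05)
  expect_true(all(s > 0))
  # symmetry about the peak
  expect_equal(targetSpectrum(Bres + 30, cu, p),
               targetSpectrum(Bres - 30, cu, p), tolerance = 1e-12)
  # half-height crossings sit (Gamma2+R)/(gammaNV+gammaCu) off peak
  gammaSum <- gyromagneticRatio(p@gNV) + gyromagneticRatio(cu@gIso)
  dBhalf <- W / gammaSum
  expect_equal(dBhalf, 49, tolerance = 0.02)   # ~49 G at W = 1.825e9
  half <- max(s) / 2
  crossings <- B[abs(s - half) < 0.002 * max(s)]
  expect_equal(max(crossings) - Bres, dBhalf, tolerance = 0.01)
})

test_that("closed form equals the numerical filter-bath convolution", {
  # the spectrum model is the convolution of the probe filter with a
  # unit-area Lorentzian bath spectral density; widths add exactly
  p <- fxProbe()
  cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
  gCu <- gyromagneticRatio(cu@gIso)
  R <- cu@RRelax
  B <- seq(410, 570, by = 16)
  num <- vapply(B, function(b) {
    wT <- gCu * b
    R * stats::integrate(function(u)
      filterFunction(wT + R * u, b, cu@couplingB2, p@Gamma2) *
        (1 / pi) / (R * (1 + u^2)),
      -Inf, Inf, rel.tol = 1e-11)$value
  }, numeric(1))
  expect_equal(num, targetSpectrum(B, cu, p), tolerance = 1e-8)
})

test_that("coupling-concentration relation is linear and consistent", {
  b2 <- couplingFromConcentration(0.1)
  expect_equal(couplingFromConcentration(0.2), 2 * b2)
  # on-resonance rate from the coupling inverts to the concentration
  p <- fxProbe()
  cu <- copperSpecies(couplingB2 = b2)
  gOn <- targetSpectrum(resonanceField(cu@gIso), cu, p)
  expect_equal(concentrationFromRate(gOn, p@hProbe, p@Gamma2, cu@RRelax),
               0.1, tolerance = 1e-12)
})
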