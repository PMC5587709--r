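# Relaxation-rate spectra: assembly from T1 fits, calibration
# subtraction, Lorentzian model fits and per-pixel g-factor maps.

#' Assemble a relaxation-rate spectrum from T1 fits
#'
#' Gamma1 = 1/T1 with uncertainty propagated as sigma_Gamma =
#' sigma_T1 / T1^2. Duplicate fields are merged by inverse-variance
#' weighting; fields are sorted ascending.
#'
#' @param B0 applied fields, G.
#' @param T1 fitted T1 values, s.
#' @param sigmaT1 standard errors of T1, s.
#' @param provenance `"FOV"`, `"ROI"` or `"pixel(i,j)"`.
#' @return A [RateSpectrum-class].
#' @examples
#' buildSpectrum(c(250, 486), c(730e-6, 96e-6), c(60e-6, 1e-6))
#' @export
buildSpectrum <- function(B0, T1, sigmaT1, provenance = "FOV") {
  keep <- is.finite(B0) & is.finite(T1) & is.finite(sigmaT1) & T1 > 0
  B0 <- B0[keep]; T1 <- T1[keep]; sigmaT1 <- sigmaT1[keep]
  if (length(B0) < 3) stop("need at least 3 fields with converged fits")
  G <- 1 / T1
  sG <- sigmaT1 / T1^2
  sG[sG <= 0] <- min(sG[sG > 0], 1e-12)
  o <- order(B0)
  B0 <- B0[o]; G <- G[o]; sG <- sG[o]
  if (anyDuplicated(B0)) {
    w <- 1 / sG^2
    Gm <- tapply(G * w, B0, sum) / tapply(w, B0, sum)
    sGm <- sqrt(1 / tapply(w, B0, sum))
    B0 <- as.numeric(names(Gm)); G <- as.numeric(Gm); sG <- as.numeric(sGm)
  }
  new("RateSpectrum", B0 = B0, Gamma1 = G, sigma = sG,
      provenance = provenance)
}

#' Field-of-view (or ROI) spectrum from a field sweep
#'
#' Fits the summed decay curve of each stack and assembles the
#' resulting rates into a [RateSpectrum-class].
#'
#' @param stacks list of [DecayStack-class] (one per field).
#' @param cfg a [FitConfig-class].
#' @param roi optional ROI `c(row0, row1, col0, col1)` passed to
#'   [roiAggregate()].
#' @return A [RateSpectrum-class].
#' @export
sweepSpectrum <- function(stacks, cfg = FitConfig(), roi = NULL) {
  B0 <- vapply(stacks, function(s) s@B0, numeric(1))
  fits <- lapply(stacks, function(s) {
    agg <- roiAggregate(s, roi)
    fitDecay(agg$tau, agg$counts, cfg)
  })
  buildSpectrum(B0,
                vapply(fits, `[[`, numeric(1), "T1"),
                vapply(fits, `[[`, numeric(1), "sigmaT1"),
                provenance = if (is.null(roi)) "FOV" else "ROI")
}

#' Subtract a calibration spectrum
#'
#' The target spectrum is the combined (intrinsic + target) spectrum
#' minus the calibration (intrinsic-only) spectrum, with the
#' calibration linearly interpolated onto the combined field grid (no
#' extrapolation: combined fields outside the calibration range are
#' dropped) and variances added.
#'
#' @param combined [RateSpectrum-class] with the target present.
#' @param calibration [RateSpectrum-class] without the target.
#' @return A [RateSpectrum-class] of the target-only rates (may contain
#'   negative values within noise).
#' @export
subtractCalibration <- function(combined, calibration) {
  lo <- min(calibration@B0); hi <- max(calibration@B0)
  keep <- combined@B0 >= lo & combined@B0 <= hi
  if (!any(keep))
    stop("no overlap between combined and calibration field ranges")
  B <- combined@B0[keep]
  calG <- stats::approx(calibration@B0, calibration@Gamma1, xout = B)$y
  calS <- stats::approx(calibration@B0, calibration@sigma, xout = B)$y
  new("RateSpectrum", B0 = B,
      Gamma1 = combined@Gamma1[keep] - calG,
      sigma = sqrt(combined@sigma[keep]^2 + calS^2),
      provenance = combined@provenance)
}

#' Fit the intrinsic (calibration) spectrum
#'
#' Single Lorentzian in field with a constant baseline:
#' Gamma1(B) = base + amp * hw^2 / (hw^2 + (B - Bc)^2). The half-width
#' is also reported in angular-frequency units through the combined
#' gyromagnetic slope (gamma_NV + gamma_e), and the centre as a
#' g-factor through the resonance relation.
#'
#' @param calibration a [RateSpectrum-class] (>= 5 points).
#' @param probe a [ProbeModel-class].
#' @param gElectron g-factor used for the field-to-frequency slope.
#' @param const physical constants.
#' @return list with `center` (G), `halfWidthField` (G),
#'   `halfWidthOmega` (rad s^-1), `amplitude` (s^-1), `base` (s^-1),
#'   `g` (from the centre), `se` (named), `converged`.
#' @export
fitIntrinsic <- function(calibration, probe = ProbeModel(),
                         gElectron = 2.0023, const = qprmConstants()) {
  B <- calibration@B0; G <- calibration@Gamma1
  if (length(B) < 5) stop("need at least 5 spectrum points")
  w <- 1 / calibration@sigma^2
  ipk <- which.max(G)
  # a spectrum with no structure above noise has zero Lorentzian
  # amplitude; centre and width are then unidentifiable
  if (diff(range(G)) < 3 * stats::median(calibration@sigma)) {
    base <- sum(G * w) / sum(w)
    return(list(center = NA_real_, halfWidthField = NA_real_,
                halfWidthOmega = NA_real_, amplitude = 0, base = base,
                g = NA_real_, se = numeric(0), converged = TRUE))
  }
  base0 <- stats::quantile(G, 0.1, names = FALSE)
  amp0 <- max(G[ipk] - base0, .Machine$double.eps)
  hw0 <- max(diff(B)[1], .halfWidthGuess(B, G, base0))
  fit <- .tryNls(G ~ base + amp * hw^2 / (hw^2 + (B - Bc)^2),
                 data = list(B = B, G = G),
                 start = list(base = base0, amp = amp0, hw = hw0,
                              Bc = B[ipk]),
                 lower = c(base = -Inf, amp = 0, hw = 1e-6, Bc = min(B)),
                 upper = c(base = Inf, amp = Inf, hw = diff(range(B)) * 10,
                           Bc = max(B)),
                 weights = w, maxiter = 200)
  if (is.null(fit))
    return(list(center = NA_real_, halfWidthField = NA_real_,
                halfWidthOmega = NA_real_, amplitude = NA_real_,
                base = NA_real_, g = NA_real_, se = numeric(0),
                converged = FALSE))
  co <- stats::coef(fit)
  slope <- gyromagneticRatio(probe@gNV, const = const) +
    gyromagneticRatio(gElectron, const = const)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(co)), names(co)))
  list(center = unname(co[["Bc"]]),
       halfWidthField = unname(co[["hw"]]),
       halfWidthOmega = unname(co[["hw"]]) * slope,
       amplitude = unname(co[["amp"]]), base = unname(co[["base"]]),
       g = gFromResonanceField(unname(co[["Bc"]]), probe, const),
       se = se, converged = TRUE)
}

.halfWidthGuess <- function(B, G, base) {
  pk <- max(G) - base
  above <- B[G - base > pk / 2]
  if (length(above) < 2) return(diff(range(B)) / 10)
  diff(range(above)) / 2
}

#' Fit the closed-form target spectrum
#'
#' Weighted least-squares fit of the Lorentzian target model (see
#' [targetSpectrum()]) with free squared coupling b2, fluctuation rate
#' R and g-factor; the probe Gamma2 is held fixed since only the sum
#' Gamma2 + R enters the lineshape. When the analyte concentration is
#' known the probe depth is recovered from the fitted coupling through
#' b2 = 2C/(4.35e10 h^3) (order-of-magnitude convention; see the
#' methods vignette).
#'
#' @param spectrum a target [RateSpectrum-class] (>= 7 points spanning
#'   the peak).
#' @param probe a [ProbeModel-class] (supplies Gamma2).
#' @param concentration analyte concentration, mol L^-1, or NULL.
#' @param const physical constants.
#' @return A [SpectrumFit-class].
#' @export
fitTargetSpectrum <- function(spectrum, probe = ProbeModel(),
                              concentration = NULL,
                              const = qprmConstants()) {
  B <- spectrum@B0; G <- spectrum@Gamma1
  if (length(B) < 7) stop("need at least 7 spectrum points")
  wts <- 1 / spectrum@sigma^2
  ipk <- which.max(G)
  if (ipk == 1 || ipk == length(B))
    warning("spectrum peak lies at the edge of the field range; ",
            "fit may extrapolate")
  g0 <- gFromResonanceField(B[ipk], probe, const)
  gNVr <- gyromagneticRatio(probe@gNV, const = const)
  slope0 <- gNVr + gyromagneticRatio(g0, const = const)
  hwB <- .halfWidthGuess(B, G, 0)
  W0 <- max(hwB * slope0, 2 * probe@Gamma2)
  R0 <- max(W0 - probe@Gamma2, 1e6)
  b20 <- max(G[ipk], .Machine$double.eps) * 2 * W0
  D2pi <- 2 * pi * probe@D
  muB <- const$mu_B_over_h

  fit <- .tryNls(
    G ~ (b2 / 2) * (G2 + R) /
      ((G2 + R)^2 + (D2pi - (gNVr + 2 * pi * g * muB) * B)^2),
    data = list(B = B, G = G, G2 = probe@Gamma2, D2pi = D2pi,
                gNVr = gNVr, muB = muB),
    start = list(b2 = b20, R = R0, g = g0),
    lower = c(b2 = 0, R = 0, g = 1.01),
    upper = c(b2 = Inf, R = Inf, g = 9.99),
    weights = wts, maxiter = 500)
  if (is.null(fit))
    return(new("SpectrumFit", gFit = NA_real_, RFit = NA_real_,
               b2Fit = NA_real_, hProbeFit = NA_real_, BRes = NA_real_,
               se = numeric(0), cov = matrix(NA_real_, 0, 0),
               converged = FALSE))
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit),
                 error = function(e) matrix(NA_real_, 3, 3))
  se <- stats::setNames(sqrt(abs(diag(vc))), names(co))
  h <- NA_real_
  if (!is.null(concentration)) {
    h <- (2 * concentration / (.EQ4_CONST * co[["b2"]]))^(1 / 3)
    se <- c(se, hProbe = unname(h / 3 * se[["b2"]] / co[["b2"]]))
  }
  new("SpectrumFit", gFit = unname(co[["g"]]), RFit = unname(co[["R"]]),
      b2Fit = unname(co[["b2"]]), hProbeFit = unname(h),
      BRes = resonanceField(unname(co[["g"]]), probe, const),
      se = se, cov = vc, converged = TRUE)
}

#' Per-pixel g-factor map and histogram
#'
#' For each pixel of a sweep of T1 maps, assembles the pixel's rate
#' spectrum, subtracts the (FOV) calibration spectrum, and fits the
#' target model with only the g-factor and amplitude free: the
#' linewidth is shared from the FOV fit to stabilise low-SNR pixels.
#' Pixels whose fit fails or whose peak is unresolvable are flagged and
#' excluded from the summary statistics.
#'
#' @param maps list of [T1Map-class] (one per field, same geometry).
#' @param calibration FOV calibration [RateSpectrum-class], or NULL if
#'   the maps already describe a target-only rate.
#' @param probe a [ProbeModel-class].
#' @param RShared shared fluctuation rate, rad s^-1 (e.g. `RFit` from
#'   the FOV [fitTargetSpectrum()]).
#' @param const physical constants.
#' @return list with `g` (matrix), `converged` (matrix), `mean`, `sd`
#'   and `n` over converged pixels.
#' @export
perPixelGMap <- function(maps, calibration = NULL, probe = ProbeModel(),
                         RShared, const = qprmConstants()) {
  B0 <- vapply(maps, fieldB0, numeric(1))
  o <- order(B0); B0 <- B0[o]; maps <- maps[o]
  ny <- nrow(maps[[1]]@T1); nx <- ncol(maps[[1]]@T1)
  gmap <- matrix(NA_real_, ny, nx)
  okmap <- matrix(FALSE, ny, nx)
  calG <- calS <- rep(0, length(B0))
  if (!is.null(calibration)) {
    calG <- stats::approx(calibration@B0, calibration@Gamma1, xout = B0)$y
    calS <- stats::approx(calibration@B0, calibration@sigma, xout = B0)$y
    if (anyNA(calG)) stop("calibration does not cover the sweep fields")
  }
  W <- probe@Gamma2 + RShared
  gNVr <- gyromagneticRatio(probe@gNV, const = const)
  muB <- const$mu_B_over_h
  D2pi <- 2 * pi * probe@D
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    T1 <- vapply(maps, function(m) m@T1[i, j], numeric(1))
    sT1 <- vapply(maps, function(m) m@sigmaT1[i, j], numeric(1))
    conv <- vapply(maps, function(m) m@converged[i, j], logical(1))
    use <- conv & is.finite(T1) & is.finite(sT1) & T1 > 0
    if (sum(use) < 5) next
    G <- 1 / T1[use] - calG[use]
    sG <- sqrt((sT1[use] / T1[use]^2)^2 + calS[use]^2)
    Bu <- B0[use]
    ipk <- which.max(G)
    if (G[ipk] <= 3 * sG[ipk]) next   # unresolvable peak
    g0 <- gFromResonanceField(Bu[ipk], probe, const)
    fit <- .tryNls(
      G ~ (b2 / 2) * W / (W^2 + (D2pi - (gNVr + 2 * pi * g * muB) * B)^2),
      data = list(B = Bu, G = G, W = W, D2pi = D2pi, gNVr = gNVr,
                  muB = muB),
      start = list(b2 = 2 * max(G) * W, g = g0),
      lower = c(b2 = 0, g = 1.01), upper = c(b2 = Inf, g = 9.99),
      weights = 1 / sG^2, maxiter = 200)
    if (is.null(fit)) next
    gmap[i, j] <- stats::coef(fit)[["g"]]
    okmap[i, j] <- TRUE
  }
  gs <- gmap[okmap]
  list(g = gmap, converged = okmap,
       mean = mean(gs), sd = stats::sd(gs), n = length(gs))
}
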