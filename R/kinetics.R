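# Two-point T1 monitoring: intensity -> rate -> concentration, and the
# reversible redox model fit.

#' Two-point relaxation-rate estimator
#'
#' Gamma1 = (deltaI / deltaI0) / (c * tauSp): the fractional change of
#' the normalised two-point intensity, divided by the optical contrast
#' and the probe time. Linear in deltaI/deltaI0 and inverse-linear in
#' tauSp and c; accurate to first order in Gamma1 * tauSp.
#'
#' @param deltaI intensity change (same units as `deltaI0`).
#' @param deltaI0 reference intensity level.
#' @param tauSp probe evolution time, s, > 0.
#' @param contrast optical spin contrast, in (0, 1).
#' @return rate, s^-1 (sign follows `deltaI`).
#' @examples
#' twoPointRate(0.004, 1, 100e-6, 0.04)  # 1000 s^-1
#' @export
twoPointRate <- function(deltaI, deltaI0, tauSp, contrast = 0.04) {
  if (any(tauSp <= 0)) stop("tauSp must be positive")
  if (contrast <= 0 || contrast >= 1) stop("contrast must be in (0, 1)")
  (deltaI / deltaI0) / (contrast * tauSp)
}

#' Target relaxation rate series from a two-point trace
#'
#' Normalises the probe-point intensity by the reference point,
#' averages the normalised intensity over the pre-reaction baseline
#' window, and converts deviations from the baseline to rate changes
#' with [twoPointRate()]. An intensity rise (slower relaxation: fewer
#' target spins) maps to a rate decrease.
#'
#' @param trace a [KineticsTrace-class].
#' @param contrast optical spin contrast.
#' @param gammaBase target-induced rate during the baseline window,
#'   s^-1 (from the spectroscopy/quantification calibration).
#' @param baselineWindow `c(t0, t1)` in s defining the reference level;
#'   default is everything before the stored baseline end (first 10% of
#'   the trace when unknown).
#' @return data.frame with `t` (s) and `gamma1` (s^-1).
#' @export
traceToGamma <- function(trace, contrast = 0.04, gammaBase,
                         baselineWindow = NULL) {
  y <- trace@ISp / trace@IRef
  if (is.null(baselineWindow)) {
    tEnd <- if (!is.null(trace@truth$redox))
      trace@truth$redox@tBaseline else stats::quantile(trace@t, 0.1)
    baselineWindow <- c(min(trace@t), tEnd)
  }
  inBase <- trace@t >= baselineWindow[1] & trace@t <= baselineWindow[2]
  if (sum(inBase) < 2) stop("baseline window contains fewer than 2 points")
  y0 <- mean(y[inBase])
  dG <- twoPointRate(y0 - y, y0, trace@tauSp, contrast)
  data.frame(t = trace@t, gamma1 = gammaBase + dG)
}

#' Concentration series from a two-point trace
#'
#' Applies [traceToGamma()] and then the concentration estimator
#' pointwise. The baseline rate is derived from the known starting
#' concentration through [rateFromConcentration()].
#'
#' @param trace a [KineticsTrace-class].
#' @param contrast optical spin contrast.
#' @param C0 baseline analyte concentration, mol L^-1.
#' @param hProbe probe depth, m.
#' @param Gamma2 probe transverse rate, rad s^-1.
#' @param R target fluctuation rate, rad s^-1.
#' @param baselineWindow see [traceToGamma()].
#' @return data.frame with `t` (s), `gamma1` (s^-1), `C` (mol/L).
#' @export
traceToConcentration <- function(trace, contrast = 0.04, C0,
                                 hProbe = ProbeModel()@hProbe,
                                 Gamma2 = ProbeModel()@Gamma2,
                                 R = 1.8e9, baselineWindow = NULL) {
  gBase <- rateFromConcentration(C0, hProbe, Gamma2, R)
  g <- traceToGamma(trace, contrast, gammaBase = gBase,
                    baselineWindow = baselineWindow)
  g$C <- concentrationFromRate(pmax(g$gamma1, 0), hProbe, Gamma2, R)
  g
}

#' Fit the redox model to a concentration series
#'
#' Least-squares fit of the Cu2+/ascorbate ODE (see [solveRedoxODE()])
#' to an observed Cu2+ concentration series, with the forward and
#' reoxidation rate constants free. Time zero of the model is the
#' reaction start (`tStart`). With the supplied equilibrium constant of
#' order 1e-9 M^2 the fitted model's full long-time recovery of Cu2+ is
#' the expected equilibrium composition.
#'
#' @param t sample times, s (>= 20 points).
#' @param C observed Cu2+ concentrations, mol L^-1.
#' @param ah0 initial ascorbic-acid concentration, mol L^-1.
#' @param Ke equilibrium constant, M^2 (reference only).
#' @param tStart reaction start time, s.
#' @param C0 initial Cu2+ concentration; default is the mean of the
#'   pre-start samples.
#' @param start named list of starting values for `kF`, `kOx`.
#' @return list with `kF`, `kOx`, `C0`, `fitted` (data.frame), `rss`,
#'   `se` (approximate standard errors), `converged`.
#' @export
fitRedoxModel <- function(t, C, ah0, Ke = 5e-9, tStart = 0, C0 = NULL,
                          start = list(kF = 0.5, kOx = 1e-3)) {
  keep <- is.finite(C)
  t <- t[keep]; C <- C[keep]
  if (length(t) < 20) stop("need at least 20 time points")
  if (is.null(C0)) {
    pre <- t <= tStart
    C0 <- if (sum(pre) >= 2) mean(C[pre]) else C[1]
  }
  tRxn <- pmax(t - tStart, 0)
  model <- function(logk) {
    k <- exp(logk)
    ode <- solveRedoxODE(unique(tRxn), RedoxConfig(), cu0 = C0, ah0 = ah0,
                         kF = k[1], kOx = k[2])
    ode$cu2[match(tRxn, ode$time)]
  }
  resFun <- function(logk) C - model(logk)
  fit <- minpack.lm::nls.lm(
    par = log(c(start$kF, start$kOx)), fn = resFun,
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10))
  conv <- fit$info %in% 1:4
  k <- exp(fit$par)
  # delta-method errors on the log scale
  seLog <- tryCatch(sqrt(diag(solve(fit$hessian)) *
                           fit$deviance / (length(t) - 2)),
                    error = function(e) rep(NA_real_, 2))
  fitted <- data.frame(t = t, C = model(fit$par))
  list(kF = k[1], kOx = k[2], C0 = C0, fitted = fitted,
       rss = fit$deviance,
       se = c(kF = k[1] * seLog[1], kOx = k[2] * seLog[2]),
       converged = conv)
}
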