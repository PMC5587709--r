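# Redox kinetics: ODE integration and two-point intensity traces.

#' Integrate the Cu2+ / ascorbate redox ODE
#'
#' d(Cu2+)/dt = -2 kF (Cu2+)^2 (AH2) + kOx (Cu+);
#' d(AH2)/dt = -kF (Cu2+)^2 (AH2);
#' with Cu+ closed by mass balance (Cu2+ plus Cu+ = cu0). The
#' forward step follows the 2:1 stoichiometry of the reduction; the
#' reoxidation is first order in Cu+ (disproportionation / aerobic
#' oxidation) and does not regenerate AH2, so the Cu2+ pool dips and
#' then recovers as the reductant is exhausted.
#'
#' @param times output times, s (reaction starts at 0).
#' @param redox a [RedoxConfig-class] (or use `cu0` etc. directly).
#' @param cu0,ah0,kF,kOx scalar overrides of the config values.
#' @return data.frame with columns `time`, `cu2` (Cu2+, mol/L),
#'   `cu1` (Cu+), `ah2` (AH2).
#' @export
solveRedoxODE <- function(times, redox = RedoxConfig(),
                          cu0 = redox@cu0, ah0 = redox@ah0,
                          kF = redox@kF, kOx = redox@kOx) {
  rhs <- function(t, s, p) {
    u <- max(s[[1]], 0); a <- max(s[[2]], 0)
    fwd <- p[["kF"]] * u^2 * a
    list(c(-2 * fwd + p[["kOx"]] * (p[["cu0"]] - u), -fwd))
  }
  tt <- sort(unique(c(0, times)))
  out <- deSolve::ode(y = c(u = cu0, a = ah0), times = tt, func = rhs,
                      parms = c(kF = kF, kOx = kOx, cu0 = cu0),
                      rtol = 1e-9, atol = 1e-12)
  out <- out[match(times, out[, "time"]), , drop = FALSE]
  data.frame(time = out[, "time"], cu2 = pmax(out[, "u"], 0),
             cu1 = pmax(cu0 - out[, "u"], 0),
             ah2 = pmax(out[, "a"], 0))
}

#' Simulate a two-point relaxation kinetics trace
#'
#' Integrates the redox ODE, maps the Cu2+ concentration to its induced
#' on-resonance relaxation rate through the concentration estimator
#' inverted ([rateFromConcentration()]), and forms the expected
#' normalised two-point intensity by the linear two-point relation:
#' relative to the pre-reaction baseline, the fractional intensity
#' change is -c * tau_sp * (Gamma1(t) - Gamma1(baseline)). Band-limited
#' multiplicative laser fluctuations (independent per channel) and
#' Poisson shot noise are added.
#'
#' @param redox a [RedoxConfig-class].
#' @param probe a [ProbeModel-class] (contrast, depth, Gamma2).
#' @param target a [SpinSpecies-class] (fluctuation rate R).
#' @param tauSp probe evolution time, s; default is the FOV T1 at the
#'   baseline composition.
#' @param gammaBackground non-target relaxation rate at the resonance
#'   field, s^-1.
#' @param photonBudget expected FOV-integrated counts per time point.
#' @param seed RNG seed.
#' @return A [KineticsTrace-class]; its `truth` list carries the ODE
#'   solution, the rate trajectory and all generator parameters.
#' @export
simulateKinetics <- function(redox = RedoxConfig(), probe = ProbeModel(),
                             target = copperSpecies(), tauSp = NULL,
                             gammaBackground = 1 / 730e-6,
                             photonBudget = 1e8, seed = NA_real_) {
  t <- seq(0, redox@tBaseline + redox@duration, by = redox@interval)
  tRxn <- pmax(t - redox@tBaseline, 0)
  ode <- solveRedoxODE(unique(tRxn), redox)
  cu <- ode$cu2[match(tRxn, ode$time)]

  gammaCu <- rateFromConcentration(cu, probe@hProbe, probe@Gamma2,
                                   target@RRelax)
  gammaTot <- gammaBackground + gammaCu
  if (is.null(tauSp)) tauSp <- 1 / gammaTot[1]
  cc <- probe@contrast
  ySp0 <- (1 - cc) + cc * exp(-gammaTot[1] * tauSp)
  # linear two-point model about the baseline rate
  ySp <- ySp0 * (1 - cc * tauSp * (gammaTot - gammaTot[1]))

  .withSeed(seed, {
    lRef <- 1 + .bandNoise(length(t), redox@laserNoise)
    lSp <- 1 + .bandNoise(length(t), redox@laserNoise)
    IRef <- stats::rpois(length(t), photonBudget * lRef)
    ISp <- stats::rpois(length(t), photonBudget * lSp * ySp)
    new("KineticsTrace", t = t, IRef = as.numeric(pmax(IRef, 1)),
        ISp = as.numeric(pmax(ISp, 1)), tauSp = tauSp,
        truth = list(cu = cu, gammaCu = gammaCu, gammaTot = gammaTot,
                     ySp = ySp, redox = redox, tauSp = tauSp,
                     gammaBackground = gammaBackground,
                     hProbe = probe@hProbe, Gamma2 = probe@Gamma2,
                     RRelax = target@RRelax, contrast = cc))
  })
}

# smoothed (band-limited) unit-amplitude noise: moving average of white
# noise rescaled to the requested sd
.bandNoise <- function(n, amplitude, window = 7) {
  if (amplitude <= 0) return(rep(0, n))
  w <- stats::rnorm(n + window)
  sm <- stats::filter(w, rep(1 / window, window), sides = 1)
  sm <- as.numeric(sm[(window + 1):(window + n)])
  amplitude * sm / stats::sd(sm)
}
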