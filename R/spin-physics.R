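# Closed-form spin physics: transition frequencies, resonance fields,
# g-factor conversions, the probe filter function and the Lorentzian
# target relaxation spectrum.
#
# Unit conventions: all spectral quantities are angular frequencies
# (rad s^-1); gyromagnetic ratios are 2*pi*g*muB/h in rad s^-1 G^-1;
# magnetic fields are in gauss at the API surface; D is in Hz.

#' Motional average of an axial g-tensor
#'
#' In solution, rapid tumbling averages the axial components of the
#' Zeeman tensor over all orientations, giving the isotropic effective
#' g-factor (gPar + 2 gPerp)/3.
#'
#' @param gPar parallel g-tensor component.
#' @param gPerp perpendicular g-tensor component.
#' @return the isotropic g-factor.
#' @examples
#' motionalAverageG(2.400, 2.099)  # 2.199 for hexaaqua-Cu2+
#' @export
motionalAverageG <- function(gPar, gPerp) {
  if (any(gPar <= 0) || any(gPerp <= 0))
    stop("g-tensor components must be positive")
  (gPar + 2 * gPerp) / 3
}

#' NV ground-state transition frequency
#'
#' Linear Zeeman regime below the ground-state level anti-crossing:
#' f = D -/+ gamma_NV * B0 for the |0> -> |-1> / |0> -> |+1> branch,
#' with gamma_NV = gNV * muB/h (~2.8 MHz/G).
#'
#' @param B0 applied field, G, in [0, 1024).
#' @param branch -1 or +1, selecting the Zeeman branch.
#' @param probe a [ProbeModel-class].
#' @param const physical constants.
#' @return transition frequency, Hz.
#' @examples
#' nvTransitionFreq(0, -1)    # 2.87e9 at zero field
#' nvTransitionFreq(512, -1)  # ~1.435 GHz
#' @export
nvTransitionFreq <- function(B0, branch = -1, probe = ProbeModel(),
                             const = qprmConstants()) {
  if (any(B0 < 0) || any(B0 >= 1024))
    stop("B0 must lie in [0, 1024) G (below the ground-state anti-crossing)")
  if (!all(branch %in% c(-1, 1))) stop("branch must be -1 or +1")
  probe@D + branch * probe@gNV * const$mu_B_over_h * B0
}

#' Resonance field for a target g-factor
#'
#' Field at which the NV |0> -> |-1> transition crosses the target-spin
#' |-1/2> -> |+1/2> transition, i.e. the solution of
#' D = (gNV + gTarget) * (muB/h) * B.
#'
#' @param gTarget target effective g-factor.
#' @param probe a [ProbeModel-class].
#' @param const physical constants.
#' @return resonance field, G.
#' @examples
#' resonanceField(2.0023)  # ~512 G, free electrons
#' resonanceField(2.199)   # ~488 G, hexaaqua-Cu2+
#' @export
resonanceField <- function(gTarget, probe = ProbeModel(),
                           const = qprmConstants()) {
  if (any(gTarget <= 0)) stop("gTarget must be positive")
  probe@D / ((probe@gNV + gTarget) * const$mu_B_over_h)
}

#' g-factor implied by a resonance field
#'
#' Inverts the resonance condition: g = hD/(muB * BRes) - gNV.
#'
#' @param BRes resonance field, G, > 0.
#' @param probe a [ProbeModel-class].
#' @param const physical constants.
#' @return the target effective g-factor.
#' @examples
#' gFromResonanceField(486)    # ~2.22, aqueous Cu2+
#' gFromResonanceField(511.3)  # ~2.01, diamond surface spins
#' @export
gFromResonanceField <- function(BRes, probe = ProbeModel(),
                                const = qprmConstants()) {
  if (any(BRes <= 0)) stop("BRes must be positive")
  probe@D / (const$mu_B_over_h * BRes) - probe@gNV
}

#' The NV filter function
#'
#' Lorentzian spectral weight with which environmental fluctuations at
#' angular frequency omegaE induce probe relaxation:
#' G = b^2 Gamma2 / (2 (Gamma2^2 + (omega_NV - omegaE)^2)), where
#' omega_NV = 2 pi (D - gamma_NV B0) is the probe transition (angular)
#' frequency at field B0. Its integral over omegaE is pi b^2 / 2.
#'
#' @param omegaE environmental angular frequency, rad s^-1.
#' @param B0 applied field, G.
#' @param b2 squared probe-environment coupling, rad^2 s^-2.
#' @param Gamma2 transverse relaxation rate, rad s^-1.
#' @param probe a [ProbeModel-class].
#' @param const physical constants.
#' @return spectral weight density, per rad s^-1.
#' @export
filterFunction <- function(omegaE, B0, b2 = 1,
                           Gamma2 = ProbeModel()@Gamma2,
                           probe = ProbeModel(),
                           const = qprmConstants()) {
  if (Gamma2 <= 0) stop("Gamma2 must be positive")
  if (b2 < 0) stop("b2 must be >= 0")
  omegaNV <- 2 * pi * (probe@D - probe@gNV * const$mu_B_over_h * B0)
  b2 * Gamma2 / (2 * (Gamma2^2 + (omegaNV - omegaE)^2))
}

#' Closed-form target relaxation spectrum
#'
#' The relaxation rate induced by a Lorentzian spin bath of isotropic
#' g-factor g, fluctuation rate R and squared coupling b2, as a function
#' of applied field:
#' Gamma1(B0) = (b2/2) (Gamma2 + R) /
#'              ((Gamma2 + R)^2 + (2 pi D - (gamma_NV + gamma_T) B0)^2),
#' the convolution of the probe filter function with the bath spectral
#' density. The maximum lies exactly at [resonanceField()] of the
#' species g, with value b2 / (2 (Gamma2 + R)).
#'
#' @param B0 applied field(s), G.
#' @param species a [SpinSpecies-class].
#' @param probe a [ProbeModel-class].
#' @param const physical constants.
#' @return relaxation rate(s), s^-1.
#' @examples
#' cu <- copperSpecies(couplingB2 = couplingFromConcentration(0.1))
#' targetSpectrum(resonanceField(cu@gIso), cu)  # on-resonance maximum
#' @export
targetSpectrum <- function(B0, species, probe = ProbeModel(),
                           const = qprmConstants()) {
  if (species@RRelax < 0) stop("RRelax must be >= 0")
  W <- probe@Gamma2 + species@RRelax
  gammaSum <- gyromagneticRatio(probe@gNV, const = const) +
    gyromagneticRatio(species@gIso, const = const)
  detuning <- 2 * pi * probe@D - gammaSum * B0
  (species@couplingB2 / 2) * W / (W^2 + detuning^2)
}

#' Squared coupling implied by a target concentration
#'
#' Consistency relation between the squared probe-target coupling and
#' the analyte concentration, obtained by equating the on-resonance
#' value of the closed-form spectrum with the inverted concentration
#' estimator: b2 = 2 C / (4.35e10 * h^3). The constant is the printed
#' proportionality of the concentration estimator; h is in metres and C
#' in mol/L, and absolute values are convention-dependent (order of
#' magnitude).
#'
#' @param C concentration, mol L^-1.
#' @param hProbe probe depth, m.
#' @return squared coupling, rad^2 s^-2.
#' @export
couplingFromConcentration <- function(C, hProbe = ProbeModel()@hProbe) {
  if (any(C < 0)) stop("concentration must be >= 0")
  if (hProbe <= 0) stop("hProbe must be positive")
  2 * C / (.EQ4_CONST * hProbe^3)
}
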