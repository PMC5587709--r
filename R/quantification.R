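# Concentration, spin-count and detection-limit estimators.

#' Concentration from an on-resonance target rate
#'
#' C = 4.35e10 * Gamma1 * h^3 * (Gamma2 + R) mol/L, the simplified
#' single-width form of the concentration estimator (the printed form
#' carries (Gamma2+R)^2/(Gamma2+R)). h is in metres; the absolute scale
#' is validated to order of magnitude only (the constant's unit
#' convention is not fully specified).
#'
#' @param gamma1 on-resonance target-induced rate, s^-1.
#' @param hProbe probe depth, m.
#' @param Gamma2 probe transverse rate, rad s^-1.
#' @param R target intrinsic fluctuation rate, rad s^-1.
#' @return concentration, mol L^-1.
#' @examples
#' concentrationFromRate(9e3, 6.7e-9, 2 * pi * 4e6, 1.8e9)  # ~0.2 mol/L
#' @export
concentrationFromRate <- function(gamma1, hProbe = ProbeModel()@hProbe,
                                  Gamma2 = ProbeModel()@Gamma2,
                                  R = 1.8e9) {
  if (hProbe <= 0 || Gamma2 <= 0 || R < 0)
    stop("hProbe and Gamma2 must be positive, R >= 0")
  .EQ4_CONST * gamma1 * hProbe^3 * (Gamma2 + R)
}

#' On-resonance rate implied by a concentration
#'
#' Inverse of [concentrationFromRate()]:
#' Gamma1 = C / (4.35e10 * h^3 * (Gamma2 + R)).
#'
#' @param C concentration, mol L^-1.
#' @inheritParams concentrationFromRate
#' @return rate, s^-1.
#' @export
rateFromConcentration <- function(C, hProbe = ProbeModel()@hProbe,
                                  Gamma2 = ProbeModel()@Gamma2,
                                  R = 1.8e9) {
  if (hProbe <= 0 || Gamma2 <= 0 || R < 0)
    stop("hProbe and Gamma2 must be positive, R >= 0")
  C / (.EQ4_CONST * hProbe^3 * (Gamma2 + R))
}

#' Spins contained in a sensing voxel
#'
#' @param C concentration, mol L^-1 (>= 0).
#' @param voxel a [Voxel-class].
#' @param const physical constants.
#' @return number of spins.
#' @examples
#' spinsPerVoxel(0.1, Voxel())  # ~1.5e6 spins at 100 mM
#' @export
spinsPerVoxel <- function(C, voxel = Voxel(), const = qprmConstants()) {
  if (any(C < 0)) stop("concentration must be >= 0")
  C * const$N_A * voxelVolume(voxel)
}

#' Convert a spin count to moles
#'
#' @param n number of spins (>= 0).
#' @param const physical constants.
#' @return amount, mol.
#' @examples
#' spinsToMoles(75000) * 1e21  # ~125 zmol
#' @export
spinsToMoles <- function(n, const = qprmConstants()) {
  if (any(n < 0)) stop("spin count must be >= 0")
  n / const$N_A
}

#' Detection limit from the rate uncertainty
#'
#' The minimal detectable concentration is reached where the rate
#' uncertainty equals the rate change it must resolve: C_min is the
#' concentration whose on-resonance rate equals `sigmaGamma1`, with the
#' matching spin count and molar amount for the sensing voxel.
#'
#' @param sigmaGamma1 one-sigma rate uncertainty, s^-1, > 0.
#' @param hProbe probe depth, m.
#' @param Gamma2 probe transverse rate, rad s^-1.
#' @param R target fluctuation rate, rad s^-1.
#' @param voxel a [Voxel-class].
#' @param const physical constants.
#' @return list with `C_min` (mol/L), `spins_min`, `mol_min`.
#' @export
detectionLimit <- function(sigmaGamma1, hProbe = ProbeModel()@hProbe,
                           Gamma2 = ProbeModel()@Gamma2, R = 1.8e9,
                           voxel = Voxel(), const = qprmConstants()) {
  if (sigmaGamma1 <= 0) stop("sigmaGamma1 must be positive")
  Cmin <- concentrationFromRate(sigmaGamma1, hProbe, Gamma2, R)
  nmin <- spinsPerVoxel(Cmin, voxel, const)
  list(C_min = Cmin, spins_min = nmin, mol_min = spinsToMoles(nmin, const))
}
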