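#' @import methods
NULL

# ---------------------------------------------------------------------------
# ProbeModel
# ---------------------------------------------------------------------------

#' NV ensemble probe parameters
#'
#' Bundles the parameters of the NV-centre probe layer: the zero-field
#' splitting `D` (Hz), the effective probe g-factor `gNV`, the transverse
#' relaxation rate `Gamma2` (rad s^-1, taken as 2*pi times the ODMR
#' linewidth in Hz), the probe depth below the diamond surface `hProbe`
#' (metres) and the optical spin-relaxation contrast `contrast`.
#'
#' @slot D zero-field splitting, Hz.
#' @slot gNV dimensionless probe g-factor.
#' @slot Gamma2 transverse relaxation rate, rad s^-1.
#' @slot hProbe probe depth, m.
#' @slot contrast optical spin contrast, in (0, 1).
#' @export
setClass("ProbeModel",
  representation(D = "numeric", gNV = "numeric", Gamma2 = "numeric",
                 hProbe = "numeric", contrast = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@D <= 0) msg <- c(msg, "D must be > 0")
    if (object@gNV <= 0) msg <- c(msg, "gNV must be > 0")
    if (object@Gamma2 <= 0) msg <- c(msg, "Gamma2 must be > 0")
    if (object@hProbe <= 0) msg <- c(msg, "hProbe must be > 0")
    if (object@contrast <= 0 || object@contrast >= 1)
      msg <- c(msg, "contrast must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ProbeModel
#'
#' Defaults describe the near-surface NV array used for aqueous spin
#' sensing: D = 2.87 GHz, g = 2.0028, Gamma2 = 2*pi*4 MHz (the ODMR
#' linewidth expressed as an angular rate), 6.7 nm probe depth and 4%
#' relaxation contrast.
#'
#' @param D zero-field splitting, Hz.
#' @param gNV probe g-factor.
#' @param Gamma2 transverse relaxation rate, rad s^-1.
#' @param hProbe probe depth, m.
#' @param contrast optical spin contrast.
#' @return A [ProbeModel-class] object.
#' @examples
#' ProbeModel()
#' @export
ProbeModel <- function(D = 2.87e9, gNV = 2.0028, Gamma2 = 2 * pi * 4e6,
                       hProbe = 6.7e-9, contrast = 0.04) {
  new("ProbeModel", D = D, gNV = gNV, Gamma2 = Gamma2,
      hProbe = hProbe, contrast = contrast)
}

# ---------------------------------------------------------------------------
# SpinSpecies
# ---------------------------------------------------------------------------

#' A target or intrinsic electronic spin bath
#'
#' Describes one paramagnetic species sensed by the probe: either an
#' axial g-tensor (`gPar`, `gPerp`), whose motional average gives the
#' isotropic `gIso` observed in solution, or an isotropic g directly;
#' the intrinsic fluctuation rate `RRelax` (rad s^-1) setting the
#' spectral-density linewidth; and the squared probe-target coupling
#' `couplingB2` (rad^2 s^-2) setting its amplitude.
#'
#' @slot label species name.
#' @slot gPar,gPerp axial g-tensor components (NA when isotropic input).
#' @slot gIso isotropic effective g-factor.
#' @slot RRelax intrinsic fluctuation rate, rad s^-1.
#' @slot couplingB2 squared coupling strength, rad^2 s^-2.
#' @export
setClass("SpinSpecies",
  representation(label = "character", gPar = "numeric", gPerp = "numeric",
                 gIso = "numeric", RRelax = "numeric",
                 couplingB2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    gs <- c(object@gIso, object@gPar, object@gPerp)
    gs <- gs[!is.na(gs)]
    if (any(gs <= 1 | gs >= 10))
      msg <- c(msg, "all g values must lie in (1, 10)")
    if (object@RRelax < 0) msg <- c(msg, "RRelax must be >= 0")
    if (object@couplingB2 < 0) msg <- c(msg, "couplingB2 must be >= 0")
    if (!is.na(object@gPar) && !is.na(object@gPerp)) {
      want <- (object@gPar + 2 * object@gPerp) / 3
      if (abs(object@gIso - want) > 1e-9 * want)
        msg <- c(msg, "gIso must equal the motional average of gPar, gPerp")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpinSpecies
#'
#' Either supply `gPar` and `gPerp` (the isotropic g is then their
#' motional average, (gPar + 2 gPerp)/3) or `gIso` directly.
#'
#' @param label species name.
#' @param gPar,gPerp axial g-tensor components (optional).
#' @param gIso isotropic g-factor (optional when gPar/gPerp given).
#' @param RRelax intrinsic fluctuation rate, rad s^-1.
#' @param couplingB2 squared probe-target coupling, rad^2 s^-2.
#' @return A [SpinSpecies-class] object.
#' @examples
#' SpinSpecies("Cu2+", gPar = 2.400, gPerp = 2.099, RRelax = 1.8e9)
#' @export
SpinSpecies <- function(label, gPar = NA_real_, gPerp = NA_real_,
                        gIso = NA_real_, RRelax = 0, couplingB2 = 0) {
  if (is.na(gIso)) {
    if (is.na(gPar) || is.na(gPerp))
      stop("supply either gIso or both gPar and gPerp")
    gIso <- motionalAverageG(gPar, gPerp)
  }
  new("SpinSpecies", label = label, gPar = gPar, gPerp = gPerp,
      gIso = gIso, RRelax = RRelax, couplingB2 = couplingB2)
}

#' The hexaaqua-Cu2+ target species with literature g-tensor
#'
#' Axial components g_par = 2.400, g_perp = 2.099 (motional average
#' 2.1993) and intrinsic fluctuation rate 1.8e9 rad s^-1.
#'
#' @param RRelax intrinsic fluctuation rate, rad s^-1.
#' @param couplingB2 squared coupling, rad^2 s^-2 (0 until a
#'   concentration is attached; see [couplingFromConcentration()]).
#' @return A [SpinSpecies-class] object.
#' @export
copperSpecies <- function(RRelax = 1.8e9, couplingB2 = 0) {
  SpinSpecies("hexaaqua-Cu2+", gPar = 2.400, gPerp = 2.099,
              RRelax = RRelax, couplingB2 = couplingB2)
}

#' The intrinsic diamond surface-spin bath
#'
#' Defaults place the calibration peak at 511.3 G (g = 2.0077) with a
#' total spectral half-width Gamma2 + RRelax = 60.4e6 rad s^-1 and a
#' coupling chosen so the on-resonance intrinsic rate is ~2500 s^-1.
#'
#' @param gIso isotropic g-factor of the surface bath.
#' @param RRelax intrinsic fluctuation rate, rad s^-1.
#' @param couplingB2 squared coupling, rad^2 s^-2.
#' @return A [SpinSpecies-class] object.
#' @export
surfaceSpecies <- function(gIso = 2.0077,
                           RRelax = 60.4e6 - 2 * pi * 4e6,
                           couplingB2 = 2 * 2500 * 60.4e6) {
  SpinSpecies("surface spins", gIso = gIso, RRelax = RRelax,
              couplingB2 = couplingB2)
}

# ---------------------------------------------------------------------------
# MaskPattern
# ---------------------------------------------------------------------------

#' A 2D concentration mask
#'
#' Row-major concentration map (mol L^-1) with square pixels of
#' `pixelSize` micrometres. Row index increases downward; element
#' `[1, 1]` is the top-left corner of the field of view.
#'
#' @slot conc matrix of concentrations, mol L^-1.
#' @slot pixelSize pixel size, um.
#' @slot kind pattern label.
#' @export
setClass("MaskPattern",
  representation(conc = "matrix", pixelSize = "numeric", kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (any(dim(object@conc) < 8)) msg <- c(msg, "grid must be at least 8x8")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# AcquisitionConfig
# ---------------------------------------------------------------------------

#' Acquisition settings for simulated decay stacks
#'
#' @slot tauGrid evolution times, s, strictly increasing, >= 5 points.
#' @slot nCycles measurement cycles accumulated per tau point.
#' @slot photonsPerCycle expected photons per pixel per cycle at tau = 0.
#' @slot cameraOffset camera offset counts per cycle.
#' @slot psfSigma Gaussian PSF sigma, um.
#' @slot fieldGradient fractional field change across the FOV, c(x, y).
#' @slot seed RNG seed (NA for unseeded).
#' @export
setClass("AcquisitionConfig",
  representation(tauGrid = "numeric", nCycles = "numeric",
                 photonsPerCycle = "numeric", cameraOffset = "numeric",
                 psfSigma = "numeric", fieldGradient = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tauGrid) < 5)
      msg <- c(msg, "tauGrid needs at least 5 points")
    if (any(diff(object@tauGrid) <= 0))
      msg <- c(msg, "tauGrid must be strictly increasing")
    if (object@nCycles < 1) msg <- c(msg, "nCycles must be >= 1")
    if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
    if (length(object@fieldGradient) != 2)
      msg <- c(msg, "fieldGradient must be length 2 (x, y)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an AcquisitionConfig
#'
#' Defaults follow the measurement conditions of the experiment the
#' generator emulates: 10,000 cycles per tau point, a diffraction-limited
#' PSF (sigma = 305/2.3548 nm) and a small linear field gradient
#' (0.07% in x, 0.4% in y across the FOV). The photon budget (counts per
#' pixel per cycle) is a generator choice sized so fitted T1
#' uncertainties at 10,000 cycles are of order 1%.
#'
#' @param tauGrid evolution times, s.
#' @param nCycles cycles per tau point.
#' @param photonsPerCycle expected photons per pixel per cycle at tau = 0.
#' @param cameraOffset offset counts per cycle.
#' @param psfSigma PSF sigma, um.
#' @param fieldGradient fractional change across FOV, c(x, y).
#' @param seed RNG seed or NA.
#' @return An [AcquisitionConfig-class] object.
#' @export
AcquisitionConfig <- function(tauGrid = tauGridDefault(),
                              nCycles = 1e4,
                              photonsPerCycle = 300,
                              cameraOffset = 0,
                              psfSigma = 0.305 / 2.3548,
                              fieldGradient = c(x = 0.0007, y = 0.004),
                              seed = NA_real_) {
  new("AcquisitionConfig", tauGrid = tauGrid, nCycles = nCycles,
      photonsPerCycle = photonsPerCycle, cameraOffset = cameraOffset,
      psfSigma = psfSigma, fieldGradient = unname(fieldGradient),
      seed = as.numeric(seed))
}

#' Default evolution-time grid
#'
#' Log-spaced tau points from 1 us to `tauMax`, suited to T1 values in
#' the tens-of-us to ms range probed across a field sweep.
#'
#' @param n number of points.
#' @param tauMax longest evolution time, s.
#' @return numeric vector of evolution times, s.
#' @export
tauGridDefault <- function(n = 18, tauMax = 3e-3) {
  exp(seq(log(1e-6), log(tauMax), length.out = n))
}

# ---------------------------------------------------------------------------
# SimTruth
# ---------------------------------------------------------------------------

#' Ground truth behind a simulated decay stack
#'
#' Per-pixel decomposition of the relaxation rate into base (far
#' off-resonance), intrinsic (surface-spin) and target contributions,
#' with the resulting T1 map, stretch exponent map and the per-pixel
#' applied field (including any gradient).
#'
#' @slot T1 per-pixel spin-lattice time, s.
#' @slot p per-pixel stretch exponent.
#' @slot gammaBase base rate, s^-1 (scalar).
#' @slot gammaIntrinsic per-pixel intrinsic rate, s^-1.
#' @slot gammaTarget per-pixel target rate, s^-1.
#' @slot B0map per-pixel applied field, G.
#' @slot B0 nominal applied field, G.
#' @slot pixelSize pixel size, um.
#' @slot contrast optical spin contrast inherited from the probe.
#' @export
setClass("SimTruth",
  representation(T1 = "matrix", p = "matrix", gammaBase = "numeric",
                 gammaIntrinsic = "matrix", gammaTarget = "matrix",
                 B0map = "matrix", B0 = "numeric", pixelSize = "numeric",
                 contrast = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@T1 <= 0)) msg <- c(msg, "T1 must be > 0")
    if (any(object@p < 0.3 | object@p > 2))
      msg <- c(msg, "stretch exponent must lie in [0.3, 2]")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# DecayStack
# ---------------------------------------------------------------------------

#' A fluorescence decay image stack
#'
#' The raw unit of measurement: one count image per evolution time tau,
#' accumulated over `nCycles` cycles at applied field `B0`.
#'
#' @slot tau evolution times, s.
#' @slot frames array (ny, nx, n_tau) of counts.
#' @slot nCycles cycles accumulated per tau point.
#' @slot B0 applied field, G.
#' @slot pixelSize pixel size, um.
#' @slot truth the generating [SimTruth-class], or NULL for real data.
#' @export
setClass("DecayStack",
  representation(tau = "numeric", frames = "array", nCycles = "numeric",
                 B0 = "numeric", pixelSize = "numeric", truth = "ANY"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3)
      msg <- c(msg, "frames must be a 3-d array (ny, nx, n_tau)")
    else if (dim(object@frames)[3] != length(object@tau))
      msg <- c(msg, "number of frames must equal length(tau)")
    if (any(object@frames < 0)) msg <- c(msg, "counts must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# FitConfig
# ---------------------------------------------------------------------------

#' Configuration for per-pixel relaxation fitting
#'
#' @slot binning integer pixel binning factor (counts are summed).
#' @slot pBounds lower/upper bounds on the stretch exponent.
#' @slot maxIter maximum optimiser iterations.
#' @slot minSNR minimum amplitude-to-noise ratio to attempt a fit.
#' @slot weights `"auto"`, `"poisson"` or `"none"`.
#' @export
setClass("FitConfig",
  representation(binning = "numeric", pBounds = "numeric",
                 maxIter = "numeric", minSNR = "numeric",
                 weights = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@binning < 1) msg <- c(msg, "binning must be >= 1")
    if (length(object@pBounds) != 2 || diff(object@pBounds) <= 0)
      msg <- c(msg, "pBounds must be c(lower, upper)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FitConfig
#'
#' @param binning pixel binning factor.
#' @param pBounds bounds on the stretch exponent.
#' @param maxIter maximum iterations for the Levenberg-Marquardt fit.
#' @param minSNR minimum SNR to attempt a pixel fit (0 = always fit).
#' @param weights `"auto"` uses Poisson weights (variance = counts) for
#'   raw count data and no weights for pre-normalised data.
#' @return A [FitConfig-class] object.
#' @export
FitConfig <- function(binning = 1, pBounds = c(0.3, 2), maxIter = 200,
                      minSNR = 0, weights = c("auto", "poisson", "none")) {
  weights <- match.arg(weights)
  new("FitConfig", binning = binning, pBounds = pBounds,
      maxIter = maxIter, minSNR = minSNR, weights = weights)
}

# ---------------------------------------------------------------------------
# T1Map
# ---------------------------------------------------------------------------

#' Per-pixel stretched-exponential fit results
#'
#' @slot A amplitude map, counts.
#' @slot T1 spin-lattice time map, s.
#' @slot p stretch exponent map.
#' @slot offset offset map, counts.
#' @slot rms root-mean-square residual map.
#' @slot sigmaT1 standard error of T1, s.
#' @slot converged logical map of fit convergence.
#' @slot B0 applied field of the parent stack, G.
#' @slot binning binning factor used.
#' @export
setClass("T1Map",
  representation(A = "matrix", T1 = "matrix", p = "matrix",
                 offset = "matrix", rms = "matrix", sigmaT1 = "matrix",
                 converged = "matrix", B0 = "numeric", binning = "numeric"),
  validity = function(object) {
    ok <- object@converged
    if (any(object@T1[ok] <= 0, na.rm = TRUE))
      "converged pixels must have T1 > 0" else TRUE
  })

# ---------------------------------------------------------------------------
# RateSpectrum
# ---------------------------------------------------------------------------

#' A relaxation-rate spectrum Gamma1(B0)
#'
#' The spectroscopy unit: relaxation rate versus applied field with
#' one-sigma uncertainties, from the FOV, an ROI or a single pixel.
#'
#' @slot B0 applied fields, G, strictly increasing.
#' @slot Gamma1 relaxation rates, s^-1.
#' @slot sigma one-sigma uncertainties, s^-1.
#' @slot provenance `"FOV"`, `"ROI"` or `"pixel(i,j)"`.
#' @export
setClass("RateSpectrum",
  representation(B0 = "numeric", Gamma1 = "numeric", sigma = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@B0)
    if (length(object@Gamma1) != n || length(object@sigma) != n)
      msg <- c(msg, "B0, Gamma1 and sigma must have equal length")
    if (any(diff(object@B0) <= 0))
      msg <- c(msg, "B0 must be strictly increasing")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be > 0")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# SpectrumFit
# ---------------------------------------------------------------------------

#' Fitted parameters of a target relaxation spectrum
#'
#' @slot gFit effective g-factor.
#' @slot RFit intrinsic fluctuation rate, rad s^-1.
#' @slot b2Fit squared coupling, rad^2 s^-2.
#' @slot hProbeFit probe depth, m (NA unless concentration known).
#' @slot BRes resonance field implied by gFit, G.
#' @slot se named standard errors.
#' @slot cov parameter covariance matrix.
#' @slot converged logical.
#' @export
setClass("SpectrumFit",
  representation(gFit = "numeric", RFit = "numeric", b2Fit = "numeric",
                 hProbeFit = "numeric", BRes = "numeric", se = "numeric",
                 cov = "matrix", converged = "logical"),
  validity = function(object) {
    if (isTRUE(object@converged) && object@RFit < 0)
      "RFit must be >= 0" else TRUE
  })

# ---------------------------------------------------------------------------
# Voxel
# ---------------------------------------------------------------------------

#' A sensing voxel
#'
#' Lateral ROI size times the effective sensing depth above the diamond
#' surface. The default 1.6 x 1.6 x 0.01 um^3 voxel has volume
#' 0.0256 um^3 = 25.6 aL (commonly rounded to 0.025 um^3 / 25 aL).
#'
#' @slot dx,dy lateral size, um.
#' @slot dz effective sensing depth, um.
#' @export
setClass("Voxel",
  representation(dx = "numeric", dy = "numeric", dz = "numeric"),
  validity = function(object) {
    if (object@dx <= 0 || object@dy <= 0 || object@dz <= 0)
      "voxel dimensions must be positive" else TRUE
  })

#' Construct a Voxel
#' @param dx,dy lateral ROI size, um.
#' @param dz effective sensing depth, um (default 0.01 um = 10 nm).
#' @return A [Voxel-class] object.
#' @examples
#' voxelVolume(Voxel())  # 2.56e-17 L
#' @export
Voxel <- function(dx = 1.6, dy = 1.6, dz = 0.01) {
  new("Voxel", dx = dx, dy = dy, dz = dz)
}

# ---------------------------------------------------------------------------
# RedoxConfig
# ---------------------------------------------------------------------------

#' Configuration of the reversible Cu2+ / ascorbate redox simulation
#'
#' The scheme is 2 Cu2+ + AH2 -> 2 Cu+ + A + 2 H+ (termolecular forward
#' step, rate `kF` in L^2 mol^-2 s^-1) with first-order reoxidation of
#' Cu+ back to Cu2+ (`kOx`, s^-1, lumping disproportionation and aerobic
#' oxidation). AH2 is consumed irreversibly by the forward step. The
#' equilibrium constant `Ke` of the printed reaction is carried for
#' reference: at Ke ~ 5e-9 M^2 equilibrium lies almost fully on the Cu2+
#' side, consistent with full long-time recovery.
#'
#' @slot cu0 initial Cu2+ concentration, mol L^-1.
#' @slot ah0 initial ascorbic-acid concentration, mol L^-1.
#' @slot kF forward rate, L^2 mol^-2 s^-1.
#' @slot kOx reoxidation rate, s^-1.
#' @slot Ke equilibrium constant, M^2.
#' @slot interval sampling interval, s.
#' @slot duration trace duration, s.
#' @slot tBaseline pre-reaction baseline length, s.
#' @slot laserNoise fractional amplitude of laser fluctuations.
#' @export
setClass("RedoxConfig",
  representation(cu0 = "numeric", ah0 = "numeric", kF = "numeric",
                 kOx = "numeric", Ke = "numeric", interval = "numeric",
                 duration = "numeric", tBaseline = "numeric",
                 laserNoise = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@cu0 < 0 || object@ah0 < 0)
      msg <- c(msg, "concentrations must be >= 0")
    if (object@kF < 0 || object@kOx < 0) msg <- c(msg, "rates must be >= 0")
    if (object@Ke <= 0) msg <- c(msg, "Ke must be > 0")
    if (object@interval <= 0 || object@duration <= object@interval)
      msg <- c(msg, "need duration > interval > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RedoxConfig
#'
#' Defaults emulate the demonstration experiment: 100 mM Cu2+ mixed 1:1
#' with ascorbic acid, sampled every 3 s over 4000 s after a 60 s
#' baseline; the rate constants reduce ~60% of the Cu2+ within 500 s
#' with near-complete recovery by 4000 s.
#'
#' @param cu0,ah0 initial concentrations, mol L^-1.
#' @param kF forward rate, L^2 mol^-2 s^-1.
#' @param kOx reoxidation rate, s^-1.
#' @param Ke equilibrium constant, M^2.
#' @param interval sampling interval, s.
#' @param duration duration after reaction start, s.
#' @param tBaseline pre-reaction baseline, s.
#' @param laserNoise fractional laser-fluctuation amplitude.
#' @return A [RedoxConfig-class] object.
#' @export
RedoxConfig <- function(cu0 = 0.1, ah0 = 0.1, kF = 0.8, kOx = 2e-3,
                        Ke = 5e-9, interval = 3, duration = 4000,
                        tBaseline = 60, laserNoise = 1e-3) {
  new("RedoxConfig", cu0 = cu0, ah0 = ah0, kF = kF, kOx = kOx, Ke = Ke,
      interval = interval, duration = duration, tBaseline = tBaseline,
      laserNoise = laserNoise)
}

# ---------------------------------------------------------------------------
# KineticsTrace
# ---------------------------------------------------------------------------

#' A two-point relaxation time series
#'
#' Time series of the reference and probe-time intensities of the
#' two-point T1 scheme. `ISp/IRef` is the normalised intensity whose
#' fractional changes encode changes in the relaxation rate.
#'
#' @slot t sample times, s, strictly increasing.
#' @slot IRef reference-point intensities, counts.
#' @slot ISp probe-point intensities, counts.
#' @slot tauSp probe evolution time, s.
#' @slot truth list with generator ground truth (empty for real data).
#' @export
setClass("KineticsTrace",
  representation(t = "numeric", IRef = "numeric", ISp = "numeric",
                 tauSp = "numeric", truth = "list"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@t) <= 0)) msg <- c(msg, "t must be strictly increasing")
    if (any(object@IRef <= 0) || any(object@ISp <= 0))
      msg <- c(msg, "intensities must be > 0")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# LineProfile
# ---------------------------------------------------------------------------

#' A line cut through an image
#'
#' @slot position positions along the cut, um, increasing from p0.
#' @slot value sampled (perpendicular-averaged) image values.
#' @slot p0,p1 cut endpoints, pixel coordinates c(row, col).
#' @slot width perpendicular averaging width, pixels.
#' @export
setClass("LineProfile",
  representation(position = "numeric", value = "numeric",
                 p0 = "numeric", p1 = "numeric", width = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(diff(object@position) <= 0))
      msg <- c(msg, "positions must be increasing")
    if (length(object@position) != length(object@value))
      msg <- c(msg, "position and value must have equal length")
    if (is.null(msg)) TRUE else msg
  })
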