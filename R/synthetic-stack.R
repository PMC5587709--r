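# Seeded simulation of fluorescence decay stacks and field sweeps.

#' Simulate a fluorescence decay stack
#'
#' For each pixel and evolution time tau, the expected per-cycle signal
#' is photonsPerCycle * ((1 - c) + c * exp(-(tau/T1)^p)) + cameraOffset,
#' so that the decaying amplitude spans the optical spin contrast c of
#' the tau = 0 level. The expected image is blurred by a Gaussian PSF
#' (normalised kernel, intensity-conserving) and counts are drawn
#' Poisson with mean scaled by the number of cycles.
#'
#' @param truth a [SimTruth-class] (see [truthFromMask()]).
#' @param acq an [AcquisitionConfig-class].
#' @param seed RNG seed; defaults to the seed stored in `acq`.
#' @param noiseless if TRUE, return the expected counts without Poisson
#'   noise (the infinite-cycle limit).
#' @return A [DecayStack-class] carrying its truth.
#' @export
simulateDecayStack <- function(truth, acq = AcquisitionConfig(),
                               seed = acq@seed, noiseless = FALSE) {
  tau <- acq@tauGrid
  if (length(tau) == 0) stop("empty tau grid")
  ny <- nrow(truth@T1); nx <- ncol(truth@T1)
  cc <- truth@contrast
  sigPx <- acq@psfSigma / truth@pixelSize

  expected <- array(0, dim = c(ny, nx, length(tau)))
  for (k in seq_along(tau)) {
    decay <- exp(-(tau[k] / truth@T1)^truth@p)
    img <- acq@photonsPerCycle * ((1 - cc) + cc * decay) + acq@cameraOffset
    if (sigPx > 0) img <- EBImage::gblur(img, sigma = sigPx)
    expected[, , k] <- img * acq@nCycles
  }
  counts <- if (noiseless) expected else
    .withSeed(seed, array(stats::rpois(length(expected),
                                       lambda = expected),
                          dim = dim(expected)))
  new("DecayStack", tau = tau, frames = counts, nCycles = acq@nCycles,
      B0 = truth@B0, pixelSize = truth@pixelSize, truth = truth)
}

#' Simulate a magnetic-field sweep of decay stacks
#'
#' One decay stack per field in `BList`, each built from its own truth
#' (the field gradient in `acq` perturbs per-pixel fields) and drawn
#' from a documented seed stream: stack i uses seed `seed + i - 1`, so
#' a sweep is reproducible from (config, seed).
#'
#' @param BList applied fields, G.
#' @param mask a [MaskPattern-class].
#' @param probe a [ProbeModel-class].
#' @param target target [SpinSpecies-class] or NULL for a calibration
#'   sweep.
#' @param intrinsic intrinsic [SpinSpecies-class].
#' @param acq an [AcquisitionConfig-class].
#' @param baseGamma base relaxation rate, s^-1.
#' @param stretchP stretch exponent.
#' @param seed base RNG seed; defaults to the seed stored in `acq`.
#' @param noiseless if TRUE, generate expected counts without shot noise.
#' @return list of [DecayStack-class] objects, one per field.
#' @export
simulateFieldSweep <- function(BList, mask, probe = ProbeModel(),
                               target = copperSpecies(),
                               intrinsic = surfaceSpecies(),
                               acq = AcquisitionConfig(),
                               baseGamma = 1 / 730e-6, stretchP = 0.8,
                               seed = acq@seed, noiseless = FALSE) {
  if (length(BList) == 0) stop("BList must be nonempty")
  lapply(seq_along(BList), function(i) {
    truth <- truthFromMask(mask, probe, target, intrinsic, BList[i],
                           baseGamma = baseGamma, stretchP = stretchP,
                           fieldGradient = acq@fieldGradient)
    s <- if (is.na(seed)) NA_real_ else seed + i - 1
    simulateDecayStack(truth, acq, seed = s, noiseless = noiseless)
  })
}
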