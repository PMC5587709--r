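# Accessor generics and show methods for the data containers.

#' @rdname DecayStack-class
#' @param object,x a package object.
#' @export
setGeneric("tauGrid", function(x) standardGeneric("tauGrid"))

#' @rdname DecayStack-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname DecayStack-class
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' Applied magnetic field(s) of an object, in gauss
#' @param x a package object carrying a field value or axis.
#' @export
setGeneric("fieldB0", function(x) standardGeneric("fieldB0"))

#' @rdname DecayStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname DecayStack-class
#' @export
setGeneric("stackTruth", function(x) standardGeneric("stackTruth"))

#' Relaxation rates of a spectrum, s^-1
#' @param x a [RateSpectrum-class].
#' @export
setGeneric("gamma1", function(x) standardGeneric("gamma1"))

#' One-sigma rate uncertainties of a spectrum, s^-1
#' @param x a [RateSpectrum-class].
#' @export
setGeneric("gammaSigma", function(x) standardGeneric("gammaSigma"))

#' Concentration map of a mask, mol L^-1
#' @param x a [MaskPattern-class].
#' @export
setGeneric("concentrationMap", function(x) standardGeneric("concentrationMap"))

#' Per-pixel T1 values of a map or truth object, s
#' @param x a [T1Map-class] or [SimTruth-class].
#' @export
setGeneric("t1Values", function(x) standardGeneric("t1Values"))

#' Voxel volume in litres
#' @param x a [Voxel-class].
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setMethod("tauGrid", "DecayStack", function(x) x@tau)
#' @export
setMethod("frames", "DecayStack", function(x) x@frames)
#' @export
setMethod("nCycles", "DecayStack", function(x) x@nCycles)
#' @export
setMethod("fieldB0", "DecayStack", function(x) x@B0)
#' @export
setMethod("pixelSize", "DecayStack", function(x) x@pixelSize)
#' @export
setMethod("stackTruth", "DecayStack", function(x) x@truth)
#' @export
setMethod("fieldB0", "RateSpectrum", function(x) x@B0)
#' @export
setMethod("gamma1", "RateSpectrum", function(x) x@Gamma1)
#' @export
setMethod("gammaSigma", "RateSpectrum", function(x) x@sigma)
#' @export
setMethod("fieldB0", "T1Map", function(x) x@B0)
#' @export
setMethod("fieldB0", "SimTruth", function(x) x@B0)
#' @export
setMethod("concentrationMap", "MaskPattern", function(x) x@conc)
#' @export
setMethod("pixelSize", "MaskPattern", function(x) x@pixelSize)
#' @export
setMethod("t1Values", "T1Map", function(x) x@T1)
#' @export
setMethod("t1Values", "SimTruth", function(x) x@T1)
#' @export
setMethod("voxelVolume", "Voxel",
          function(x) x@dx * x@dy * x@dz * 1e-15)

setMethod("show", "ProbeModel", function(object) {
  cat("ProbeModel: D =", object@D / 1e9, "GHz, gNV =", object@gNV,
      ", Gamma2 =", signif(object@Gamma2, 4), "rad/s\n",
      " hProbe =", object@hProbe * 1e9, "nm, contrast =",
      object@contrast, "\n")
})

setMethod("show", "SpinSpecies", function(object) {
  cat("SpinSpecies <", object@label, ">: gIso =", round(object@gIso, 4))
  if (!is.na(object@gPar))
    cat(" (gPar =", object@gPar, ", gPerp =", object@gPerp, ")")
  cat("\n  RRelax =", signif(object@RRelax, 4), "rad/s, b2 =",
      signif(object@couplingB2, 4), "rad^2/s^2\n")
})

setMethod("show", "MaskPattern", function(object) {
  d <- dim(object@conc)
  cat("MaskPattern <", object@kind, ">: ", d[1], "x", d[2], " px @ ",
      object@pixelSize, " um; C in [", min(object@conc), ", ",
      max(object@conc), "] mol/L\n", sep = "")
})

setMethod("show", "DecayStack", function(object) {
  d <- dim(object@frames)
  cat("DecayStack: ", d[1], "x", d[2], " px, ", d[3], " tau points (",
      signif(min(object@tau) * 1e6, 3), "-",
      signif(max(object@tau) * 1e6, 3), " us), B0 = ", object@B0,
      " G, Nc = ", object@nCycles,
      if (!is.null(object@truth)) ", with truth" else "", "\n", sep = "")
})

setMethod("show", "T1Map", function(object) {
  ok <- object@converged
  cat("T1Map: ", nrow(object@T1), "x", ncol(object@T1), " px, B0 = ",
      object@B0, " G; ", sum(ok), "/", length(ok), " converged; median T1 = ",
      signif(stats::median(object@T1[ok]) * 1e6, 4), " us\n", sep = "")
})

setMethod("show", "RateSpectrum", function(object) {
  cat("RateSpectrum [", object@provenance, "]: ", length(object@B0),
      " fields, ", min(object@B0), "-", max(object@B0), " G; peak ",
      signif(max(object@Gamma1), 4), " 1/s at ",
      object@B0[which.max(object@Gamma1)], " G\n", sep = "")
})

setMethod("show", "SpectrumFit", function(object) {
  cat("SpectrumFit: g =", round(object@gFit, 4), "(B_res =",
      round(object@BRes, 1), "G), R =", signif(object@RFit, 4),
      "rad/s\n  b2 =", signif(object@b2Fit, 4),
      if (!is.na(object@hProbeFit))
        paste(", h_probe =", signif(object@hProbeFit * 1e9, 3), "nm")
      else "", "\n")
})

setMethod("show", "KineticsTrace", function(object) {
  cat("KineticsTrace: ", length(object@t), " samples over ",
      max(object@t), " s, tau_sp = ", object@tauSp * 1e6, " us\n", sep = "")
})

setMethod("show", "Voxel", function(object) {
  cat("Voxel: ", object@dx, " x ", object@dy, " x ", object@dz,
      " um^3 = ", voxelVolume(object) * 1e18, " aL\n", sep = "")
})
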