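# Configuration handling and seeded end-to-end workflows.

.CONFIG_SCHEMA <- list(
  seed = c("integer"),
  physics = c("mu_B_over_h", "N_A"),
  probe = c("D", "gNV", "Gamma2", "hProbe", "contrast"),
  target = c("gPar", "gPerp", "gIso", "RRelax"),
  intrinsic = c("gIso", "RRelax", "couplingB2"),
  mask = c("kind", "nx", "ny", "pixelSize", "C0", "width", "pitch", "text"),
  acquisition = c("tauN", "tauMax", "nCycles", "photonsPerCycle",
                  "cameraOffset", "psfSigma", "fieldGradientX",
                  "fieldGradientY"),
  sweep = c("fields", "calibrationFields", "baseGamma", "stretchP"),
  quantification = c("concentration", "voxelDx", "voxelDy", "voxelDz"),
  kinetics = c("enabled", "cu0", "ah0", "kF", "kOx", "Ke", "interval",
               "duration", "tBaseline", "laserNoise", "photonBudget")
)

#' Default run configuration
#'
#' Nested list describing a complete simulated experiment: probe and
#' species parameters, the concentration mask, acquisition settings,
#' the field sweep, quantification voxel and the optional kinetics
#' stage. Field sizes are kept small enough that the full pipeline
#' runs in well under a minute.
#'
#' @param seed RNG seed for the whole run.
#' @return a named list accepted by [runSimulation()] / [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    probe = list(D = 2.87e9, gNV = 2.0028, Gamma2 = 2 * pi * 4e6,
                 hProbe = 6.7e-9, contrast = 0.04),
    target = list(gPar = 2.400, gPerp = 2.099, RRelax = 1.8e9),
    intrinsic = list(gIso = 2.0077, RRelax = 60.4e6 - 2 * pi * 4e6,
                     couplingB2 = 2 * 2500 * 60.4e6),
    mask = list(kind = "uniform", nx = 16, ny = 16, pixelSize = 0.4,
                C0 = 0.1),
    acquisition = list(tauN = 18, tauMax = 3e-3, nCycles = 1e4,
                       photonsPerCycle = 300, cameraOffset = 0,
                       psfSigma = 0.305 / 2.3548,
                       fieldGradientX = 0.0007, fieldGradientY = 0.004),
    sweep = list(fields = seq(400, 560, by = 10),
                 calibrationFields = sort(c(seq(400, 560, by = 10),
                                            seq(507, 516, by = 0.75))),
                 baseGamma = 1 / 730e-6, stretchP = 0.8),
    quantification = list(concentration = 0.1, voxelDx = 1.6,
                          voxelDy = 1.6, voxelDz = 0.01),
    kinetics = list(enabled = FALSE, cu0 = 0.1, ah0 = 0.1, kF = 0.8,
                    kOx = 2e-3, Ke = 5e-9, interval = 3, duration = 4000,
                    tBaseline = 60, laserNoise = 1e-3, photonBudget = 1e8)
  )
}

#' Read and validate a run configuration from YAML
#'
#' Unknown sections or keys are rejected with the path of the
#' offending key; values present override the defaults of
#' [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (sec in names(user)) {
    if (!sec %in% names(.CONFIG_SCHEMA))
      stop("unknown config section: ", sec)
    if (sec == "seed") { cfg$seed <- user$seed; next }
    for (key in names(user[[sec]])) {
      if (!key %in% .CONFIG_SCHEMA[[sec]])
        stop("unknown config key: ", sec, "$", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

.probeFromConfig <- function(cfg) {
  p <- cfg$probe
  ProbeModel(D = p$D, gNV = p$gNV, Gamma2 = p$Gamma2, hProbe = p$hProbe,
             contrast = p$contrast)
}

.targetFromConfig <- function(cfg) {
  t <- cfg$target
  if (!is.null(t$gIso))
    SpinSpecies("target", gIso = t$gIso, RRelax = t$RRelax)
  else
    SpinSpecies("target", gPar = t$gPar, gPerp = t$gPerp,
                RRelax = t$RRelax)
}

.intrinsicFromConfig <- function(cfg) {
  i <- cfg$intrinsic
  SpinSpecies("surface spins", gIso = i$gIso, RRelax = i$RRelax,
              couplingB2 = i$couplingB2)
}

.acqFromConfig <- function(cfg, seed) {
  a <- cfg$acquisition
  AcquisitionConfig(tauGrid = tauGridDefault(a$tauN, a$tauMax),
                    nCycles = a$nCycles,
                    photonsPerCycle = a$photonsPerCycle,
                    cameraOffset = a$cameraOffset, psfSigma = a$psfSigma,
                    fieldGradient = c(a$fieldGradientX, a$fieldGradientY),
                    seed = seed)
}

.maskFromConfig <- function(cfg) {
  m <- cfg$mask
  makeMask(m$kind, nx = m$nx, ny = m$ny, pixelSize = m$pixelSize,
           C0 = m$C0,
           width = if (is.null(m$width)) 0.5 else m$width,
           pitch = if (is.null(m$pitch)) 1.0 else m$pitch,
           text = if (is.null(m$text)) "CU" else m$text)
}

#' Simulate and write a full synthetic experiment to disk
#'
#' Generates the combined (target + intrinsic) and calibration
#' (intrinsic-only) field sweeps plus, optionally, the kinetics trace,
#' and writes TIFF stacks with JSON truth sidecars, CSV traces, the
#' resolved configuration and a manifest with MD5 hashes. Outputs are
#' deterministic for a given (config, seed); existing files are reused
#' when `resume = TRUE`.
#'
#' @param cfg config list, see [defaultRunConfig()] / [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @param resume skip files that already exist.
#' @return invisible list of written paths.
#' @export
runSimulation <- function(cfg = defaultRunConfig(), outDir,
                          resume = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  probe <- .probeFromConfig(cfg)
  target <- .targetFromConfig(cfg)
  intrinsic <- .intrinsicFromConfig(cfg)
  mask <- .maskFromConfig(cfg)
  acq <- .acqFromConfig(cfg, cfg$seed)
  paths <- character(0)

  writeSweep <- function(fields, withTarget, prefix, seedOffset) {
    out <- character(length(fields))
    todo <- !resume | !file.exists(
      file.path(outDir, sprintf("%s_%04.0fG.tif", prefix, fields)))
    stacks <- if (any(todo))
      simulateFieldSweep(fields, mask, probe,
                         target = if (withTarget) target else NULL,
                         intrinsic = intrinsic, acq = acq,
                         baseGamma = cfg$sweep$baseGamma,
                         stretchP = cfg$sweep$stretchP,
                         seed = cfg$seed + seedOffset)
    for (i in seq_along(fields)) {
      f <- file.path(outDir, sprintf("%s_%04.0fG.tif", prefix, fields[i]))
      if (todo[i]) writeDecayStack(stacks[[i]], f)
      out[i] <- f
    }
    out
  }
  paths <- c(paths,
             writeSweep(cfg$sweep$fields, TRUE, "combined", 0),
             writeSweep(cfg$sweep$calibrationFields, FALSE, "calibration",
                        1000))
  if (isTRUE(cfg$kinetics$enabled)) {
    k <- cfg$kinetics
    redox <- RedoxConfig(cu0 = k$cu0, ah0 = k$ah0, kF = k$kF, kOx = k$kOx,
                         Ke = k$Ke, interval = k$interval,
                         duration = k$duration, tBaseline = k$tBaseline,
                         laserNoise = k$laserNoise)
    trace <- simulateKinetics(redox, probe, target,
                              gammaBackground = cfg$sweep$baseGamma,
                              photonBudget = k$photonBudget,
                              seed = cfg$seed + 2000)
    f <- file.path(outDir, "kinetics_trace.csv")
    writeKineticsTrace(trace, f)
    paths <- c(paths, f)
  }
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yaml"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(stacks = paths,
                 config = file.path(outDir, "config_resolved.yaml"),
                 manifest = file.path(outDir, "manifest.csv")))
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Simulates the configured experiment in memory (relaxometry input),
#' then runs: per-field FOV decay fits -> rate spectra -> calibration
#' subtraction -> intrinsic and target spectrum fits -> concentration,
#' spins per voxel and detection limit -> (optionally) kinetics trace
#' conversion and redox model fit. Writes the spectra as CSV and a
#' machine-readable JSON report.
#'
#' @param cfg config list.
#' @param outDir output directory.
#' @param resume if TRUE and a report already exists, read and return
#'   it without recomputing.
#' @return the report as a list.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir,
                        resume = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reportPath <- file.path(outDir, "report.json")
  if (resume && file.exists(reportPath))
    return(jsonlite::read_json(reportPath, simplifyVector = TRUE))

  probe <- .probeFromConfig(cfg)
  target <- .targetFromConfig(cfg)
  intrinsic <- .intrinsicFromConfig(cfg)
  mask <- .maskFromConfig(cfg)
  acq <- .acqFromConfig(cfg, cfg$seed)

  combined <- simulateFieldSweep(cfg$sweep$fields, mask, probe, target,
                                 intrinsic, acq,
                                 baseGamma = cfg$sweep$baseGamma,
                                 stretchP = cfg$sweep$stretchP,
                                 seed = cfg$seed)
  calibration <- simulateFieldSweep(cfg$sweep$calibrationFields, mask,
                                    probe, NULL, intrinsic, acq,
                                    baseGamma = cfg$sweep$baseGamma,
                                    stretchP = cfg$sweep$stretchP,
                                    seed = cfg$seed + 1000)
  specIT <- sweepSpectrum(combined)
  specI <- sweepSpectrum(calibration)
  specT <- subtractCalibration(specIT, specI)
  writeSpectrum(specIT, file.path(outDir, "spectrum_combined.csv"))
  writeSpectrum(specI, file.path(outDir, "spectrum_calibration.csv"))
  writeSpectrum(specT, file.path(outDir, "spectrum_target.csv"))

  intFit <- fitIntrinsic(specI, probe)
  conc <- cfg$quantification$concentration
  tarFit <- fitTargetSpectrum(specT, probe, concentration = conc)

  voxel <- Voxel(cfg$quantification$voxelDx, cfg$quantification$voxelDy,
                 cfg$quantification$voxelDz)
  ipk <- which.max(specT@Gamma1)
  CEst <- concentrationFromRate(specT@Gamma1[ipk], probe@hProbe,
                                probe@Gamma2, tarFit@RFit)
  dl <- detectionLimit(specT@sigma[ipk], probe@hProbe, probe@Gamma2,
                       tarFit@RFit, voxel)
  report <- list(
    seed = cfg$seed,
    target = list(
      g = tarFit@gFit, B_res_G = tarFit@BRes, R_rad_per_s = tarFit@RFit,
      b2_rad2_per_s2 = tarFit@b2Fit, h_probe_m = tarFit@hProbeFit),
    intrinsic = list(
      center_G = intFit$center, g = intFit$g,
      half_width_rad_per_s = intFit$halfWidthOmega),
    quantification = list(
      concentration_mol_per_L = CEst,
      spins_per_voxel = spinsPerVoxel(CEst, voxel),
      detection_limit = dl))

  if (isTRUE(cfg$kinetics$enabled)) {
    k <- cfg$kinetics
    redox <- RedoxConfig(cu0 = k$cu0, ah0 = k$ah0, kF = k$kF, kOx = k$kOx,
                         Ke = k$Ke, interval = k$interval,
                         duration = k$duration, tBaseline = k$tBaseline,
                         laserNoise = k$laserNoise)
    trace <- simulateKinetics(redox, probe, target,
                              gammaBackground = cfg$sweep$baseGamma,
                              photonBudget = k$photonBudget,
                              seed = cfg$seed + 2000)
    writeKineticsTrace(trace, file.path(outDir, "kinetics_trace.csv"))
    cc <- traceToConcentration(trace, probe@contrast, C0 = k$cu0,
                               hProbe = probe@hProbe,
                               Gamma2 = probe@Gamma2, R = target@RRelax)
    rfit <- fitRedoxModel(cc$t, cc$C, ah0 = k$ah0, Ke = k$Ke,
                          tStart = k$tBaseline)
    report$kinetics <- list(kF = rfit$kF, kOx = rfit$kOx,
                            C0 = rfit$C0, rss = rfit$rss)
  }
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yaml"))
  report
}
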