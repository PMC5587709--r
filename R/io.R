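# File interchange: multi-page TIFF stacks with JSON sidecars, CSV
# spectra and traces. Unit suffixes are embedded in CSV headers.

#' Write a decay stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit TIFF page per evolution time; counts are stored
#' normalised by a scale factor recorded in the sidecar, which also
#' carries the tau grid, field, cycle count, pixel size and a truth
#' summary when present.
#'
#' @param stack a [DecayStack-class].
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeDecayStack <- function(stack, path) {
  scale <- max(stack@frames, 1)
  pages <- lapply(seq_along(stack@tau), function(k)
    stack@frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(tau_s = stack@tau, B0_G = stack@B0,
               n_cycles = stack@nCycles, pixel_size_um = stack@pixelSize,
               scale = scale)
  if (!is.null(stack@truth) && methods::is(stack@truth, "SimTruth")) {
    tr <- stack@truth
    meta$truth <- list(
      gamma_base_per_s = tr@gammaBase,
      median_T1_s = stats::median(tr@T1),
      median_gamma_target_per_s = stats::median(tr@gammaTarget),
      stretch_p = tr@p[1, 1], contrast = tr@contrast)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a decay stack written by [writeDecayStack()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return A [DecayStack-class] (truth reduced to the sidecar summary,
#'   stored as NULL).
#' @export
readDecayStack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- pages[[k]] * meta$scale
  new("DecayStack", tau = as.numeric(meta$tau_s), frames = fr,
      nCycles = meta$n_cycles, B0 = meta$B0_G,
      pixelSize = meta$pixel_size_um, truth = NULL)
}

#' Write a rate spectrum as CSV
#'
#' Columns `B0_G`, `Gamma1_per_s`, `sigma_per_s`.
#'
#' @param spectrum a [RateSpectrum-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(B0_G = spectrum@B0, Gamma1_per_s = spectrum@Gamma1,
               sigma_per_s = spectrum@sigma),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a rate spectrum CSV written by [writeSpectrum()]
#'
#' @param path CSV path.
#' @param provenance provenance label to attach.
#' @return A [RateSpectrum-class].
#' @export
readSpectrum <- function(path, provenance = "FOV") {
  d <- utils::read.csv(path)
  need <- c("B0_G", "Gamma1_per_s", "sigma_per_s")
  if (!all(need %in% names(d)))
    stop("spectrum CSV must have columns ", paste(need, collapse = ", "))
  new("RateSpectrum", B0 = d$B0_G, Gamma1 = d$Gamma1_per_s,
      sigma = d$sigma_per_s, provenance = provenance)
}

#' Write a kinetics trace as CSV
#'
#' Columns `t_s`, `I_ref`, `I_sp`; the probe time is stored in a
#' comment-free companion column header convention (`tau_sp_s`
#' replicated).
#'
#' @param trace a [KineticsTrace-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeKineticsTrace <- function(trace, path) {
  utils::write.csv(
    data.frame(t_s = trace@t, I_ref = trace@IRef, I_sp = trace@ISp,
               tau_sp_s = trace@tauSp),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a kinetics trace CSV written by [writeKineticsTrace()]
#'
#' @param path CSV path.
#' @return A [KineticsTrace-class] (without generator truth).
#' @export
readKineticsTrace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "I_ref", "I_sp", "tau_sp_s")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  new("KineticsTrace", t = d$t_s, IRef = d$I_ref, ISp = d$I_sp,
      tauSp = d$tau_sp_s[1], truth = list())
}

#' Write a line profile as CSV
#'
#' Columns `pos_um`, `value`.
#'
#' @param profile a [LineProfile-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLineProfile <- function(profile, path) {
  utils::write.csv(data.frame(pos_um = profile@position,
                              value = profile@value),
                   path, row.names = FALSE)
  invisible(path)
}
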