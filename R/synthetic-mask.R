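# Concentration masks and per-pixel ground-truth rate maps.

#' Build a 2D concentration mask
#'
#' Binary-valued concentration patterns emulating lithographic image
#' masks on the diamond chip: a uniform field, block letters, or a
#' vertical grating of given line width and pitch.
#'
#' @param kind `"uniform"`, `"letters"` or `"grating"`.
#' @param nx,ny grid size in pixels (>= 8 each).
#' @param pixelSize pixel size, um.
#' @param C0 concentration inside the pattern, mol L^-1.
#' @param width grating line width, um (grating only).
#' @param pitch grating pitch, um (grating only; must exceed width).
#' @param text letters to render (letters only; subset of A-Z rendered
#'   as coarse block glyphs).
#' @return A [MaskPattern-class].
#' @examples
#' m <- makeMask("grating", nx = 64, ny = 32, pixelSize = 0.1,
#'               C0 = 0.1, width = 0.5, pitch = 1.0)
#' mean(concentrationMap(m) > 0)  # ~ width/pitch
#' @export
makeMask <- function(kind = c("uniform", "letters", "grating"),
                     nx = 64, ny = 64, pixelSize = 0.1, C0 = 0.1,
                     width = 0.5, pitch = 1.0, text = "CU") {
  kind <- match.arg(kind)
  if (nx < 8 || ny < 8) stop("grid must be at least 8x8")
  conc <- matrix(0, nrow = ny, ncol = nx)
  if (kind == "uniform") {
    conc[] <- C0
  } else if (kind == "grating") {
    if (pitch <= width) stop("grating pitch must exceed the line width")
    # pixel centre x-positions, um; stripe where (x mod pitch) < width
    x <- (seq_len(nx) - 0.5) * pixelSize
    on <- (x %% pitch) < width
    conc[, on] <- C0
  } else {
    conc <- C0 * .renderLetters(text, nx, ny)
  }
  new("MaskPattern", conc = conc, pixelSize = pixelSize, kind = kind)
}

# coarse 5x5 block glyphs, enough to pattern a recognisable mask
.GLYPHS <- list(
  C = c("0111", "1000", "1000", "1000", "0111"),
  U = c("1001", "1001", "1001", "1001", "0110"),
  N = c("1001", "1101", "1011", "1001", "1001"),
  V = c("1001", "1001", "1001", "0110", "0110")
)

.renderLetters <- function(text, nx, ny) {
  chars <- strsplit(toupper(text), "")[[1]]
  chars <- chars[chars %in% names(.GLYPHS)]
  if (length(chars) == 0) stop("no renderable letters in 'text'")
  glyphs <- lapply(chars, function(ch) {
    g <- .GLYPHS[[ch]]
    do.call(rbind, lapply(g, function(r) as.integer(strsplit(r, "")[[1]])))
  })
  block <- do.call(cbind, lapply(glyphs, function(g)
    cbind(g, matrix(0L, nrow(g), 1))))
  # scale the glyph block up to ~60% of the grid
  sy <- max(1L, floor(0.6 * ny / nrow(block)))
  sx <- max(1L, floor(0.6 * nx / ncol(block)))
  big <- block[rep(seq_len(nrow(block)), each = sy),
               rep(seq_len(ncol(block)), each = sx), drop = FALSE]
  out <- matrix(0, ny, nx)
  r0 <- max(1L, floor((ny - nrow(big)) / 2))
  c0 <- max(1L, floor((nx - ncol(big)) / 2))
  rr <- r0 + seq_len(min(nrow(big), ny - r0 + 1)) - 1
  cc <- c0 + seq_len(min(ncol(big), nx - c0 + 1)) - 1
  out[rr, cc] <- big[seq_along(rr), seq_along(cc)]
  out
}

#' Ground-truth rate maps from a concentration mask
#'
#' Per pixel, the relaxation rate is the sum of a base (far
#' off-resonance) rate, the intrinsic surface-spin spectrum and the
#' target spectrum with squared coupling proportional to the local
#' concentration (b2 = 2 C / (4.35e10 h^3)). A linear field gradient
#' (fractional change across the FOV in x and y) perturbs the per-pixel
#' field before the spectra are evaluated.
#'
#' @param mask a [MaskPattern-class].
#' @param probe a [ProbeModel-class].
#' @param target target [SpinSpecies-class] or NULL for a calibration
#'   (intrinsic-only) truth; its `couplingB2` is ignored in favour of
#'   the concentration scaling.
#' @param intrinsic intrinsic [SpinSpecies-class] (surface spins).
#' @param B0 nominal applied field, G.
#' @param baseGamma base relaxation rate, s^-1 (default 1/730 us, the
#'   far off-resonance rate of the probe array with analyte present).
#' @param stretchP stretch exponent assigned to every pixel.
#' @param fieldGradient fractional field change across the FOV, c(x, y).
#' @param const physical constants.
#' @return A [SimTruth-class].
#' @export
truthFromMask <- function(mask, probe = ProbeModel(),
                          target = copperSpecies(),
                          intrinsic = surfaceSpecies(),
                          B0, baseGamma = 1 / 730e-6, stretchP = 0.8,
                          fieldGradient = c(0, 0),
                          const = qprmConstants()) {
  conc <- mask@conc
  ny <- nrow(conc); nx <- ncol(conc)
  fx <- if (nx > 1) (col(conc) - 1) / (nx - 1) - 0.5 else 0
  fy <- if (ny > 1) (row(conc) - 1) / (ny - 1) - 0.5 else 0
  B0map <- B0 * (1 + fieldGradient[1] * fx + fieldGradient[2] * fy)

  gInt <- matrix(targetSpectrum(as.vector(B0map), intrinsic, probe, const),
                 ny, nx)
  if (is.null(target)) {
    gTar <- matrix(0, ny, nx)
  } else {
    unitB2 <- couplingFromConcentration(1, probe@hProbe)
    shape <- targetSpectrum(as.vector(B0map),
                            .withB2(target, unitB2), probe, const)
    gTar <- matrix(shape, ny, nx) * conc
  }
  G1 <- baseGamma + gInt + gTar
  new("SimTruth", T1 = 1 / G1, p = matrix(stretchP, ny, nx),
      gammaBase = baseGamma, gammaIntrinsic = gInt, gammaTarget = gTar,
      B0map = B0map, B0 = B0, pixelSize = mask@pixelSize,
      contrast = probe@contrast)
}

.withB2 <- function(species, b2) {
  species@couplingB2 <- b2
  species
}
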