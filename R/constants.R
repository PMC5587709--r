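#' Physical constants used throughout the package
#'
#' Returns the fixed physical constants used by the spin-physics layer:
#' the Bohr magneton over the Planck constant (in Hz per gauss) and the
#' Avogadro constant. These are CODATA values and are not meant to be
#' edited; an explicit override is possible for sensitivity studies.
#'
#' @param mu_B_over_h Bohr magneton over Planck constant, Hz G^-1.
#' @param N_A Avogadro constant, mol^-1.
#' @return A named list with elements `mu_B_over_h` and `N_A`.
#' @examples
#' qprmConstants()$mu_B_over_h  # 1.399624604e6 Hz/G
#' @export
qprmConstants <- function(mu_B_over_h = 1.399624604e6,
                          N_A = 6.02214076e23) {
  stopifnot(is.numeric(mu_B_over_h), mu_B_over_h > 0,
            is.numeric(N_A), N_A > 0)
  list(mu_B_over_h = mu_B_over_h, N_A = N_A)
}

#' Gyromagnetic ratio of a spin with effective g-factor g
#'
#' @param g dimensionless effective g-factor.
#' @param units `"rad_s_G"` (angular, default; gamma = 2 pi g mu_B/h) or
#'   `"Hz_G"` (ordinary frequency).
#' @param const physical constants, see [qprmConstants()].
#' @return gyromagnetic ratio in the requested units per gauss.
#' @examples
#' gyromagneticRatio(2.0028, "Hz_G")  # ~2.803e6 Hz/G, the NV 2.8 MHz/G
#' @export
gyromagneticRatio <- function(g, units = c("rad_s_G", "Hz_G"),
                              const = qprmConstants()) {
  units <- match.arg(units)
  if (any(g <= 0)) stop("g-factor must be positive")
  gHz <- g * const$mu_B_over_h
  if (units == "Hz_G") gHz else 2 * pi * gHz
}

# Eq.-4 style proportionality between target concentration and squared
# probe-target coupling; printed constant, h in metres, C in mol/L.
.EQ4_CONST <- 4.35e10

# run expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
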