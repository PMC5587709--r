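# Stretched-exponential relaxation fitting: per-curve, per-pixel maps,
# ROI aggregation and single-tau contrast images.

#' Fit a stretched-exponential decay
#'
#' Weighted nonlinear least squares of y = A exp(-(tau/T1)^p) + c to a
#' decay curve. Initialisation: the offset from the mean of the last
#' decile of y, the amplitude from the first point, T1 from the 1/e
#' crossing (linear interpolation) and p = 1; p is bounded to
#' `cfg@pBounds`. On non-convergence the fit is retried once with p
#' fixed at 1; a still-failing fit is returned flagged, not thrown.
#'
#' @param tau evolution times, s (>= 5 points).
#' @param y counts (or normalised intensities) at each tau.
#' @param cfg a [FitConfig-class]. With `weights = "auto"`, Poisson
#'   weights (variance = counts) are used when the data look like raw
#'   counts (max > 100), none when pre-normalised.
#' @return list with `A`, `T1`, `p`, `offset`, `rms` (root-mean-square
#'   residual), `sigmaT1` (standard error of T1), `cov` (parameter
#'   covariance) and `converged`.
#' @examples
#' tau <- tauGridDefault()
#' y <- 1000 * exp(-(tau / 96e-6)^0.8) + 100
#' fitDecay(tau, y)$T1  # 96 us
#' @export
fitDecay <- function(tau, y, cfg = FitConfig()) {
  if (length(tau) < 5 || length(y) != length(tau))
    stop("need >= 5 (tau, y) points of equal length")
  if (stats::sd(y) == 0) stop("degenerate input: y is constant")

  useW <- switch(cfg@weights,
                 poisson = TRUE, none = FALSE,
                 auto = max(y) > 100)
  # Poisson weights, capped at a 1e3 dynamic range so nearly-empty
  # tail bins cannot dominate (and destabilise) the fit
  w <- if (useW) 1 / pmax(y, 1, max(y) * 1e-3) else rep(1, length(y))

  n10 <- max(2L, ceiling(length(y) / 10))
  c0 <- mean(utils::tail(y, n10))
  A0 <- max(y[1] - c0, 0.1 * max(abs(y - c0)), .Machine$double.eps)
  T10 <- .oneOverETime(tau, (y - c0) / A0)
  start <- list(A = A0, T1 = T10, p = 1, c0 = c0)
  lower <- c(A = 0, T1 = min(diff(tau)) / 100, p = cfg@pBounds[1],
             c0 = -Inf)
  upper <- c(A = Inf, T1 = 1e4 * max(tau), p = cfg@pBounds[2], c0 = Inf)

  # small multi-start: the rank check of the LM implementation can
  # reject a near-collinear initial Jacobian, which a slight shift of
  # the starting point avoids
  starts <- list(start,
                 modifyList(start, list(T1 = 1.3 * T10, p = 0.9)),
                 modifyList(start, list(T1 = 0.7 * T10, p = 1.2)))
  fit <- NULL
  for (s in starts) {
    fit <- .tryNls(y ~ A * exp(-(tau / T1)^p) + c0,
                   data = list(tau = tau, y = y), start = s,
                   lower = lower, upper = upper, weights = w,
                   maxiter = cfg@maxIter)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {   # tie-break: single-exponential refit
    fit <- .tryNls(y ~ A * exp(-tau / T1) + c0,
                   data = list(tau = tau, y = y),
                   start = start[c("A", "T1", "c0")],
                   lower = lower[c("A", "T1", "c0")],
                   upper = upper[c("A", "T1", "c0")], weights = w,
                   maxiter = cfg@maxIter)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      co <- c(co["A"], co["T1"], p = 1, co["c0"])
    }
  } else co <- stats::coef(fit)

  if (is.null(fit))
    return(list(A = NA_real_, T1 = NA_real_, p = NA_real_,
                offset = NA_real_, rms = NA_real_, sigmaT1 = NA_real_,
                cov = matrix(NA_real_, 0, 0), converged = FALSE))

  resid <- y - stats::predict(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  sT1 <- if (!is.null(vc) && "T1" %in% rownames(vc))
    sqrt(abs(vc["T1", "T1"])) else NA_real_
  list(A = unname(co[["A"]]), T1 = unname(co[["T1"]]),
       p = unname(co[["p"]]), offset = unname(co[["c0"]]),
       rms = sqrt(mean(resid^2)), sigmaT1 = sT1,
       cov = if (is.null(vc)) matrix(NA_real_, 0, 0) else vc,
       converged = TRUE)
}

.oneOverETime <- function(tau, yn) {
  below <- which(yn < exp(-1))
  if (length(below) == 0) return(max(tau))
  i <- below[1]
  if (i == 1) return(tau[1])
  # linear interpolation between bracketing points
  f <- (yn[i - 1] - exp(-1)) / (yn[i - 1] - yn[i])
  tau[i - 1] + f * (tau[i] - tau[i - 1])
}

.tryNls <- function(formula, data, start, lower, upper, weights, maxiter) {
  # do.call so the weights vector is passed by value (nls evaluates the
  # weights argument non-standardly and would not find a local variable)
  fit <- tryCatch(
    suppressWarnings(do.call(minpack.lm::nlsLM, list(
      formula, data = data, start = start, lower = lower, upper = upper,
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)))),
    error = function(e) NULL)
  if (is.null(fit))   # LM can reject a near-singular initial Jacobian
    fit <- tryCatch(
      suppressWarnings(do.call(stats::nls, list(
        formula, data = data, start = start, lower = lower,
        upper = upper, weights = weights, algorithm = "port",
        control = stats::nls.control(maxiter = maxiter,
                                     warnOnly = FALSE)))),
      error = function(e) NULL)
  if (!is.null(fit) && any(!is.finite(stats::coef(fit)))) fit <- NULL
  fit
}

#' Fit a T1 map from a decay stack
#'
#' Runs [fitDecay()] on every (optionally binned) pixel of the stack.
#' Binning sums counts over `binning` x `binning` blocks. Unconverged
#' pixels are flagged and excluded from downstream aggregates.
#'
#' @param stack a [DecayStack-class].
#' @param cfg a [FitConfig-class].
#' @return A [T1Map-class].
#' @export
fitT1Map <- function(stack, cfg = FitConfig()) {
  fr <- stack@frames
  b <- as.integer(cfg@binning)
  if (b > 1) {
    ny <- floor(dim(fr)[1] / b); nx <- floor(dim(fr)[2] / b)
    binned <- array(0, c(ny, nx, dim(fr)[3]))
    for (k in seq_len(dim(fr)[3])) {
      sub <- fr[seq_len(ny * b), seq_len(nx * b), k]
      binned[, , k] <- .binSum(sub, b)
    }
    fr <- binned
  }
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  mk <- function() matrix(NA_real_, ny, nx)
  A <- mk(); T1 <- mk(); p <- mk(); off <- mk(); rms <- mk(); sT1 <- mk()
  ok <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    yij <- fr[i, j, ]
    if (cfg@minSNR > 0) {
      amp <- max(yij) - min(yij)
      if (amp / sqrt(max(yij, 1)) < cfg@minSNR) next
    }
    f <- tryCatch(fitDecay(stack@tau, yij, cfg), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    A[i, j] <- f$A; T1[i, j] <- f$T1; p[i, j] <- f$p
    off[i, j] <- f$offset; rms[i, j] <- f$rms; sT1[i, j] <- f$sigmaT1
    ok[i, j] <- TRUE
  }
  new("T1Map", A = A, T1 = T1, p = p, offset = off, rms = rms,
      sigmaT1 = sT1, converged = ok, B0 = stack@B0, binning = cfg@binning)
}

.binSum <- function(m, b) {
  ny <- nrow(m) / b; nx <- ncol(m) / b
  out <- matrix(0, ny, nx)
  for (di in seq_len(b)) for (dj in seq_len(b))
    out <- out + m[seq(di, by = b, length.out = ny),
                   seq(dj, by = b, length.out = nx)]
  out
}

#' Aggregate a decay stack over a region of interest
#'
#' Sums the counts of each frame over a rectangular ROI, giving the
#' decay curve of that region. The full-frame ROI reproduces the FOV
#' curve.
#'
#' @param stack a [DecayStack-class].
#' @param roi `c(row0, row1, col0, col1)` (1-based, inclusive); NULL
#'   for the whole frame.
#' @return data.frame with columns `tau` (s) and `counts`.
#' @export
roiAggregate <- function(stack, roi = NULL) {
  d <- dim(stack@frames)
  if (is.null(roi)) roi <- c(1, d[1], 1, d[2])
  if (length(roi) != 4 || roi[1] > roi[2] || roi[3] > roi[4] ||
      roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 || roi[4] > d[2])
    stop("roi must be c(row0, row1, col0, col1) within the frame")
  y <- apply(stack@frames[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE],
             3, sum)
  data.frame(tau = stack@tau, counts = y)
}

#' Single evolution-time contrast image
#'
#' The frame at the chosen probe time divided per pixel by a reference
#' intensity (by default the earliest-tau frame). Lower values mean
#' faster relaxation; with the probe time set near the FOV T1 the
#' contrast between fast- and slow-relaxing regions is maximal.
#'
#' @param stack a [DecayStack-class].
#' @param tauSp probe time, s; must match a tau point of the stack.
#' @param reference per-pixel reference intensity matrix; default is
#'   the first frame.
#' @return matrix of normalised intensities; pixels with zero reference
#'   are NA.
#' @export
singleTauContrast <- function(stack, tauSp, reference = NULL) {
  k <- which(abs(stack@tau - tauSp) <= 1e-12 * max(tauSp, 1e-30))
  if (length(k) != 1) {
    k <- which.min(abs(stack@tau - tauSp))
    if (abs(stack@tau[k] - tauSp) > 1e-6 * tauSp)
      stop("tauSp is not a tau point of this stack")
  }
  ref <- if (is.null(reference)) stack@frames[, , 1] else reference
  out <- stack@frames[, , k] / ref
  out[!is.finite(out)] <- NA_real_
  out[ref == 0] <- NA_real_
  out
}

#' Probe time for single-tau imaging
#'
#' The probe evolution time is set to the field-of-view T1, which
#' maximises the sensitivity of the single-point intensity to small
#' rate changes.
#'
#' @param T1fov field-of-view T1, s, > 0.
#' @return the probe time, s.
#' @export
chooseTauSp <- function(T1fov) {
  if (!is.numeric(T1fov) || any(T1fov <= 0)) stop("T1 must be positive")
  T1fov
}
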