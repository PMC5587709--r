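# Spatial-resolution analysis: line profiles, multi-Gaussian peak fits
# and the diffraction limit.

#' Line profile through an image
#'
#' Samples the image along the segment p0 -> p1 by bilinear
#' interpolation, averaging over `width` parallel lines offset
#' perpendicular to the cut. Sample spacing is at most one pixel.
#'
#' @param image numeric matrix (row = y, increasing downward).
#' @param p0,p1 endpoints, `c(row, col)` in pixel coordinates (may be
#'   fractional); must be distinct and within the image.
#' @param width perpendicular averaging width, pixels (odd effective
#'   count, centred on the cut).
#' @param pixelSize pixel size, um.
#' @return A [LineProfile-class] with positions in um.
#' @export
lineProfile <- function(image, p0, p1, width = 1, pixelSize = 1) {
  if (length(p0) != 2 || length(p1) != 2 || all(p0 == p1))
    stop("endpoints must be two distinct c(row, col) pairs")
  .checkInside <- function(p) {
    if (p[1] < 1 || p[1] > nrow(image) || p[2] < 1 || p[2] > ncol(image))
      stop("endpoint outside the image")
  }
  .checkInside(p0); .checkInside(p1)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  n <- ceiling(len) + 1
  tt <- seq(0, 1, length.out = n)
  u <- d / len                        # unit vector along the cut
  v <- c(-u[2], u[1])                 # perpendicular unit vector
  offs <- seq_len(width) - (width + 1) / 2
  vals <- rep(0, n)
  m <- 0
  for (o in offs) {
    rr <- p0[1] + tt * d[1] + o * v[1]
    cc <- p0[2] + tt * d[2] + o * v[2]
    ok <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
    if (!all(ok)) next
    vals <- vals + .bilinear(image, rr, cc)
    m <- m + 1
  }
  if (m == 0) stop("averaging width pushes every line out of bounds")
  new("LineProfile", position = tt * len * pixelSize, value = vals / m,
      p0 = as.numeric(p0), p1 = as.numeric(p1), width = width)
}

.bilinear <- function(image, r, c) {
  r0 <- pmin(pmax(floor(r), 1), nrow(image) - 1)
  c0 <- pmin(pmax(floor(c), 1), ncol(image) - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1)
  i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  image[i00] * (1 - fr) * (1 - fc) + image[i01] * (1 - fr) * fc +
    image[i10] * fr * (1 - fc) + image[i11] * fr * fc
}

#' Fit a sum of Gaussians to a line profile
#'
#' Sum-of-Gaussians plus constant baseline, least squares. Peaks are
#' seeded from supplied centres or from local maxima exceeding the
#' baseline by three median absolute deviations.
#'
#' @param profile a [LineProfile-class] (positions in um).
#' @param nPeaks number of Gaussians (>= 1).
#' @param centers optional seed centres, um.
#' @param invert fit dips instead of peaks (profile is negated).
#' @return list with `centers`, `sigma`, `amplitude` (per peak, um
#'   where applicable), `baseline`, `converged`.
#' @export
fitGaussianPeaks <- function(profile, nPeaks = 1, centers = NULL,
                             invert = FALSE) {
  if (nPeaks < 1) stop("nPeaks must be >= 1")
  x <- profile@position
  y <- if (invert) -profile@value else profile@value
  if (is.null(centers)) {
    centers <- .seedPeaks(x, y, nPeaks)
    if (length(centers) < nPeaks)
      stop("found only ", length(centers), " candidate peaks")
  }
  base0 <- stats::quantile(y, 0.1, names = FALSE)
  amp0 <- rep(max(y) - base0, nPeaks)
  sig0 <- rep(diff(range(x)) / (6 * nPeaks), nPeaks)

  par0 <- c(base0, amp0, centers[seq_len(nPeaks)], sig0)
  fn <- function(par) {
    base <- par[1]
    a <- par[1 + seq_len(nPeaks)]
    m <- par[1 + nPeaks + seq_len(nPeaks)]
    s <- par[1 + 2 * nPeaks + seq_len(nPeaks)]
    pred <- base
    for (k in seq_len(nPeaks))
      pred <- pred + a[k] * exp(-(x - m[k])^2 / (2 * s[k]^2))
    y - pred
  }
  # sigma below the sample spacing is not resolvable; bound it away
  # from degenerate collapse
  sigMin <- stats::median(diff(x)) / 2
  lower <- c(-Inf, rep(0, nPeaks), rep(min(x), nPeaks),
             rep(sigMin, nPeaks))
  upper <- c(Inf, rep(Inf, nPeaks), rep(max(x), nPeaks),
             rep(diff(range(x)), nPeaks))
  fit <- minpack.lm::nls.lm(par = par0, fn = fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  conv <- fit$info %in% 1:4
  p <- fit$par
  o <- order(p[1 + nPeaks + seq_len(nPeaks)])
  list(centers = p[1 + nPeaks + seq_len(nPeaks)][o],
       sigma = abs(p[1 + 2 * nPeaks + seq_len(nPeaks)])[o],
       amplitude = (if (invert) -1 else 1) * p[1 + seq_len(nPeaks)][o],
       baseline = (if (invert) -1 else 1) * p[1],
       converged = conv)
}

.seedPeaks <- function(x, y, nPeaks) {
  base <- stats::median(y)
  thr <- base + 3 * stats::mad(y)
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] >= y[3:n], FALSE) & y > thr
  cand <- x[isMax]
  if (length(cand) > nPeaks) {
    o <- order(y[isMax], decreasing = TRUE)
    cand <- sort(cand[o[seq_len(nPeaks)]])
  }
  cand
}

#' Diffraction-limited optical resolution
#'
#' Rayleigh criterion 1.22 lambda / (2 NA).
#'
#' @param lambda wavelength, nm.
#' @param NA_ numerical aperture, in (0, 2).
#' @return resolution, nm.
#' @examples
#' diffractionLimit(700, 1.4)  # 305 nm
#' @export
diffractionLimit <- function(lambda, NA_) {
  if (lambda <= 0 || NA_ <= 0 || NA_ >= 2)
    stop("need lambda > 0 and 0 < NA < 2")
  1.22 * lambda / (2 * NA_)
}
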