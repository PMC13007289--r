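# Resolution metrics: theoretical blur, Monte Carlo displacement metrics
# (FWHM equivalent, std x 2.355), blur-vs-diameter curves, quadrature
# resolution, profile FWHM, magnitude-histogram fits, and Rayleigh-criterion
# spot resolvability.

# Fraction of a 3D standard Gaussian's mass inside the half-FWHM sphere;
# the defining constant of the FWHM-equivalent metric is the rounded
# literature value 0.292 (exact chi-3 mass: 0.29125).
.FWHM_MASS_3D <- 0.292

#' Theoretical acollinearity-limited spatial blur
#'
#' FWHM of the Gaussian image blur induced by acollinearity under the
#' 2D-Gaussian-deviation model: radians(acoFwhmDeg) / 2 * R. For the 0.58
#' degree deviation FWHM this is 0.0051 * R; for 0.50 degrees, 0.0044 * R.
#'
#' @param acoFwhmDeg acollinearity FWHM in degrees.
#' @param R scanner radius in mm.
#' @return blur FWHM in mm.
#' @examples
#' theoreticalFwhm(0.58, 405)  # 2.05 mm, the 81 cm whole-body case
#' @export
theoreticalFwhm <- function(acoFwhmDeg, R) {
  stopifnot(all(acoFwhmDeg >= 0), all(R >= 0))
  (acoFwhmDeg * pi / 180) / 2 * R
}

#' Monte Carlo displacement samples of the acollinearity blur
#'
#' Draws the transverse-plane spatial response of a centered source whose
#' only blur source is acollinearity: theta from the model's magnitude law,
#' azimuth uniform, displacement (theta * R / 2) * (cos a, sin a) in mm.
#' \code{mode = "isotropic3d"} instead spreads the displacement uniformly
#' over the 3D sphere (three columns); the 2D transverse convention is the
#' default because it is the one whose metrics match the known printed
#' whole-body values.
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param R scanner radius in mm.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @param mode \code{"transverse2d"} (default) or \code{"isotropic3d"}.
#' @return an n x 2 (or n x 3) matrix of mm displacements.
#' @export
sampleBlurDisplacements <- function(model, R, n, seed = NULL,
                                    mode = c("transverse2d", "isotropic3d")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "ApaModel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sigma <- .modelSigmaRad(model)
  theta <- if (model@kind == "GaussMag") abs(rnorm(n, 0, sigma))
           else sigma * sqrt(-2 * log(runif(n)))
  d <- theta * R / 2
  if (mode == "transverse2d") {
    a <- runif(n, 0, 2 * pi)
    cbind(d * cos(a), d * sin(a))
  } else {
    z <- runif(n, -1, 1)
    a <- runif(n, 0, 2 * pi)
    rho <- sqrt(pmax(0, 1 - z^2))
    cbind(d * rho * cos(a), d * rho * sin(a), d * z)
  }
}

#' FWHM-equivalent blur metric
#'
#' Width metric for response functions whose FWHM is ill-defined (the
#' Gaussian-magnitude response has a cusp): twice the radius enclosing the
#' same probability mass (29.2 percent) as the FWHM sphere of a 3D
#' Gaussian.
#'
#' @param samples displacement matrix from
#'   \code{\link{sampleBlurDisplacements}}.
#' @param massFraction enclosed-mass fraction defining the metric.
#' @return blur width in mm.
#' @export
fwhmEquivalent <- function(samples, massFraction = .FWHM_MASS_3D) {
  if (is.null(dim(samples))) stop("samples must be a displacement matrix")
  if (nrow(samples) < 1e4) stop("need at least 1e4 samples")
  r <- sqrt(rowSums(samples^2))
  2 * unname(quantile(r, massFraction, names = FALSE))
}

#' Standard-deviation blur metric
#'
#' The per-component standard deviation of the displacement samples times
#' 2.355, i.e. the FWHM the response would have if it were Gaussian.
#' Components are pooled via the covariance trace, which makes the metric
#' exactly rotation invariant.
#'
#' @param samples displacement matrix.
#' @param factor FWHM conversion constant (the literature rounds to 2.355).
#' @return blur width in mm.
#' @export
stddevBlur <- function(samples, factor = 2.355) {
  if (is.null(dim(samples))) stop("samples must be a displacement matrix")
  if (nrow(samples) < 1e4) stop("need at least 1e4 samples")
  v <- mean(apply(samples, 2, var))
  factor * sqrt(v)
}

#' Blur versus scanner diameter
#'
#' Tabulates, over scanner diameters, the Gaussian-deviation blur (its
#' analytic FWHM) and the two Monte Carlo metrics of the Gaussian-magnitude
#' blur. A single displacement cloud is drawn at unit radius and rescaled
#' per diameter (the response is exactly homogeneous in R).
#'
#' @param diameters scanner diameters in mm.
#' @param acoFwhmDeg acollinearity FWHM in degrees.
#' @param n Monte Carlo sample size.
#' @param seed integer seed.
#' @return data.frame: diameter_mm, gaussdev_fwhm_mm,
#'   gaussmag_fwhm_equiv_mm, gaussmag_std235_mm.
#' @export
blurCurve <- function(diameters, acoFwhmDeg = 0.58, n = 1e6, seed = NULL) {
  stopifnot(all(diameters > 0))
  gm <- apaModel("GaussMag", acoFwhmDeg = acoFwhmDeg)
  base <- sampleBlurDisplacements(gm, R = 1, n = n, seed = seed)
  data.frame(
    diameter_mm = diameters,
    gaussdev_fwhm_mm = theoreticalFwhm(acoFwhmDeg, diameters / 2),
    gaussmag_fwhm_equiv_mm = vapply(diameters, function(D)
      fwhmEquivalent(base * (D / 2)), numeric(1)),
    gaussmag_std235_mm = vapply(diameters, function(D)
      stddevBlur(base * (D / 2)), numeric(1)))
}

#' Quadrature combination of resolution components
#'
#' @param components nonnegative FWHM contributions in mm (the detector-size
#'   contribution of a coincidence pair is half the crystal width).
#' @return square root of the sum of squares.
#' @examples
#' quadratureResolution(c(2.76 / 2, theoreticalFwhm(0.58, 393)))  # ~2.4 mm
#' @export
quadratureResolution <- function(components) {
  stopifnot(all(components >= 0))
  sqrt(sum(components^2))
}

#' FWHM of a peaked 1D profile
#'
#' Background-subtracted half-maximum width with linear interpolation of
#' the two half-maximum crossings.
#'
#' @param profile sample values.
#' @param dx sample spacing in mm (ignored when \code{x} is given).
#' @param background background level to subtract.
#' @param x optional sample positions.
#' @return FWHM in the units of \code{dx} / \code{x}.
#' @export
profileFwhm <- function(profile, dx = 1, background = 0, x = NULL) {
  if (is.null(x)) x <- (seq_along(profile) - 1) * dx
  v <- profile - background
  ip <- which.max(v)
  half <- v[ip] / 2
  if (half <= 0) stop("profile has no peak above background")
  left <- which(v[seq_len(ip - 1)] < half)
  right <- which(v[(ip + 1):length(v)] < half) + ip
  if (!length(left) || !length(right))
    stop("no half-maximum crossing found")
  l <- max(left)
  r <- min(right)
  xl <- x[l] + (half - v[l]) / (v[l + 1] - v[l]) * (x[l + 1] - x[l])
  xr <- x[r - 1] + (half - v[r - 1]) / (v[r] - v[r - 1]) * (x[r] - x[r - 1])
  xr - xl
}

#' Gaussian fit of a point-source profile
#'
#' Least-squares fit of A * exp(-(x - mu)^2 / (2 s^2)) + b to a line
#' profile; used to report the fitted FWHM of the Gaussian-deviation point
#' response.
#'
#' @param x sample positions (mm).
#' @param y sample values.
#' @param background if NULL, the baseline b is a free fit parameter
#'   started at the median of the outer quarter of samples; otherwise fixed.
#' @return list: mu, sigma, amplitude, background, fwhm (mm), fit (the
#'   nls.lm fit object).
#' @export
fitGaussianProfile <- function(x, y, background = NULL) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  outer <- c(seq_len(length(x) %/% 4),
             (length(x) - length(x) %/% 4 + 1):length(x))
  b0 <- if (is.null(background)) median(y[outer]) else background
  i0 <- which.max(y)
  a0 <- max(y[i0] - b0, 1e-12)
  s0 <- tryCatch(profileFwhm(y, background = b0, x = x) / .FWHM_SIGMA,
                 error = function(e) diff(range(x)) / 10)
  if (is.null(background)) {
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + b,
      start = list(A = a0, mu = x[i0], s = s0, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + background,
      start = list(A = a0, mu = x[i0], s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- as.list(coef(fit))
  s <- abs(cf$s)
  list(mu = cf$mu, sigma = s, amplitude = cf$A,
       background = if (is.null(background)) cf$b else background,
       fwhm = .FWHM_SIGMA * s, fit = fit)
}

#' Fit a magnitude histogram
#'
#' Least-squares fit of an amplitude-scaled Gaussian
#' (A * exp(-theta^2 / (2 s^2))) or Rayleigh
#' (A * theta/s * exp(-theta^2 / (2 s^2))) profile to an
#' acollinearity-magnitude histogram, as done on the simulator benchmark
#' histograms.
#'
#' @param hist data.frame with columns binCenterDeg (or binCenter) and
#'   count, e.g. from \code{\link{thetaHistogram}}.
#' @param family \code{"gaussian"} or \code{"rayleigh"}.
#' @return a \code{\link{ProfileFit-class}} object; the scale is in the
#'   units of the histogram axis.
#' @export
fitMagnitudeHistogram <- function(hist, family = c("gaussian", "rayleigh")) {
  family <- match.arg(family)
  th <- if (!is.null(hist$binCenterDeg)) hist$binCenterDeg else hist$binCenter
  if (is.null(th) || !nrow(hist)) stop("empty or malformed histogram")
  y <- hist$count
  m2 <- sum(y * th^2) / sum(y)
  s0 <- if (family == "rayleigh") sqrt(m2 / 2) else sqrt(m2)
  a0 <- max(y)
  fit <- tryCatch({
    if (family == "gaussian")
      minpack.lm::nlsLM(y ~ A * exp(-th^2 / (2 * s^2)),
                        start = list(A = a0, s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * (th / s) * exp(-th^2 / (2 * s^2)),
                        start = list(A = a0, s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) stop("histogram fit did not converge: ",
                              conditionMessage(e)))
  cf <- coef(fit)
  s <- abs(unname(cf["s"]))
  new("ProfileFit", family = family, scale = s,
      amplitude = unname(cf["A"]), fwhm = .FWHM_SIGMA * s,
      rss = sum(residuals(fit)^2), converged = TRUE)
}

#' Which interpretation do these samples follow?
#'
#' Histograms the acollinearity magnitude, fits both the Gaussian and the
#' Rayleigh profile, and reports the better-fitting family: "gaussian"
#' indicates magnitude-as-Gaussian sampling, "rayleigh" indicates a
#' Gaussian 2D deviation.
#'
#' @param theta magnitudes in radians (or a
#'   \code{\link{CoincidenceList-class}} with debug fields).
#' @param binWidthDeg histogram bin width in degrees.
#' @return list: verdict ("GaussMag" or "GaussDev"), gaussian and rayleigh
#'   \code{\link{ProfileFit-class}} fits, and the histogram.
#' @export
t19Check <- function(theta, binWidthDeg = 0.02) {
  h <- thetaHistogram(theta, binWidthDeg)
  fg <- fitMagnitudeHistogram(h, "gaussian")
  fr <- fitMagnitudeHistogram(h, "rayleigh")
  list(verdict = if (fg@rss < fr@rss) "GaussMag" else "GaussDev",
       gaussian = fg, rayleigh = fr, histogram = h)
}

#' Bilinear interpolation of an image
#'
#' @param img an \code{\link{ActivityImage-class}} or matrix.
#' @param pts n x 2 matrix of mm positions.
#' @param pixelSize,origin grid geometry (taken from \code{img} when it is
#'   an ActivityImage).
#' @return interpolated values (0 outside the grid).
#' @export
bilinearAt <- function(img, pts, pixelSize = NULL, origin = NULL) {
  if (is(img, "ActivityImage") || is(img, "ReconResult")) {
    pixelSize <- pixelSize(img); origin <- imageOrigin(img)
    img <- imageValues(img)
  }
  fx <- (pts[, 1] - origin[1]) / pixelSize
  fy <- (pts[, 2] - origin[2]) / pixelSize
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  nx <- nrow(img); ny <- ncol(img)
  val <- function(i, j) {
    ok <- i >= 0 & i <= nx - 1 & j >= 0 & j <= ny - 1
    out <- numeric(length(i))
    out[ok] <- img[cbind(i[ok] + 1, j[ok] + 1)]
    out
  }
  (1 - tx) * (1 - ty) * val(ix, iy) + tx * (1 - ty) * val(ix + 1, iy) +
    (1 - tx) * ty * val(ix, iy + 1) + tx * ty * val(ix + 1, iy + 1)
}

#' Rayleigh-criterion spot resolvability
#'
#' For each adjacent same-diameter spot pair of a hot-spot phantom, reads
#' the background-subtracted image at the two true spot centers and at
#' their midpoint (bilinear interpolation) and scores the pair resolved
#' when the midpoint valley is at most \code{threshold} times the mean of
#' the two center peaks (classical two-point dip 0.735). The background
#' level is the median image value inside the phantom far from every spot.
#'
#' @param image a \code{\link{ReconResult-class}}, an
#'   \code{\link{ActivityImage-class}}, or matrix (then give
#'   \code{pixelSize}/\code{origin}).
#' @param spec the hot-spot \code{\link{PhantomSpec-class}}.
#' @param threshold Rayleigh dip threshold.
#' @param pixelSize,origin grid geometry for a bare matrix.
#' @return data.frame: diameter_mm, n_pairs, n_resolved, fraction.
#' @export
resolvability <- function(image, spec, threshold = 0.735,
                          pixelSize = NULL, origin = NULL) {
  stopifnot(spec@kind == "hot_spot")
  if (is(image, "ActivityImage") || is(image, "ReconResult")) {
    pixelSize <- pixelSize(image); origin <- imageOrigin(image)
    img <- imageValues(image)
  } else img <- image

  allCen <- do.call(rbind, spec@centers)
  if (max(abs(allCen)) > max(abs(origin)) + 1)
    stop("spot centers outside the image")
  # background: pixels inside the phantom, away from every spot
  nx <- nrow(img); ny <- ncol(img)
  gx <- origin[1] + (seq_len(nx) - 1) * pixelSize
  gy <- origin[2] + (seq_len(ny) - 1) * pixelSize
  GX <- matrix(gx, nx, ny); GY <- matrix(gy, nx, ny, byrow = TRUE)
  rr <- sqrt(GX^2 + GY^2)
  minD <- matrix(Inf, nx, ny)
  for (j in seq_len(nrow(allCen)))
    minD <- pmin(minD, sqrt((GX - allCen[j, 1])^2 + (GY - allCen[j, 2])^2))
  bgMask <- rr < spec@phantomRadius - 1 & minD > pmax(2.5, 2 * max(spec@diameters) / 2)
  bg <- if (any(bgMask)) median(img[bgMask]) else 0

  pairs <- adjacentSpotPairs(spec)
  res <- lapply(seq_along(spec@diameters), function(k) {
    cen <- spec@centers[[k]]
    pr <- pairs[[k]]
    d <- spec@diameters[k]
    nRes <- 0L
    for (q in seq_len(nrow(pr))) {
      p1 <- cen[pr[q, 1], ]; p2 <- cen[pr[q, 2], ]
      if (.pairResolved(img, pixelSize, origin, p1, p2, d, bg, threshold))
        nRes <- nRes + 1L
    }
    data.frame(diameter_mm = d, n_pairs = nrow(pr), n_resolved = nRes,
               fraction = if (nrow(pr)) nRes / nrow(pr) else NA_real_)
  })
  do.call(rbind, res)
}

# Score one spot pair by the classical two-point dip: peak values taken at
# the true spot centers, the valley at their midpoint (bilinear
# interpolation). Extremizing noisy profile samples instead would bias flat
# plateaus towards "resolved", since the min of many valley samples drops
# below the max of the peak windows on noise alone.
.pairResolved <- function(img, pixelSize, origin, p1, p2, diameter, bg,
                          threshold) {
  sep <- sqrt(sum((p2 - p1)^2))
  if (sep <= 0) return(FALSE)
  pts <- rbind(p1, p2, (p1 + p2) / 2)
  v <- bilinearAt(img, pts, pixelSize, origin) - bg
  if (v[1] <= 0 || v[2] <= 0) return(FALSE)
  v[3] <= threshold * (v[1] + v[2]) / 2
}
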