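# Sampling and analytic densities for annihilation-photon acollinearity
# under the two competing interpretations, plus the rotation construction of
# the deviated photon direction.

#' Convert a Gaussian FWHM to a standard deviation
#'
#' Divides by 2*sqrt(2*log(2)) = 2.35482..., the conversion used throughout
#' the acollinearity literature. Units are preserved.
#'
#' @param fwhm nonnegative full width at half maximum.
#' @return the corresponding Gaussian sigma.
#' @examples
#' fwhmToSigma(2.354820045)  # 1
#' fwhmToSigma(0.58)         # 0.2463 degrees
#' @export
fwhmToSigma <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm < 0))
    stop("fwhm must be nonnegative and finite")
  fwhm / .FWHM_SIGMA
}

#' Per-axis deviation sigma of a model, in radians
#' @noRd
.modelSigmaRad <- function(model) fwhmToSigma(model@acoFwhmDeg * pi / 180)

#' Draw angular deviations from an acollinearity model
#'
#' \code{GaussDev}: phi and psi are independent zero-mean Gaussians with
#' sigma = \code{fwhmToSigma(acoFwhm)}; the magnitude
#' theta = sqrt(phi^2 + psi^2) is then Rayleigh(sigma).
#' \code{GaussMag}: a signed Gaussian magnitude d with the same sigma and an
#' azimuth uniform on [0, pi) are drawn (mirroring the usual simulator
#' code); (phi, psi) = d * (cos a, sin a) and theta = |d| is half-normal.
#'
#' Uses the current RNG state.
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param n number of samples.
#' @return data.frame with columns phi, psi, theta, all in radians.
#' @examples
#' set.seed(1)
#' d <- sampleDeviation(apaModel("GaussDev"), 1000)
#' mean(d$theta) * 180 / pi  # ~ 0.309 deg (Rayleigh mean)
#' @export
sampleDeviation <- function(model, n) {
  stopifnot(is(model, "ApaModel"))
  validObject(model)
  sigma <- .modelSigmaRad(model)
  if (model@kind == "GaussDev") {
    phi <- rnorm(n, 0, sigma)
    psi <- rnorm(n, 0, sigma)
    theta <- sqrt(phi^2 + psi^2)
  } else {
    d <- rnorm(n, 0, sigma)
    a <- runif(n, 0, pi)
    phi <- d * cos(a)
    psi <- d * sin(a)
    theta <- abs(d)
  }
  data.frame(phi = phi, psi = psi, theta = theta)
}

#' Rotate a direction by an angular deviation
#'
#' Applies to each unit vector p a rotation of theta = sqrt(phi^2 + psi^2)
#' towards the direction (phi, psi) expressed in an orthonormal frame
#' (u, v, p): the result is
#' sin(theta) * phi/theta * u + sin(theta) * psi/theta * v + cos(theta) * p.
#' The 0/0 limit at theta = 0 returns p unchanged (threshold 1e-15 rad).
#' The angle between p and the result equals theta exactly; the frame choice
#' is immaterial for the isotropic deviation laws used here.
#'
#' @param p numeric(3) or an n x 3 matrix of unit vectors.
#' @param phi,psi deviation components in radians (recycled to n).
#' @return an n x 3 matrix of unit vectors (or numeric(3) if p was a vector).
#' @export
deviationToDirection <- function(p, phi, psi) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3L) stop("p must have 3 components")
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm < 1e-12)) stop("p must have nonzero norm")
  if (any(abs(nrm - 1) > 1e-9)) p <- p / nrm
  n <- nrow(p)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  # frame: u = normalize(a x p) with a = z-hat, or y-hat near the pole
  # (so that p = z-hat yields u = x-hat, v = y-hat)
  az <- abs(p[, 3]) > 0.99
  u <- cbind(ifelse(az, p[, 3], -p[, 2]),
             ifelse(az, 0, p[, 1]),
             ifelse(az, -p[, 1], 0))
  u <- u / sqrt(rowSums(u^2))
  # v = p x u
  v <- cbind(p[, 2] * u[, 3] - p[, 3] * u[, 2],
             p[, 3] * u[, 1] - p[, 1] * u[, 3],
             p[, 1] * u[, 2] - p[, 2] * u[, 1])

  theta <- sqrt(phi^2 + psi^2)
  small <- theta < 1e-15
  st <- ifelse(small, 0, sin(theta))
  cphi <- ifelse(small, 0, phi / pmax(theta, 1e-300))
  cpsi <- ifelse(small, 0, psi / pmax(theta, 1e-300))
  out <- st * cphi * u + st * cpsi * v + cos(theta) * p
  if (vec) out[1, ] else out
}

#' Analytic density of the acollinearity magnitude
#'
#' \code{GaussMag}: half-normal, 2 * N(theta; 0, sigma). \code{GaussDev}:
#' Rayleigh, (theta/sigma^2) exp(-theta^2 / (2 sigma^2)). Both normalized
#' over [0, Inf).
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param theta nonnegative angles.
#' @param degrees if TRUE, theta is in degrees and the density is per
#'   degree; default radians.
#' @return density values.
#' @export
magnitudePdf <- function(model, theta, degrees = FALSE) {
  stopifnot(is(model, "ApaModel"))
  if (any(theta < 0)) stop("theta must be >= 0")
  sigma <- if (degrees) fwhmToSigma(model@acoFwhmDeg) else .modelSigmaRad(model)
  if (model@kind == "GaussMag") 2 * dnorm(theta, 0, sigma)
  else (theta / sigma^2) * exp(-theta^2 / (2 * sigma^2))
}

#' Analytic density of the 2D angular deviation
#'
#' \code{GaussDev}: isotropic 2D Gaussian with per-axis sigma.
#' \code{GaussMag}: the induced deviation density is a Gaussian divided by
#' the norm of its argument, (1 / (2 pi theta)) * halfnormal(theta) with
#' theta = sqrt(phi^2 + psi^2); it is singular at the origin. In both cases
#' the magnitude and deviation densities are linked by
#' f(theta) = 2 pi theta g(theta).
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param phi,psi deviation components.
#' @param degrees if TRUE, arguments in degrees.
#' @return density values.
#' @export
deviationPdf <- function(model, phi, psi, degrees = FALSE) {
  stopifnot(is(model, "ApaModel"))
  sigma <- if (degrees) fwhmToSigma(model@acoFwhmDeg) else .modelSigmaRad(model)
  if (model@kind == "GaussDev") {
    dnorm(phi, 0, sigma) * dnorm(psi, 0, sigma)
  } else {
    theta <- sqrt(phi^2 + psi^2)
    if (any(theta == 0))
      stop("GaussMag deviation density is singular at (0, 0)")
    2 * dnorm(theta, 0, sigma) / (2 * pi * theta)
  }
}

#' Generate back-to-back annihilation photon pairs
#'
#' Draws the first photon direction and constructs the second by applying a
#' sampled angular deviation to its opposite:
#' dirB = deviationToDirection(-dirA, phi, psi).
#'
#' Modes: \code{"in_plane"} (default) draws dirA uniformly on the transaxial
#' unit circle, matching the acceptance of a thin 2D ring whose small axial
#' aperture admits only (near-)in-plane events; \code{"isotropic3d"} draws
#' dirA uniformly on the 3D unit sphere.
#'
#' @param origin 2D mm position(s): numeric(2) or an n x 2 matrix.
#' @param model an \code{\link{ApaModel-class}} object.
#' @param n number of pairs.
#' @param mode direction-draw mode, see Details.
#' @return list with origin (n x 2), dirA, dirB (n x 3 unit vectors) and
#'   theta (radians).
#' @export
makePair <- function(origin, model, n,
                     mode = c("in_plane", "isotropic3d")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "ApaModel"))
  if (is.null(dim(origin))) origin <- matrix(origin, nrow = 1)
  if (nrow(origin) == 1L && n > 1L)
    origin <- origin[rep(1L, n), , drop = FALSE]
  if (nrow(origin) != n) stop("origin must have 1 or n rows")
  if (mode == "isotropic3d") {
    z <- runif(n, -1, 1)
    az <- runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    dirA <- cbind(r * cos(az), r * sin(az), z)
  } else {
    b <- runif(n, 0, 2 * pi)
    dirA <- cbind(cos(b), sin(b), 0)
  }
  dev <- sampleDeviation(model, n)
  dirB <- deviationToDirection(-dirA, dev$phi, dev$psi)
  list(origin = origin, dirA = dirA, dirB = dirB, theta = dev$theta)
}
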