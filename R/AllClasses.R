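#' @import methods
#' @importFrom stats rnorm runif dnorm median quantile var setNames dist coef residuals
#' @importFrom Matrix colSums rowSums crossprod t
#' @useDynLib apaSim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # 2.35482...

#' Acollinearity model
#'
#' An \code{ApaModel} fixes one of the two readings of "annihilation photon
#' acollinearity follows a Gaussian distribution":
#' \describe{
#'   \item{\code{GaussMag}}{the scalar \emph{magnitude} of the acollinearity
#'     angle is drawn from a Gaussian (equivalently, theta is half-normal and
#'     the 2D angular deviation has a Gaussian-over-norm, cusp-shaped
#'     density);}
#'   \item{\code{GaussDev}}{the 2D angular \emph{deviation} (phi, psi) is an
#'     isotropic Gaussian, so theta follows a Rayleigh law. This is the
#'     reading consistent with experimental acollinearity measurements.}
#' }
#'
#' @slot kind character, \code{"GaussMag"} or \code{"GaussDev"}.
#' @slot acoFwhmDeg numeric, FWHM of the Gaussian in degrees. The default
#'   0.58 is the value used by the GATE back-to-back benchmark; 0.50
#'   (water measurements) and 0.55 (energy-based estimate) are the other
#'   common literature choices.
#' @export
setClass("ApaModel",
  representation(kind = "character", acoFwhmDeg = "numeric"),
  prototype(kind = "GaussDev", acoFwhmDeg = 0.58))

setValidity("ApaModel", function(object) {
  msg <- NULL
  if (length(object@kind) != 1L || !object@kind %in% c("GaussMag", "GaussDev"))
    msg <- c(msg, "kind must be exactly one of 'GaussMag', 'GaussDev'")
  if (length(object@acoFwhmDeg) != 1L || !is.finite(object@acoFwhmDeg) ||
      object@acoFwhmDeg < 0)
    msg <- c(msg, "acoFwhmDeg must be a single nonnegative finite number")
  if (is.null(msg)) TRUE else msg
})

#' @param kind interpretation, \code{"GaussDev"} (default) or
#'   \code{"GaussMag"}.
#' @param acoFwhmDeg acollinearity FWHM in degrees (default 0.58).
#' @return \code{apaModel} returns an \code{ApaModel}.
#' @examples
#' apaModel("GaussDev")
#' apaModel("GaussMag", acoFwhmDeg = 0.5)
#' @rdname ApaModel-class
#' @export
apaModel <- function(kind = c("GaussDev", "GaussMag"), acoFwhmDeg = 0.58) {
  kind <- match.arg(kind)
  new("ApaModel", kind = kind, acoFwhmDeg = acoFwhmDeg)
}

#' Polygonal 2D PET detector ring
#'
#' A regular polygon of flat detector banks. Each side carries
#' \code{crystalsPerSide} crystals of width \code{crystalWidth} (negligible
#' depth); detection is an idealized photoelectric absorption at the first
#' front face a photon crosses. The default geometry is a 40-sided ring with
#' 128 x 0.5 mm crystals per side (5120 crystals) and the snug inradius
#' \code{sideWidth / (2 tan(pi/nSides))} = 406.63 mm, i.e. a face-to-face
#' diameter of about 81 cm. Supplying a larger \code{inradius} leaves
#' uncovered corner gaps; photons crossing a gap are discarded.
#'
#' @slot nSides integer, number of polygon sides.
#' @slot crystalsPerSide integer, crystals per side.
#' @slot crystalWidth numeric, transaxial crystal width in mm.
#' @slot inradius numeric, face-to-face half-diameter in mm.
#' @slot crystalAxial numeric, axial crystal size in mm. Recorded for
#'   bookkeeping; transport is purely 2D.
#' @export
setClass("RingScanner",
  representation(nSides = "integer", crystalsPerSide = "integer",
                 crystalWidth = "numeric", inradius = "numeric",
                 crystalAxial = "numeric"))

setValidity("RingScanner", function(object) {
  msg <- NULL
  if (object@nSides < 3L) msg <- c(msg, "nSides must be >= 3")
  if (object@crystalsPerSide < 1L) msg <- c(msg, "crystalsPerSide must be >= 1")
  if (object@crystalWidth <= 0) msg <- c(msg, "crystalWidth must be positive")
  sw <- object@crystalsPerSide * object@crystalWidth
  if (2 * object@inradius * tan(pi / object@nSides) < sw - 1e-9)
    msg <- c(msg, "crystals do not fit the polygon side: need 2*inradius*tan(pi/nSides) >= crystalsPerSide*crystalWidth")
  if (is.null(msg)) TRUE else msg
})

#' @param nSides,crystalsPerSide,crystalWidth,inradius,crystalAxial see slots.
#'   \code{inradius = NULL} (default) uses the snug value
#'   \code{sideWidth / (2 tan(pi/nSides))}.
#' @return \code{ringScanner} returns a \code{RingScanner}.
#' @examples
#' sc <- ringScanner()
#' nCrystals(sc)
#' @rdname RingScanner-class
#' @export
ringScanner <- function(nSides = 40L, crystalsPerSide = 128L,
                        crystalWidth = 0.5, inradius = NULL,
                        crystalAxial = 4) {
  nSides <- as.integer(nSides)
  crystalsPerSide <- as.integer(crystalsPerSide)
  if (is.null(inradius))
    inradius <- crystalsPerSide * crystalWidth / (2 * tan(pi / nSides))
  new("RingScanner", nSides = nSides, crystalsPerSide = crystalsPerSide,
      crystalWidth = crystalWidth, inradius = inradius,
      crystalAxial = crystalAxial)
}

#' Phantom specification
#'
#' Describes an emission-activity distribution together with the ground
#' truth geometry needed by the resolution metrics. Two kinds:
#' \code{"point_plus_background"} (a geometric point over a uniform disk)
#' and \code{"hot_spot"} (six 60-degree sectors of circular spots on a
#' triangular lattice with center spacing twice the spot diameter, spot to
#' background activity-density ratio \code{ratio}).
#'
#' @slot kind character, phantom kind.
#' @slot point numeric(2), point-source position in mm.
#' @slot bgFraction numeric, fraction of emissions from the background disk.
#' @slot fovRadius numeric, radius of the background disk in mm.
#' @slot diameters numeric, hot-spot diameters in mm.
#' @slot centers list of 2-column matrices of spot centers (mm), one per
#'   diameter.
#' @slot ratio numeric, spot to background density ratio.
#' @slot phantomRadius numeric, hot-spot phantom radius in mm.
#' @export
setClass("PhantomSpec",
  representation(kind = "character", point = "numeric",
                 bgFraction = "numeric", fovRadius = "numeric",
                 diameters = "numeric", centers = "list",
                 ratio = "numeric", phantomRadius = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("point_plus_background", "hot_spot"))
    msg <- c(msg, "kind must be 'point_plus_background' or 'hot_spot'")
  if (object@kind == "point_plus_background") {
    if (length(object@point) != 2L) msg <- c(msg, "point must have length 2")
    if (object@bgFraction < 0 || object@bgFraction > 1)
      msg <- c(msg, "bgFraction must be in [0, 1]")
    if (sqrt(sum(object@point^2)) > object@fovRadius)
      msg <- c(msg, "point must lie inside the field of view")
  } else {
    if (any(object@diameters <= 0)) msg <- c(msg, "diameters must be positive")
    if (object@ratio <= 1) msg <- c(msg, "spot:background ratio must exceed 1")
    if (length(object@centers) != length(object@diameters))
      msg <- c(msg, "one centers matrix per diameter required")
  }
  if (is.null(msg)) TRUE else msg
})

#' 2D activity image
#'
#' A nonnegative emission-density raster. \code{origin} is the center of
#' pixel \code{[1, 1]}; the matrix is indexed \code{[ix, iy]} with x along
#' rows, so \code{values[ix, iy]} sits at
#' \code{origin + (ix - 1, iy - 1) * pixelSize}.
#'
#' @slot values numeric matrix of densities.
#' @slot pixelSize numeric, pixel width in mm.
#' @slot origin numeric(2), mm position of the center of pixel [1, 1].
#' @export
setClass("ActivityImage",
  representation(values = "matrix", pixelSize = "numeric",
                 origin = "numeric"))

setValidity("ActivityImage", function(object) {
  msg <- NULL
  if (any(object@values < 0)) msg <- c(msg, "activity values must be >= 0")
  if (sum(object@values) <= 0) msg <- c(msg, "total activity must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (is.null(msg)) TRUE else msg
})

#' @param values,pixelSize,origin see slots.
#' @return \code{activityImage} returns an \code{ActivityImage}.
#' @rdname ActivityImage-class
#' @export
activityImage <- function(values, pixelSize, origin = NULL) {
  if (is.null(origin))
    origin <- -c(nrow(values) - 1, ncol(values) - 1) / 2 * pixelSize
  new("ActivityImage", values = values, pixelSize = pixelSize,
      origin = origin)
}

#' True-coincidence list-mode data
#'
#' Events recorded by \code{\link{simulateCoincidences}}: one row per
#' coincidence with the two crystal ids (0-based, canonical
#' \code{idA < idB}) and, when debug retention is on, the emission position
#' and the 3D acollinearity magnitude theta (radians).
#'
#' @slot events data.frame with columns idA, idB and optionally x, y, theta.
#' @slot scanner the \code{RingScanner} used.
#' @slot model the \code{ApaModel} used.
#' @slot stats list: nGenerated, nGap, nAxial, seed, mode.
#' @export
setClass("CoincidenceList",
  representation(events = "data.frame", scanner = "RingScanner",
                 model = "ApaModel", stats = "list"))

setValidity("CoincidenceList", function(object) {
  msg <- NULL
  ev <- object@events
  if (!all(c("idA", "idB") %in% names(ev)))
    msg <- c(msg, "events must have columns idA, idB")
  else {
    n <- nCrystals(object@scanner)
    if (nrow(ev) && (min(ev$idA) < 0 || max(ev$idB) >= n))
      msg <- c(msg, "crystal ids out of range")
    if (nrow(ev) && any(ev$idA >= ev$idB))
      msg <- c(msg, "LORs must be canonically ordered idA < idB")
  }
  if (is.null(msg)) TRUE else msg
})

#' Geometric system matrix
#'
#' Siddon intersection lengths of crystal-center chords with a square pixel
#' grid. Stored as the transposed sparse matrix \code{At} (pixels x LORs) so
#' one compressed-column structure serves forward and back projection.
#'
#' @slot At \code{Matrix::dgCMatrix}, pixels x LORs, entries in mm.
#' @slot lors integer matrix with columns idA, idB (0-based crystal ids).
#' @slot nx,ny integer grid dimensions.
#' @slot pixelSize numeric, pixel width mm.
#' @slot origin numeric(2), center of pixel [1, 1] in mm.
#' @slot scanner the \code{RingScanner} the LORs refer to.
#' @export
setClass("SystemMatrix",
  representation(At = "dgCMatrix", lors = "matrix", nx = "integer",
                 ny = "integer", pixelSize = "numeric", origin = "numeric",
                 scanner = "RingScanner"))

#' ML-EM reconstruction result
#'
#' Final image, a decimated iterate trajectory, and the Poisson
#' log-likelihood path. Images are pixel vectors reshaped to
#' \code{nx x ny} matrices in \code{ActivityImage} orientation.
#'
#' @slot image numeric matrix, final iterate.
#' @slot trajectory numeric matrix, one stored iterate per column.
#' @slot trajIterations integer, iteration number of each stored column.
#' @slot loglik numeric, per-iteration Poisson log-likelihood.
#' @slot nIter integer, iterations run.
#' @slot pixelSize numeric; @slot origin numeric(2): grid geometry.
#' @export
setClass("ReconResult",
  representation(image = "matrix", trajectory = "matrix",
                 trajIterations = "integer", loglik = "numeric",
                 nIter = "integer", pixelSize = "numeric",
                 origin = "numeric"))

#' Fitted magnitude-histogram profile
#'
#' Result of least-squares fitting an amplitude-scaled Gaussian or Rayleigh
#' density to an acollinearity-magnitude histogram.
#'
#' @slot family character, "gaussian" or "rayleigh".
#' @slot scale fitted scale parameter (same units as the histogram axis).
#' @slot amplitude fitted amplitude.
#' @slot fwhm scale expressed as a Gaussian FWHM (2.35482 * scale).
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @export
setClass("ProfileFit",
  representation(family = "character", scale = "numeric",
                 amplitude = "numeric", fwhm = "numeric", rss = "numeric",
                 converged = "logical"))

setValidity("ProfileFit", function(object) {
  if (length(object@scale) == 1L && is.finite(object@scale) &&
      object@scale <= 0) "fitted scale must be positive" else TRUE
})
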