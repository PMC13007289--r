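# Polygonal 2D detector-ring geometry: crystal layout, idealized photon
# detection (first front face crossed absorbs), and LOR bookkeeping.
#
# Conventions: sides are numbered 0..nSides-1; side s has outward normal at
# angle 2*pi*s/nSides (side 0 faces +x). Crystals are numbered 0..K-1 within
# a side from negative to positive lateral offset; crystal ids are 0-based,
# id = side * crystalsPerSide + k.

.sideAngles <- function(scanner) 2 * pi * (seq_len(scanner@nSides) - 1) / scanner@nSides

#' Crystal front-face center positions
#'
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @return an nCrystals x 2 matrix of mm positions, ordered by crystal id.
#' @export
crystalCenters <- function(scanner) {
  stopifnot(is(scanner, "RingScanner"))
  K <- scanner@crystalsPerSide
  alpha <- .sideAngles(scanner)
  lat <- (seq_len(K) - 1 - (K - 1) / 2) * scanner@crystalWidth
  nx <- rep(cos(alpha), each = K)
  ny <- rep(sin(alpha), each = K)
  l <- rep(lat, times = scanner@nSides)
  cbind(scanner@inradius * nx - l * ny,
        scanner@inradius * ny + l * nx)
}

#' @rdname crystalCenters
#' @param id 0-based crystal id(s) in [0, nCrystals).
#' @export
crystalCenter <- function(scanner, id) {
  if (any(id < 0) || any(id >= nCrystals(scanner)))
    stop("crystal id out of range")
  crystalCenters(scanner)[id + 1L, , drop = FALSE]
}

#' Detect photons on the ring
#'
#' Traces rays from interior points and returns the crystal whose front-face
#' segment each ray crosses first, or NA when the ray exits through an
#' uncovered corner gap (possible only when the configured inradius exceeds
#' the snug value). Exit-vertex ties go to the lower side index.
#'
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param origin numeric(2) or n x 2 matrix of interior mm positions.
#' @param direction numeric(2) or n x 2 matrix of transaxial directions
#'   (need not be normalized).
#' @return integer vector of 0-based crystal ids (NA = gap).
#' @export
detect <- function(scanner, origin, direction) {
  stopifnot(is(scanner, "RingScanner"))
  if (is.null(dim(origin))) origin <- matrix(origin, nrow = 1)
  if (is.null(dim(direction))) direction <- matrix(direction, nrow = 1)
  if (nrow(origin) == 1L && nrow(direction) > 1L)
    origin <- origin[rep(1L, nrow(direction)), , drop = FALSE]
  n <- nrow(origin)
  alpha <- .sideAngles(scanner)
  N <- rbind(cos(alpha), sin(alpha))          # 2 x nSides outward normals
  r <- scanner@inradius
  np <- origin %*% N                          # n x nSides
  if (any(np >= r - 1e-9))
    stop("origin must lie strictly inside the polygon")
  nd <- direction %*% N
  tt <- (r - np) / nd
  tt[nd <= 0] <- Inf
  side <- max.col(-tt, ties.method = "first") # lower index on ties
  tstar <- tt[cbind(seq_len(n), side)]
  ex <- origin + tstar * direction
  # lateral coordinate along the side tangent (-sin a, cos a)
  a <- alpha[side]
  lat <- -ex[, 1] * sin(a) + ex[, 2] * cos(a)
  K <- scanner@crystalsPerSide
  half <- sideWidth(scanner) / 2
  k <- floor(lat / scanner@crystalWidth + K / 2)
  k[lat < -half | lat >= half | k < 0 | k > K - 1] <- NA_integer_
  as.integer((side - 1L) * K + k)
}

#' Project a 3D direction to the transaxial plane
#'
#' Renormalizes the (x, y) components. A (numerically) purely axial
#' direction cannot be detected by the 2D ring.
#'
#' @param d numeric(3) or n x 3 matrix.
#' @param onAxial \code{"error"} (default) or \code{"na"}: what to do when
#'   the transaxial norm is below 1e-12.
#' @return n x 2 matrix of unit vectors (rows NA under \code{onAxial="na"}).
#' @export
projectDirection <- function(d, onAxial = c("error", "na")) {
  onAxial <- match.arg(onAxial)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  nrm <- sqrt(d[, 1]^2 + d[, 2]^2)
  bad <- nrm < 1e-12
  if (any(bad) && onAxial == "error")
    stop("purely axial direction cannot be projected")
  out <- cbind(d[, 1] / nrm, d[, 2] / nrm)
  out[bad, ] <- NA_real_
  out
}

#' Enumerate LORs crossing a central disk
#'
#' Lists all canonical crystal pairs (idA < idB) whose center-to-center
#' chord passes within \code{radius} mm of the scanner axis. Used to define
#' the system-matrix row set for a reconstruction field of view.
#'
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param radius disk radius in mm.
#' @return integer matrix with columns idA, idB (0-based ids).
#' @export
enumerateLors <- function(scanner, radius) {
  C <- crystalCenters(scanner)
  N <- nrow(C)
  K <- scanner@crystalsPerSide
  out <- vector("list", N - 1L)
  for (a in seq_len(N - 1L)) {
    b <- (a + 1L):N
    dx <- C[b, 1] - C[a, 1]
    dy <- C[b, 2] - C[a, 2]
    L <- sqrt(dx^2 + dy^2)
    # distance from origin to the infinite line through the two centers
    dist <- abs(dx * C[a, 2] - dy * C[a, 1]) / L
    keep <- which(dist <= radius & L > 0 &
                    ((a - 1L) %/% K) != ((b - 1L) %/% K))
    if (length(keep))
      out[[a]] <- cbind(idA = a - 1L, idB = b[keep] - 1L)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("idA", "idB")))
  storage.mode(m) <- "integer"
  m
}

#' Scanner JSON configuration
#'
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @return \code{scannerToJson}: a JSON string.
#' @export
scannerToJson <- function(scanner) {
  jsonlite::toJSON(list(
    n_sides = scanner@nSides,
    crystals_per_side = scanner@crystalsPerSide,
    crystal_width_mm = scanner@crystalWidth,
    inradius_mm = scanner@inradius,
    crystal_axial_mm = scanner@crystalAxial), auto_unbox = TRUE, digits = NA)
}

#' @rdname scannerToJson
#' @param json a JSON string or parsed list.
#' @export
scannerFromJson <- function(json) {
  cfg <- if (is.character(json)) jsonlite::fromJSON(json) else json
  ringScanner(nSides = cfg$n_sides, crystalsPerSide = cfg$crystals_per_side,
              crystalWidth = cfg$crystal_width_mm,
              inradius = cfg$inradius_mm,
              crystalAxial = if (is.null(cfg$crystal_axial_mm)) 4
                             else cfg$crystal_axial_mm)
}
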