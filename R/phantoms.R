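# Phantom activity models: a geometric point source over a uniform disk
# background, and a sectored hot-spot (Derenzo-style) phantom, with
# ground-truth rasterization and exact emission-position sampling.

#' Point-plus-background phantom
#'
#' A geometric point (no physical extent) over a uniform disk background.
#' \code{bgFraction} is the fraction of sampled emissions originating from
#' the background; the imaging experiments instead simulate the point alone
#' and add a noiseless background in data space (see
#' \code{\link{pointSourceExperiment}}), which is how the converged
#' point-to-background intensity condition is enforced.
#'
#' The default position [0.15625, 0.15625] mm is the center of a
#' 0.3125 mm reconstruction pixel whose edges lie on multiples of
#' 0.3125 mm, avoiding the numerical instability of a source at the exact
#' grid center.
#'
#' @param position numeric(2) mm, point position.
#' @param fovRadius background disk radius in mm.
#' @param bgFraction fraction of emissions from the background, in [0, 1].
#' @return a \code{\link{PhantomSpec-class}} object.
#' @export
pointPhantom <- function(position = c(0.15625, 0.15625), fovRadius = 10,
                         bgFraction = 0.97) {
  new("PhantomSpec", kind = "point_plus_background", point = position,
      bgFraction = bgFraction, fovRadius = fovRadius,
      diameters = numeric(0), centers = list(), ratio = 1,
      phantomRadius = fovRadius)
}

# triangular-lattice spot centers for one 60-degree sector
.sectorCenters <- function(diameter, sectorIndex, phantomRadius, margin) {
  s <- 2 * diameter                       # center-to-center spacing
  phi0 <- (sectorIndex - 1) * pi / 3      # lower bounding radius
  bis <- phi0 + pi / 6
  e1 <- s * c(cos(bis), sin(bis))
  e2 <- s * c(cos(bis + pi / 3), sin(bis + pi / 3))
  m <- ceiling(phantomRadius / s) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  P <- cbind(ij$i * e1[1] + ij$j * e2[1], ij$i * e1[2] + ij$j * e2[2])
  r <- sqrt(rowSums(P^2))
  ang <- atan2(P[, 2], P[, 1]) %% (2 * pi)
  dAng <- (ang - phi0) %% (2 * pi)
  inSector <- dAng >= 0 & dAng <= pi / 3
  # distance to the two bounding radii (lines through the origin)
  d1 <- r * sin(pmin(dAng, pi))
  d2 <- r * sin(pmin(pi / 3 - dAng, pi))
  keep <- inSector & d1 >= margin & d2 >= margin &
    r <= phantomRadius - margin & r > 0
  P[keep, , drop = FALSE]
}

#' Hot-spot phantom
#'
#' Six 60-degree sectors, one spot diameter per sector, spots on a
#' triangular lattice with center-to-center spacing twice the diameter.
#' Spot activity density is \code{ratio} times the uniform background that
#' fills the rest of the phantom disk. Spot centers keep a \code{margin}
#' clearance from the sector bounding radii and the phantom rim.
#'
#' @param diameters spot diameters in mm, one sector each (at most 6).
#' @param ratio spot:background activity-density ratio.
#' @param phantomRadius phantom disk radius in mm.
#' @param margin clearance of spot centers from sector boundaries, mm.
#' @return a \code{\link{PhantomSpec-class}} object.
#' @examples
#' ph <- hotSpotPhantom(phantomRadius = 20)
#' @export
hotSpotPhantom <- function(diameters = c(0.5, 0.9, 1.3, 1.7, 2.1, 2.5),
                           ratio = 4, phantomRadius = 40, margin = 2) {
  if (length(diameters) > 6L) stop("at most six sectors")
  centers <- lapply(seq_along(diameters), function(k)
    .sectorCenters(diameters[k], k, phantomRadius, margin))
  empty <- vapply(centers, nrow, 1L) == 0L
  if (any(empty))
    message("dropping diameters with no spot fitting the sector: ",
            paste(diameters[empty], collapse = ", "))
  new("PhantomSpec", kind = "hot_spot", point = c(0, 0), bgFraction = 0,
      fovRadius = phantomRadius, diameters = diameters,
      centers = centers, ratio = ratio, phantomRadius = phantomRadius)
}

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "PhantomSpec",
  function(spec, pixelSize, nx = NULL, ny = NULL, supersample = 8L) {
    R <- spec@phantomRadius
    if (is.null(nx)) nx <- 2L * ceiling(R / pixelSize) + 2L
    if (is.null(ny)) ny <- nx
    origin <- -c(nx - 1, ny - 1) / 2 * pixelSize
    ss <- as.integer(supersample)
    off <- (seq_len(ss) - (ss + 1) / 2) / ss * pixelSize
    vals <- matrix(0, nx, ny)
    xc <- origin[1] + (seq_len(nx) - 1) * pixelSize
    yc <- origin[2] + (seq_len(ny) - 1) * pixelSize
    for (ox in off) for (oy in off) {
      gx <- matrix(xc + ox, nx, ny)
      gy <- matrix(yc + oy, nx, ny, byrow = TRUE)
      v <- (gx^2 + gy^2 <= R^2) * 1.0
      if (spec@kind == "hot_spot") {
        for (k in seq_along(spec@diameters)) {
          cen <- spec@centers[[k]]
          rad2 <- (spec@diameters[k] / 2)^2
          for (j in seq_len(nrow(cen))) {
            hit <- (gx - cen[j, 1])^2 + (gy - cen[j, 2])^2 <= rad2
            v[hit & v > 0] <- spec@ratio
          }
        }
      }
      vals <- vals + v
    }
    vals <- vals / ss^2
    if (spec@kind == "point_plus_background") {
      # background disk integrates to bgFraction, the point carries the rest
      tot <- sum(vals) * pixelSize^2
      if (tot > 0) vals <- vals * spec@bgFraction / tot
      ij <- round((spec@point - origin) / pixelSize) + 1
      vals[ij[1], ij[2]] <- vals[ij[1], ij[2]] +
        (1 - spec@bgFraction) / pixelSize^2
    }
    activityImage(vals, pixelSize, origin)
  })

#' @rdname sampleEmission
#' @export
setMethod("sampleEmission", "PhantomSpec", function(spec, n) {
  if (spec@kind == "point_plus_background") {
    fromBg <- runif(n) < spec@bgFraction
    nb <- sum(fromBg)
    out <- matrix(rep(spec@point, each = n), n, 2)
    if (nb) {
      r <- spec@fovRadius * sqrt(runif(nb))
      a <- runif(nb, 0, 2 * pi)
      out[fromBg, ] <- cbind(r * cos(a), r * sin(a))
    }
    return(out)
  }
  # hot-spot: exact mixture of [uniform disk, density 1] and, per spot,
  # [uniform spot disk, excess density ratio - 1]
  R <- spec@phantomRadius
  spotArea <- unlist(lapply(seq_along(spec@diameters), function(k)
    rep(pi * (spec@diameters[k] / 2)^2, nrow(spec@centers[[k]]))))
  cen <- do.call(rbind, spec@centers)
  dia <- unlist(lapply(seq_along(spec@diameters), function(k)
    rep(spec@diameters[k], nrow(spec@centers[[k]]))))
  w <- c(pi * R^2, (spec@ratio - 1) * spotArea)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  r <- sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  isBg <- comp == 1L
  rad <- ifelse(isBg, R, dia[pmax(comp - 1L, 1L)] / 2)
  cx <- ifelse(isBg, 0, cen[pmax(comp - 1L, 1L), 1])
  cy <- ifelse(isBg, 0, cen[pmax(comp - 1L, 1L), 2])
  cbind(cx + rad * r * cos(a), cy + rad * r * sin(a))
})

#' Adjacent same-diameter spot pairs
#'
#' Lists lattice-neighbour spot pairs (center distance equal to the lattice
#' spacing, i.e. twice the diameter) for each hot-spot diameter; these are
#' the pairs scored by \code{\link{resolvability}}.
#'
#' @param spec a hot-spot \code{\link{PhantomSpec-class}} object.
#' @return list (one element per diameter) of two-column matrices of row
#'   indices into the diameter's center matrix.
#' @export
adjacentSpotPairs <- function(spec) {
  stopifnot(spec@kind == "hot_spot")
  lapply(seq_along(spec@diameters), function(k) {
    cen <- spec@centers[[k]]
    s <- 2 * spec@diameters[k]
    if (nrow(cen) < 2L) return(matrix(integer(0), 0, 2))
    D <- as.matrix(dist(cen))
    pr <- which(D > 0.99 * s & D < 1.01 * s &
                  upper.tri(D), arr.ind = TRUE)
    pr[pr[, 1] < pr[, 2], , drop = FALSE]
  })
}
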