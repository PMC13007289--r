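# Seeded event loop producing true-coincidence list-mode data from a
# phantom, a scanner and an acollinearity model.

#' Simulate true coincidences
#'
#' Repeats \{sample an emission position, draw a back-to-back photon pair
#' with the model's angular deviation, project both directions to the
#' transaxial plane, detect both photons on the ring\} until
#' \code{nCoincidences} events have both photons detected. Corner-gap and
#' axial-degenerate losses are counted in the returned stats. Identical
#' seeds give identical output.
#'
#' @param nCoincidences number of coincidences to record.
#' @param model an \code{\link{ApaModel-class}} object.
#' @param phantom a \code{\link{PhantomSpec-class}} object.
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param seed integer seed (required field of a run configuration; NULL
#'   continues the current RNG stream).
#' @param mode first-photon draw mode passed to \code{\link{makePair}};
#'   \code{"in_plane"} (default) reproduces the acceptance of a thin
#'   axially-gated 2D ring, \code{"isotropic3d"} draws on the full sphere.
#' @param keepDebug retain emission position and theta per event.
#' @return a \code{\link{CoincidenceList-class}} object.
#' @examples
#' sc <- ringScanner()
#' cl <- simulateCoincidences(500, apaModel("GaussDev"),
#'                            pointPhantom(bgFraction = 0), sc, seed = 7)
#' @export
simulateCoincidences <- function(nCoincidences, model, phantom, scanner,
                                 seed = NULL,
                                 mode = c("in_plane", "isotropic3d"),
                                 keepDebug = TRUE) {
  mode <- match.arg(mode)
  stopifnot(nCoincidences > 0)
  if (!is.null(seed)) set.seed(seed)
  if (phantom@fovRadius > scanner@inradius)
    stop("phantom extends outside the scanner bore")
  got <- 0L
  nGen <- 0L; nGap <- 0L; nAxial <- 0L; nDet <- 0L
  chunks <- list()
  while (got < nCoincidences) {
    m <- as.integer(ceiling((nCoincidences - got) * 1.1) + 64L)
    pos <- sampleEmission(phantom, m)
    pair <- makePair(pos, model, m, mode = mode)
    dA <- projectDirection(pair$dirA, onAxial = "na")
    dB <- projectDirection(pair$dirB, onAxial = "na")
    axial <- is.na(dA[, 1]) | is.na(dB[, 1])
    nAxial <- nAxial + sum(axial)
    idA <- idB <- rep(NA_integer_, m)
    okDir <- !axial
    if (any(okDir)) {
      idA[okDir] <- detect(scanner, pos[okDir, , drop = FALSE],
                           dA[okDir, , drop = FALSE])
      idB[okDir] <- detect(scanner, pos[okDir, , drop = FALSE],
                           dB[okDir, , drop = FALSE])
    }
    gap <- okDir & (is.na(idA) | is.na(idB))
    nGap <- nGap + sum(gap)
    ok <- which(!is.na(idA) & !is.na(idB) & idA != idB)
    nGen <- nGen + m
    nDet <- nDet + length(ok)
    if (length(ok)) {
      lo <- pmin(idA[ok], idB[ok])
      hi <- pmax(idA[ok], idB[ok])
      df <- if (keepDebug)
        data.frame(idA = lo, idB = hi, x = pos[ok, 1], y = pos[ok, 2],
                   theta = pair$theta[ok])
      else data.frame(idA = lo, idB = hi)
      chunks[[length(chunks) + 1L]] <- df
      got <- got + length(ok)
    }
  }
  ev <- do.call(rbind, chunks)[seq_len(nCoincidences), , drop = FALSE]
  rownames(ev) <- NULL
  new("CoincidenceList", events = ev, scanner = scanner, model = model,
      stats = list(nGenerated = nGen, nGap = nGap, nAxial = nAxial,
                   seed = if (is.null(seed)) NA_integer_ else seed,
                   mode = mode,
                   acceptance = nDet / nGen))
}

#' Histogram of the acollinearity magnitude
#'
#' Bins the per-event 3D acollinearity magnitude theta (the quantity the
#' standard simulator benchmark histograms) in degrees.
#'
#' @param cl a \code{\link{CoincidenceList-class}} with debug fields, or a
#'   numeric vector of theta values in radians.
#' @param binWidthDeg bin width in degrees.
#' @return data.frame with columns binCenterDeg, count.
#' @export
thetaHistogram <- function(cl, binWidthDeg = 0.02) {
  theta <- if (is(cl, "CoincidenceList")) {
    if (is.null(cl@events$theta))
      stop("theta was not retained; simulate with keepDebug = TRUE")
    cl@events$theta
  } else cl
  deg <- theta * 180 / pi
  nb <- max(1L, ceiling(max(deg) / binWidthDeg + 1e-9))
  breaks <- seq(0, nb * binWidthDeg, by = binWidthDeg)
  cnt <- tabulate(findInterval(deg, breaks, rightmost.closed = TRUE,
                               left.open = FALSE), nbins = nb)
  data.frame(binCenterDeg = breaks[-1] - binWidthDeg / 2, count = cnt)
}

#' Aggregate list-mode events into per-LOR counts
#'
#' @param cl a \code{\link{CoincidenceList-class}} object.
#' @param sm a \code{\link{SystemMatrix-class}} whose LOR rows define the
#'   count vector ordering.
#' @return numeric vector of counts, one per system-matrix LOR. Events on
#'   LORs outside the system matrix are dropped with a warning.
#' @export
lorCounts <- function(cl, sm) {
  nc <- nCrystals(cl@scanner)
  key <- cl@events$idA * nc + cl@events$idB
  smKey <- sm@lors[, 1] * nc + sm@lors[, 2]
  idx <- match(key, smKey)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " events on LORs outside the system matrix")
  tab <- tabulate(idx[!is.na(idx)], nbins = length(smKey))
  as.numeric(tab)
}
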