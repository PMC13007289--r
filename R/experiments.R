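# End-to-end imaging experiments: point-source PSF study and hot-spot
# resolvability study on the 40-sided ring.

# uniform disk raster (value 1 inside), supersampled at spot edges
.diskImage <- function(nx, ny, pixelSize, radius, supersample = 4L) {
  origin <- -c(nx - 1, ny - 1) / 2 * pixelSize
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * pixelSize
  vals <- matrix(0, nx, ny)
  xc <- origin[1] + (seq_len(nx) - 1) * pixelSize
  yc <- origin[2] + (seq_len(ny) - 1) * pixelSize
  for (ox in off) for (oy in off) {
    gx <- matrix(xc + ox, nx, ny)
    gy <- matrix(yc + oy, nx, ny, byrow = TRUE)
    vals <- vals + (gx^2 + gy^2 <= radius^2)
  }
  activityImage(vals / supersample^2, pixelSize, origin)
}

#' Point-source resolution experiment
#'
#' Simulates true coincidences from a geometric point at
#' [0.15625, 0.15625] mm, adds a noiseless uniform-disk background to the
#' LOR data (scaled from the sensitivity at the point pixel so that the
#' converged point-to-background intensity ratio is below 110 percent, the
#' validity condition for ML-EM resolution measurements), reconstructs with
#' ML-EM, and measures the central-row point response: a fitted Gaussian
#' FWHM and the half-maximum crossing width.
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param nCoincidences point-source true coincidences to record.
#' @param nIter ML-EM iterations.
#' @param seed integer seed.
#' @param pixelSize reconstruction pixel in mm.
#' @param nGrid grid size (nGrid x nGrid pixels).
#' @param fovRadius background-disk radius in mm.
#' @param maxPeakShare assumed upper bound on the fraction of point
#'   activity landing in one pixel, used to scale the background so the
#'   110 percent condition holds with margin.
#' @param storeEvery trajectory decimation.
#' @return list: fwhmGaussFit, fwhmHalfMax (mm), peakBgRatio (converged
#'   point-pixel over local background), profile (data.frame x, value),
#'   background (estimated recon background level), recon, sim stats.
#' @export
pointSourceExperiment <- function(model, scanner = ringScanner(),
                                  nCoincidences = 1e5, nIter = 2000,
                                  seed = 1, pixelSize = 0.3125,
                                  nGrid = 64L, fovRadius = 10,
                                  maxPeakShare = 0.5, storeEvery = 500L) {
  phantom <- pointPhantom(fovRadius = fovRadius, bgFraction = 0)
  cl <- simulateCoincidences(nCoincidences, model, phantom, scanner,
                             seed = seed, mode = "in_plane",
                             keepDebug = FALSE)
  lors <- enumerateLors(scanner, fovRadius + 0.5)
  sm <- buildSystemMatrix(scanner, lors, nGrid, nGrid, pixelSize)
  y <- lorCounts(cl, sm)

  # noiseless background in data space
  disk <- .diskImage(nGrid, nGrid, pixelSize, fovRadius)
  s <- sensitivity(sm)
  pij <- round((phantom@point - sm@origin) / pixelSize) + 1
  pidx <- pij[1] + (pij[2] - 1) * nGrid
  bgLevel <- maxPeakShare * nCoincidences / s[pidx] / 0.1
  y <- y + bgLevel * forwardProject(sm, disk)

  recon <- mlem(sm, y, nIter = nIter, storeEvery = storeEvery)
  img <- recon@image
  x <- sm@origin[1] + (seq_len(nGrid) - 1) * pixelSize
  prof <- img[, pij[2]]
  px <- phantom@point[1]
  wing <- abs(x - px) >= 4 & abs(x - px) <= 8
  bg <- median(prof[wing])
  keep <- abs(x - px) <= 8
  gf <- fitGaussianProfile(x[keep], prof[keep], background = NULL)
  fwhmHm <- profileFwhm(prof[keep], background = bg, x = x[keep])
  list(fwhmGaussFit = gf$fwhm,
       fwhmHalfMax = fwhmHm,
       peakBgRatio = img[pij[1], pij[2]] / bg,
       profile = data.frame(x = x, value = prof),
       background = bg,
       gaussFit = gf,
       recon = recon,
       stats = cl@stats)
}

#' Hot-spot resolvability experiment
#'
#' Simulates a sectored hot-spot phantom, reconstructs with ML-EM, selects
#' the iterate with the lowest mean squared error against the ground truth,
#' and scores Rayleigh-criterion resolvability per spot diameter.
#'
#' @param model an \code{\link{ApaModel-class}} object.
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param nCoincidences coincidences to record.
#' @param phantomRadius phantom disk radius in mm.
#' @param diameters spot diameters in mm.
#' @param nIter,storeEvery ML-EM iterations and trajectory decimation.
#' @param seed integer seed.
#' @param pixelSize reconstruction pixel in mm.
#' @return list: resolvability (data.frame), optIteration, mse
#'   (data.frame), image (the selected \code{ActivityImage}), recon,
#'   truth, spec, sim stats.
#' @export
hotSpotExperiment <- function(model, scanner = ringScanner(),
                              nCoincidences = 1e6, phantomRadius = 20,
                              diameters = c(0.5, 0.9, 1.3, 1.7, 2.1, 2.5),
                              nIter = 250, storeEvery = 10L, seed = 1,
                              pixelSize = 0.3125) {
  spec <- hotSpotPhantom(diameters = diameters, ratio = 4,
                         phantomRadius = phantomRadius)
  cl <- simulateCoincidences(nCoincidences, model, spec, scanner,
                             seed = seed, mode = "in_plane",
                             keepDebug = FALSE)
  nGrid <- 2L * ceiling((phantomRadius + 2) / pixelSize) + 2L
  lors <- enumerateLors(scanner, phantomRadius + 3)
  sm <- buildSystemMatrix(scanner, lors, nGrid, nGrid, pixelSize)
  y <- lorCounts(cl, sm)
  recon <- mlem(sm, y, nIter = nIter, storeEvery = storeEvery)
  truth <- groundTruth(spec, pixelSize, nx = nGrid, ny = nGrid)
  opt <- mseOptimalIteration(recon, truth)
  img <- reconImageAt(recon, opt$iteration)
  res <- resolvability(img, spec)
  list(resolvability = res, optIteration = opt$iteration, mse = opt$mse,
       image = img, recon = recon, truth = truth, spec = spec,
       stats = cl@stats)
}
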