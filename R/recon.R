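# Geometric 2D ML-EM reconstruction: Siddon intersection-length system
# matrix on crystal-center chords, multiplicative EM updates, and MSE-based
# iteration selection.

#' Build a Siddon system matrix
#'
#' Row i holds the intersection lengths (mm) of LOR i's crystal-center
#' chord with every pixel of a square grid centered on the scanner axis.
#'
#' @param scanner a \code{\link{RingScanner-class}} object.
#' @param lors integer matrix (idA, idB), e.g. from
#'   \code{\link{enumerateLors}}.
#' @param nx,ny grid dimensions in pixels.
#' @param pixelSize pixel width in mm.
#' @return a \code{\link{SystemMatrix-class}} object.
#' @export
buildSystemMatrix <- function(scanner, lors, nx, ny, pixelSize) {
  stopifnot(is(scanner, "RingScanner"), ncol(lors) == 2)
  nx <- as.integer(nx); ny <- as.integer(ny)
  C <- crystalCenters(scanner)
  a <- C[lors[, 1] + 1L, , drop = FALSE]
  b <- C[lors[, 2] + 1L, , drop = FALSE]
  origin <- -c(nx - 1, ny - 1) / 2 * pixelSize
  gx0 <- origin[1] - pixelSize / 2
  gy0 <- origin[2] - pixelSize / 2
  csc <- .siddonCsc(a[, 1], a[, 2], b[, 1], b[, 2],
                    nx, ny, pixelSize, gx0, gy0)
  At <- new("dgCMatrix", i = csc$i, p = csc$p, x = csc$x,
            Dim = c(nx * ny, nrow(lors)))
  lors <- as.matrix(lors)
  storage.mode(lors) <- "integer"
  new("SystemMatrix", At = At, lors = lors, nx = nx, ny = ny,
      pixelSize = pixelSize, origin = origin, scanner = scanner)
}

#' Forward and back projection
#'
#' \code{forwardProject} maps an image to expected per-LOR line integrals;
#' \code{backProject} applies the transpose.
#'
#' @param sm a \code{\link{SystemMatrix-class}} object.
#' @param img an \code{\link{ActivityImage-class}}, matrix, or pixel vector.
#' @return numeric vector (per LOR / per pixel).
#' @export
forwardProject <- function(sm, img) {
  x <- if (is(img, "ActivityImage")) as.vector(img@values)
       else as.vector(img)
  if (length(x) != nrow(sm@At)) stop("image does not match grid")
  as.vector(Matrix::crossprod(sm@At, x))
}

#' @rdname forwardProject
#' @param y numeric per-LOR vector.
#' @export
backProject <- function(sm, y) {
  if (length(y) != ncol(sm@At)) stop("counts do not match LOR set")
  as.vector(sm@At %*% y)
}

#' Per-pixel sensitivity (backprojection of ones)
#' @param sm a \code{\link{SystemMatrix-class}} object.
#' @return numeric vector of column sums of the system matrix.
#' @export
sensitivity <- function(sm) as.vector(Matrix::rowSums(sm@At))

#' Per-LOR chord length inside the grid
#' @rdname sensitivity
#' @export
chordLengths <- function(sm) as.vector(Matrix::colSums(sm@At))

#' ML-EM reconstruction
#'
#' Standard multiplicative Poisson EM update
#' x <- (x / s) * A^T (y / (A x)), initialized uniform on the pixels with
#' positive sensitivity; zero-sensitivity pixels are masked to zero. A small
#' epsilon guards empty forward projections. The Poisson log-likelihood is
#' non-decreasing over iterations.
#'
#' @param sm a \code{\link{SystemMatrix-class}} object.
#' @param counts nonnegative per-LOR data (real-valued allowed, e.g. with a
#'   noiseless background added in data space).
#' @param nIter iterations to run.
#' @param storeEvery store every storeEvery-th iterate (plus the last).
#' @param eps forward-projection guard.
#' @return a \code{\link{ReconResult-class}} object.
#' @export
mlem <- function(sm, counts, nIter, storeEvery = 10L, eps = 1e-12) {
  stopifnot(is(sm, "SystemMatrix"))
  if (length(counts) != ncol(sm@At)) stop("counts do not match LOR set")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("all-zero counts")
  s <- sensitivity(sm)
  res <- .mlemCsc(sm@At@p, sm@At@i, sm@At@x, nrow(sm@At),
                  as.numeric(counts), s, as.integer(nIter),
                  as.integer(storeEvery), eps)
  new("ReconResult",
      image = matrix(res$x, sm@nx, sm@ny),
      trajectory = res$trajectory,
      trajIterations = as.integer(res$iterations),
      loglik = res$loglik, nIter = as.integer(nIter),
      pixelSize = sm@pixelSize, origin = sm@origin)
}

#' Extract a stored iterate
#'
#' @param recon a \code{\link{ReconResult-class}} object.
#' @param iteration iteration number; must be one of the stored iterations.
#' @return the iterate as an \code{\link{ActivityImage-class}}.
#' @export
reconImageAt <- function(recon, iteration) {
  k <- match(iteration, recon@trajIterations)
  if (is.na(k)) stop("iteration ", iteration, " was not stored")
  nx <- nrow(recon@image)
  activityImage(matrix(recon@trajectory[, k], nx, ncol(recon@image)),
                recon@pixelSize, recon@origin)
}

#' MSE-optimal iteration
#'
#' Selects, among the stored iterates, the one with the lowest mean squared
#' pixel error against the ground truth. Truth and iterates are both
#' normalized to unit total inside the field of view before comparison.
#'
#' @param recon a \code{\link{ReconResult-class}} object.
#' @param truth an \code{\link{ActivityImage-class}} on the same grid.
#' @return list: \code{iteration} (the argmin), \code{mse} (data.frame of
#'   iteration and mse over the stored trajectory).
#' @export
mseOptimalIteration <- function(recon, truth) {
  if (length(recon@trajIterations) == 0L) stop("empty trajectory")
  tv <- as.vector(imageValues(truth))
  if (length(tv) != nrow(recon@trajectory))
    stop("truth grid does not match reconstruction grid")
  tv <- tv / sum(tv)
  mse <- vapply(seq_along(recon@trajIterations), function(k) {
    v <- recon@trajectory[, k]
    sv <- sum(v)
    if (sv <= 0) return(Inf)
    mean((v / sv - tv)^2)
  }, numeric(1))
  k <- which.min(mse)
  list(iteration = recon@trajIterations[k],
       mse = data.frame(iteration = recon@trajIterations, mse = mse))
}
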