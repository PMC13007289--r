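#' @importClassesFrom Matrix dgCMatrix
NULL

#' @rdname RingScanner-class
#' @param object,x an object.
#' @export
setGeneric("nCrystals", function(x) standardGeneric("nCrystals"))
#' @rdname RingScanner-class
#' @export
setGeneric("sideWidth", function(x) standardGeneric("sideWidth"))
#' @rdname RingScanner-class
#' @export
setGeneric("circumradius", function(x) standardGeneric("circumradius"))
#' @rdname RingScanner-class
#' @export
setGeneric("inradius", function(x) standardGeneric("inradius"))

#' @rdname ApaModel-class
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))
#' @rdname ApaModel-class
#' @export
setGeneric("acoFwhm", function(x) standardGeneric("acoFwhm"))

#' @rdname CoincidenceList-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname CoincidenceList-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname CoincidenceList-class
#' @export
setGeneric("simStats", function(x) standardGeneric("simStats"))

#' @rdname ActivityImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname ActivityImage-class
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname ActivityImage-class
#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))

#' Sample emission positions from a phantom
#'
#' Positions are distributed proportionally to the phantom's activity
#' density, using exact mixture sampling (no rejection): for the point
#' phantom a Bernoulli split between the point and the uniform disk, for the
#' hot-spot phantom a mixture of the uniform disk and the excess-activity
#' spot disks.
#'
#' @param spec a \code{\link{PhantomSpec-class}} object.
#' @param n number of positions. Uses the current RNG state; seed with
#'   \code{set.seed} for reproducibility.
#' @return an n x 2 matrix of mm positions.
#' @export
setGeneric("sampleEmission", function(spec, n) standardGeneric("sampleEmission"))

#' Rasterize a phantom's ground-truth activity
#'
#' @param spec a \code{\link{PhantomSpec-class}} object.
#' @param pixelSize pixel width in mm.
#' @param nx,ny grid dimensions (default: square grid covering the phantom).
#' @param supersample linear subpixel sampling factor for partial-volume
#'   accuracy at spot boundaries.
#' @return an \code{\link{ActivityImage-class}} object.
#' @export
setGeneric("groundTruth",
  function(spec, pixelSize, nx = NULL, ny = NULL, supersample = 8L)
    standardGeneric("groundTruth"))

# -- accessors ---------------------------------------------------------------

#' @rdname RingScanner-class
#' @export
setMethod("nCrystals", "RingScanner",
  function(x) x@nSides * x@crystalsPerSide)
#' @rdname RingScanner-class
#' @export
setMethod("sideWidth", "RingScanner",
  function(x) x@crystalsPerSide * x@crystalWidth)
#' @rdname RingScanner-class
#' @export
setMethod("circumradius", "RingScanner",
  function(x) x@inradius / cos(pi / x@nSides))
#' @rdname RingScanner-class
#' @export
setMethod("inradius", "RingScanner", function(x) x@inradius)

#' @rdname ApaModel-class
#' @export
setMethod("modelKind", "ApaModel", function(x) x@kind)
#' @rdname ApaModel-class
#' @export
setMethod("acoFwhm", "ApaModel", function(x) x@acoFwhmDeg)

#' @rdname CoincidenceList-class
#' @export
setMethod("events", "CoincidenceList", function(x) x@events)
#' @rdname CoincidenceList-class
#' @export
setMethod("nEvents", "CoincidenceList", function(x) nrow(x@events))
#' @rdname CoincidenceList-class
#' @export
setMethod("simStats", "CoincidenceList", function(x) x@stats)

#' @rdname ActivityImage-class
#' @export
setMethod("pixelSize", "ActivityImage", function(x) x@pixelSize)
#' @rdname ActivityImage-class
#' @export
setMethod("imageValues", "ActivityImage", function(x) x@values)
#' @rdname ActivityImage-class
#' @export
setMethod("imageOrigin", "ActivityImage", function(x) x@origin)
#' @rdname ReconResult-class
#' @export
setMethod("pixelSize", "ReconResult", function(x) x@pixelSize)
#' @rdname ReconResult-class
#' @export
setMethod("imageValues", "ReconResult", function(x) x@image)
#' @rdname ReconResult-class
#' @export
setMethod("imageOrigin", "ReconResult", function(x) x@origin)

# -- show methods ------------------------------------------------------------

setMethod("show", "ApaModel", function(object) {
  cat("ApaModel:", object@kind, "with acollinearity FWHM",
      object@acoFwhmDeg, "deg\n")
})

setMethod("show", "RingScanner", function(object) {
  cat(sprintf(
    "RingScanner: %d sides x %d crystals (%g mm), inradius %.2f mm\n",
    object@nSides, object@crystalsPerSide, object@crystalWidth,
    object@inradius))
})

setMethod("show", "PhantomSpec", function(object) {
  if (object@kind == "point_plus_background") {
    cat(sprintf(
      "PhantomSpec: point at [%g, %g] mm over a %g mm disk (bgFraction %g)\n",
      object@point[1], object@point[2], object@fovRadius,
      object@bgFraction))
  } else {
    cat(sprintf(
      "PhantomSpec: hot-spot, diameters %s mm, ratio %g:1, radius %g mm (%d spots)\n",
      paste(object@diameters, collapse = "/"), object@ratio,
      object@phantomRadius, sum(vapply(object@centers, nrow, 1L))))
  }
})

setMethod("show", "ActivityImage", function(object) {
  cat(sprintf("ActivityImage: %d x %d pixels of %g mm, total activity %g\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              sum(object@values)))
})

setMethod("show", "CoincidenceList", function(object) {
  st <- object@stats
  cat(sprintf(
    "CoincidenceList: %d true coincidences (%s, %s), %d generated, %d gap / %d axial discards\n",
    nrow(object@events), object@model@kind, st$mode,
    st$nGenerated, st$nGap, st$nAxial))
})

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf(
    "SystemMatrix: %d LORs x %d pixels (%d x %d at %g mm), %d nonzeros\n",
    ncol(object@At), nrow(object@At), object@nx, object@ny,
    object@pixelSize, length(object@At@x)))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf(
    "ReconResult: %d x %d image at %g mm, %d ML-EM iterations (%d stored)\n",
    nrow(object@image), ncol(object@image), object@pixelSize,
    object@nIter, length(object@trajIterations)))
})

setMethod("show", "ProfileFit", function(object) {
  cat(sprintf("ProfileFit: %s, scale %.5g (FWHM %.5g), rss %.4g%s\n",
              object@family, object@scale, object@fwhm, object@rss,
              if (object@converged) "" else " [not converged]"))
})
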