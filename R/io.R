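# Plain-text/IO formats: list-mode and histogram CSV, flat float32 image
# rasters with JSON sidecars, deviation-sample CSV.

#' Write / read list-mode coincidence CSV
#'
#' One row per coincidence: id_a, id_b and, when present, x_mm, y_mm,
#' theta_rad.
#'
#' @param cl a \code{\link{CoincidenceList-class}} object.
#' @param path output file.
#' @export
writeListmodeCsv <- function(cl, path) {
  ev <- cl@events
  names(ev)[match(c("idA", "idB"), names(ev))] <- c("id_a", "id_b")
  if ("x" %in% names(ev))
    names(ev)[match(c("x", "y", "theta"), names(ev))] <-
      c("x_mm", "y_mm", "theta_rad")
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeListmodeCsv
#' @param scanner,model objects to attach to the read list.
#' @export
readListmodeCsv <- function(path, scanner, model) {
  ev <- utils::read.csv(path)
  names(ev)[match(c("id_a", "id_b"), names(ev))] <- c("idA", "idB")
  if ("x_mm" %in% names(ev))
    names(ev)[match(c("x_mm", "y_mm", "theta_rad"), names(ev))] <-
      c("x", "y", "theta")
  new("CoincidenceList", events = ev, scanner = scanner, model = model,
      stats = list(nGenerated = NA_integer_, nGap = NA_integer_,
                   nAxial = NA_integer_, seed = NA_integer_,
                   mode = "unknown"))
}

#' Write angular-deviation samples as CSV
#'
#' Three columns: phi_rad, psi_rad, theta_rad.
#'
#' @param dev data.frame from \code{\link{sampleDeviation}}.
#' @param path output file.
#' @export
writeDeviationCsv <- function(dev, path) {
  utils::write.csv(setNames(dev, c("phi_rad", "psi_rad", "theta_rad")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a theta histogram as CSV
#'
#' Two columns: bin_center_deg, count.
#'
#' @param hist data.frame from \code{\link{thetaHistogram}}.
#' @param path output file.
#' @export
writeThetaHistogramCsv <- function(hist, path) {
  utils::write.csv(setNames(hist, c("bin_center_deg", "count")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a flat float32 image raster with JSON sidecar
#'
#' The raster is little-endian 32-bit floats in column-major pixel order;
#' the sidecar \code{<path>.json} records dims, pixel size and origin.
#'
#' @param img an \code{\link{ActivityImage-class}} object.
#' @param path output raster file (sidecar written as path.json).
#' @export
writeImageRaster <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(img@values), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(dims = dim(img@values), pixel_size_mm = img@pixelSize,
         origin_mm = img@origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageRaster
#' @export
readImageRaster <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  activityImage(matrix(v, meta$dims[1], meta$dims[2]),
                meta$pixel_size_mm, meta$origin_mm)
}
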