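# Raster and table I/O. Rasters are written as plain (multi-page) TIFF
# with a JSON metadata sidecar; the pipeline's georeferencing is an
# identity affine transform, so no geokeys are needed.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a multiband scene
#'
#' The scene is stored as a multi-page 32-bit float TIFF (one page per
#' band, in configured band order) together with a JSON sidecar carrying
#' the scene metadata (bands, date, sensor, tide, optics, noise, seed).
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param path output path (.tif); the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{writeSceneStack} invisibly returns \code{path};
#'   \code{readSceneStack} returns the reconstructed
#'   \linkS4class{SceneStack}.
#' @export
writeSceneStack <- function(scene, path) {
  stopifnot(is(scene, "SceneStack"))
  cfg <- scene@config
  pages <- lapply(cfg@bands, function(b) scene@reflectance[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    nRows = cfg@nRows, nCols = cfg@nCols, pixelSize = cfg@pixelSize,
    bands = cfg@bands, greenBand = cfg@greenBand, nirBand = cfg@nirBand,
    date = as.character(cfg@date), sensorTag = cfg@sensorTag,
    tideHeight = cfg@tideHeight, kd = cfg@kd, klu = cfg@klu,
    pathOffset = as.list(cfg@pathOffset), noiseSd = cfg@noiseSd,
    seed = cfg@seed)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSceneStack
#' @export
readSceneStack <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cfg <- sceneConfig(
    nRows = meta$nRows, nCols = meta$nCols, pixelSize = meta$pixelSize,
    bands = meta$bands, greenBand = meta$greenBand, nirBand = meta$nirBand,
    date = as.Date(meta$date), sensorTag = meta$sensorTag,
    tideHeight = meta$tideHeight, kd = meta$kd, klu = meta$klu,
    pathOffset = unlist(meta$pathOffset), noiseSd = meta$noiseSd,
    seed = meta$seed)
  refl <- array(0, dim = c(meta$nRows, meta$nCols, length(meta$bands)),
                dimnames = list(NULL, NULL, meta$bands))
  for (i in seq_along(pages)) refl[, , i] <- pages[[i]]
  new("SceneStack", reflectance = refl, config = cfg)
}

#' Write / read an integer-coded grid
#'
#' Class maps, truth class grids and difference maps are written as
#' 8-bit single-page TIFFs of small integer codes (NA stored as 255),
#' with the code legend in the JSON sidecar.
#'
#' @param codes integer matrix of codes in 0..254 (NA allowed).
#' @param path output path (.tif).
#' @param legend named integer vector mapping labels to codes; defaults
#'   to \code{\link{classCodes}}.
#' @return \code{writeCodedGrid} invisibly returns \code{path};
#'   \code{readCodedGrid} returns the integer matrix with the legend in
#'   attribute \code{"legend"}.
#' @export
writeCodedGrid <- function(codes, path, legend = classCodes()) {
  m <- codes
  m[is.na(m)] <- 255L
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(as.list(legend), .sidecarPath(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCodedGrid
#' @export
readCodedGrid <- function(path) {
  m <- round(tiff::readTIFF(path) * 255)
  m[m == 255] <- NA
  mode(m) <- "integer"
  legend <- unlist(jsonlite::read_json(.sidecarPath(path),
                                       simplifyVector = TRUE))
  storage.mode(legend) <- "integer"
  attr(m, "legend") <- legend
  m
}

#' Write / read a real-valued grid
#'
#' LAI grids, DEMs and frequency grids are stored as 32-bit float TIFF,
#' rescaled to [0, 1] with the scale and NA sentinel recorded in the
#' sidecar, so values round-trip to float precision.
#'
#' @param values numeric matrix (NA allowed).
#' @param path output path (.tif).
#' @return \code{writeValueGrid} invisibly returns \code{path};
#'   \code{readValueGrid} returns the numeric matrix.
#' @export
writeValueGrid <- function(values, path) {
  finite <- is.finite(values)
  lo <- if (any(finite)) min(values[finite]) else 0
  hi <- if (any(finite)) max(values[finite]) else 1
  scale <- max(hi - lo, 1e-30)
  m <- (values - lo) / scale
  m[!finite] <- 1 # sentinel written past the data range flag in sidecar
  tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(lo = lo, scale = scale,
                            na = which(!finite) - 1L),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeValueGrid
#' @export
readValueGrid <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale + meta$lo
  if (length(meta$na)) m[meta$na + 1L] <- NA_real_
  m
}

#' Write / read a covariate table
#'
#' Plain CSV with header \code{year,season,enso,nao,sst}.
#'
#' @param covariates data.frame as from \code{\link{simulateCovariates}}.
#' @param path CSV path.
#' @return \code{writeCovariates} invisibly returns \code{path};
#'   \code{readCovariates} returns the data.frame.
#' @export
writeCovariates <- function(covariates, path) {
  need <- c("year", "season", "enso", "nao", "sst")
  stopifnot(all(need %in% names(covariates)))
  utils::write.csv(covariates[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCovariates
#' @export
readCovariates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
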