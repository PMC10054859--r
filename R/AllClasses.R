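#' @import methods
NULL

# ---------------------------------------------------------------- SceneConfig

#' Scene configuration
#'
#' Holds everything the synthetic-scene generators need: grid geometry,
#' band layout, acquisition metadata (date, sensor, tide), water-column
#' optics at 560 nm, the additive atmospheric path offset, sensor noise,
#' and the knobs controlling the generated bathymetry and seagrass field.
#'
#' @slot nRows,nCols integer grid size in pixels (>= 8 each).
#' @slot pixelSize numeric, pixel edge length in metres (default 30).
#' @slot bands character, ordered band identifiers.
#' @slot greenBand,nirBand character, which entries of \code{bands} are the
#'   green (560 nm) and near-infrared bands.
#' @slot date acquisition date.
#' @slot sensorTag free-text sensor label.
#' @slot tideHeight numeric, tide height above the bathymetric datum (m).
#' @slot kd,klu numeric, downwelling/upwelling diffuse attenuation
#'   coefficients at 560 nm (1/m), both > 0.
#' @slot pathOffset numeric, per-band additive atmospheric path reflectance
#'   (recycled across bands), all >= 0.
#' @slot noiseSd numeric >= 0, Gaussian sensor noise (reflectance units).
#' @slot seed integer, master seed; equal seeds give bit-identical scenes.
#' @slot demShape one of \code{"coast"}, \code{"constant"},
#'   \code{"gradient"} selecting the bathymetry template.
#' @slot demDepth numeric, depth for the \code{"constant"} template (m).
#' @slot shelfDepthRange numeric length 2, depth span of the vegetated
#'   shelf (m).
#' @slot basinDepth numeric, depth of the optically-deep basin (m).
#' @slot classTargets named numeric, target areal fractions for
#'   \code{land}, \code{intertidal} and \code{deep_water}; the remainder is
#'   shallow shelf.
#' @slot seagrassFraction numeric in [0, 1], fraction of the shelf
#'   occupied by seagrass (the rest is submerged sand).
#' @slot laiMean numeric, target mean LAI of the seagrass field.
#' @slot laiMax numeric, upper clip for the LAI field.
#' @slot laiConstant numeric, when finite overrides the smooth LAI field
#'   with a uniform value (NA = smooth field).
#' @slot separation numeric > 0, multiplier on the contrast between class
#'   mean spectra (1 = library defaults).
#' @export
setClass("SceneConfig", representation(
  nRows = "integer", nCols = "integer", pixelSize = "numeric",
  bands = "character", greenBand = "character", nirBand = "character",
  date = "Date", sensorTag = "character", tideHeight = "numeric",
  kd = "numeric", klu = "numeric", pathOffset = "numeric",
  noiseSd = "numeric", seed = "integer",
  demShape = "character", demDepth = "numeric",
  shelfDepthRange = "numeric", basinDepth = "numeric",
  classTargets = "numeric", seagrassFraction = "numeric",
  laiMean = "numeric", laiMax = "numeric", laiConstant = "numeric",
  separation = "numeric"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nRows < 8L || object@nCols < 8L)
    msg <- c(msg, "grid must be at least 8 x 8 pixels")
  if (object@kd <= 0) msg <- c(msg, "kd must be > 0")
  if (object@klu <= 0) msg <- c(msg, "klu must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@pathOffset < 0)) msg <- c(msg, "pathOffset must be >= 0")
  if (!(object@greenBand %in% object@bands))
    msg <- c(msg, "greenBand must be one of bands")
  if (!(object@nirBand %in% object@bands))
    msg <- c(msg, "nirBand must be one of bands")
  if (!all(c("land", "intertidal", "deep_water") %in%
           names(object@classTargets)))
    msg <- c(msg, "classTargets needs land, intertidal, deep_water entries")
  if (sum(object@classTargets) >= 1)
    msg <- c(msg, "classTargets must leave room for the shelf (sum < 1)")
  if (object@seagrassFraction < 0 || object@seagrassFraction > 1)
    msg <- c(msg, "seagrassFraction must lie in [0, 1]")
  if (object@separation <= 0) msg <- c(msg, "separation must be > 0")
  if (length(object@shelfDepthRange) != 2 ||
      diff(object@shelfDepthRange) < 0)
    msg <- c(msg, "shelfDepthRange must be an increasing length-2 vector")
  if (length(msg)) msg else TRUE
})

#' Build a scene configuration
#'
#' Defaults describe the study conditions the pipeline targets: a 30 m
#' pixel, six reflective bands with a designated green and NIR band,
#' long-term mean optics kd = 0.734 1/m (klu derived as kd / 2 pi), mean
#' tide 0.24 m, a shallow vegetated shelf around 0.2--1.8 m deep next to a
#' 6.4 m basin, and a seagrass field with mean LAI 1.6.
#'
#' @param nRows,nCols grid size in pixels.
#' @param pixelSize pixel edge length (m).
#' @param bands ordered band names.
#' @param greenBand,nirBand names of the green and NIR bands.
#' @param date acquisition date.
#' @param sensorTag sensor label.
#' @param tideHeight tide height (m).
#' @param kd downwelling diffuse attenuation at 560 nm (1/m).
#' @param klu upwelling diffuse attenuation (1/m); defaults to kd / 2 pi.
#' @param pathOffset per-band additive path reflectance.
#' @param noiseSd Gaussian sensor noise sd (reflectance units).
#' @param seed master integer seed.
#' @param demShape bathymetry template.
#' @param demDepth constant-template depth (m).
#' @param shelfDepthRange shelf depth span (m).
#' @param basinDepth basin depth (m).
#' @param classTargets target fractions for land/intertidal/deep_water.
#' @param seagrassFraction seagrass fraction of the shelf.
#' @param laiMean target mean LAI under seagrass.
#' @param laiMax LAI clip ceiling.
#' @param laiConstant uniform LAI override (NA for a smooth field).
#' @param separation class-spectra contrast multiplier.
#' @return A \linkS4class{SceneConfig}.
#' @export
#' @examples
#' cfg <- sceneConfig(nRows = 32, nCols = 32, seed = 1)
#' cfg
sceneConfig <- function(nRows = 96L, nCols = 96L, pixelSize = 30,
                        bands = c("blue", "green", "red", "nir",
                                  "swir1", "swir2"),
                        greenBand = "green", nirBand = "nir",
                        date = as.Date("2010-11-19"), sensorTag = "SYN",
                        tideHeight = 0.24, kd = 0.734,
                        klu = kd / (2 * pi),
                        pathOffset = 0.01, noiseSd = 0.002, seed = 1L,
                        demShape = c("coast", "constant", "gradient"),
                        demDepth = 1.0, shelfDepthRange = c(0.2, 1.8),
                        basinDepth = 6.4,
                        classTargets = c(land = 0.12, intertidal = 0.05,
                                         deep_water = 0.38),
                        seagrassFraction = 5 / 9, laiMean = 1.6,
                        laiMax = 4, laiConstant = NA_real_,
                        separation = 1) {
  demShape <- match.arg(demShape)
  pathOffset <- rep_len(pathOffset, length(bands))
  names(pathOffset) <- bands
  new("SceneConfig", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pixelSize = pixelSize, bands = bands, greenBand = greenBand,
      nirBand = nirBand, date = as.Date(date), sensorTag = sensorTag,
      tideHeight = tideHeight, kd = kd, klu = klu,
      pathOffset = pathOffset, noiseSd = noiseSd, seed = as.integer(seed),
      demShape = demShape, demDepth = demDepth,
      shelfDepthRange = shelfDepthRange, basinDepth = basinDepth,
      classTargets = classTargets, seagrassFraction = seagrassFraction,
      laiMean = laiMean, laiMax = laiMax, laiConstant = laiConstant,
      separation = separation)
}

# ------------------------------------------------------------------ TruthMaps

#' Ground-truth maps for a synthetic scene
#'
#' @slot classGrid integer matrix of class codes (see \code{\link{classCodes}}).
#' @slot laiGrid numeric matrix; LAI >= 0, nonzero only under seagrass.
#' @slot dem numeric matrix of water depth (m, positive down); NA over land.
#' @export
setClass("TruthMaps", representation(
  classGrid = "matrix", laiGrid = "matrix", dem = "matrix"))

setValidity("TruthMaps", function(object) {
  msg <- character()
  if (!identical(dim(object@classGrid), dim(object@laiGrid)) ||
      !identical(dim(object@classGrid), dim(object@dem)))
    msg <- c(msg, "classGrid, laiGrid and dem must share one shape")
  sg <- object@classGrid == .codeOf("seagrass")
  if (any(object@laiGrid[!sg] != 0))
    msg <- c(msg, "laiGrid must be 0 wherever class is not seagrass")
  if (any(object@laiGrid < 0))
    msg <- c(msg, "laiGrid must be >= 0")
  if (any(is.na(object@dem) & object@classGrid != .codeOf("land")))
    msg <- c(msg, "depth may be absent only over land")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------------ SceneStack

#' Multiband reflectance scene
#'
#' The pipeline's raster currency: a rows x cols x bands array of surface
#' reflectance plus the generating/acquisition configuration.
#'
#' @slot reflectance 3-D numeric array, dimnames on the band axis.
#' @slot config the \linkS4class{SceneConfig} echo.
#' @export
setClass("SceneStack", representation(
  reflectance = "array", config = "SceneConfig"))

setValidity("SceneStack", function(object) {
  msg <- character()
  d <- dim(object@reflectance)
  if (length(d) != 3) msg <- c(msg, "reflectance must be rows x cols x bands")
  if (!identical(dimnames(object@reflectance)[[3]], object@config@bands))
    msg <- c(msg, "band axis dimnames must match config bands")
  if (any(!is.finite(object@reflectance)))
    msg <- c(msg, "reflectance must be finite")
  if (any(object@reflectance < 0))
    msg <- c(msg, "reflectance must be >= 0")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------------- ROISet

#' Homogeneous training regions of interest
#'
#' Rectangular, spatially homogeneous regions, 3--6 per class, mutually
#' disjoint; the sampling frame for classifier training.
#'
#' @slot table data.frame with columns roi, class, row0, col0, h, w
#'   (top-left corner and extent, 1-based).
#' @slot gridDim integer length 2, the grid the ROIs index into.
#' @export
setClass("ROISet", representation(table = "data.frame", gridDim = "integer"))

setValidity("ROISet", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("roi", "class", "row0", "col0", "h", "w")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "table must have roi, class, row0, col0, h, w")
  else {
    counts <- table(tab$class)
    if (any(counts < 3 | counts > 6))
      msg <- c(msg, "each class needs 3-6 regions")
    if (any(tab$row0 < 1 | tab$col0 < 1 |
            tab$row0 + tab$h - 1 > object@gridDim[1] |
            tab$col0 + tab$w - 1 > object@gridDim[2]))
      msg <- c(msg, "regions must lie inside the grid")
  }
  if (length(msg)) msg else TRUE
})

# ----------------------------------------------------------------- DarkOffset

#' Dark-object subtraction offsets
#'
#' @slot offsets named numeric, per-band path offsets (>= 0).
#' @slot darkPixel integer (row, col) of the dark pixel.
#' @slot sourceBand band used to locate the dark pixel (the NIR band).
#' @export
setClass("DarkOffset", representation(
  offsets = "numeric", darkPixel = "integer", sourceBand = "character"))

setValidity("DarkOffset", function(object) {
  if (any(!is.finite(object@offsets)) || any(object@offsets < 0))
    "offsets must be finite and >= 0" else TRUE
})

# -------------------------------------------------------- TrainingSet / model

#' Per-pixel training set
#'
#' @slot spectra numeric matrix, samples x bands.
#' @slot labels factor of class labels, one per row of spectra.
#' @export
setClass("TrainingSet", representation(spectra = "matrix", labels = "factor"))

setValidity("TrainingSet", function(object) {
  msg <- character()
  if (nrow(object@spectra) != length(object@labels))
    msg <- c(msg, "one label per spectrum required")
  if (any(!is.finite(object@spectra)))
    msg <- c(msg, "spectra must be finite")
  if (length(msg)) msg else TRUE
})

#' Fitted per-pixel classifier
#'
#' Wraps the fitted network together with the band layout, class levels,
#' the training configuration and a short training log.
#'
#' @slot fit the fitted \code{nnet} object.
#' @slot bands character, band order the model expects.
#' @slot levels character, class labels in code order.
#' @slot config list of training hyperparameters (size, decay, maxit, seed).
#' @slot log list; includes trainAccuracy and, when a held-out set was
#'   supplied, heldoutAccuracy.
#' @export
setClass("ClassifierModel", representation(
  fit = "ANY", bands = "character", levels = "character",
  config = "list", log = "list"))

# ------------------------------------------------------------------- ClassMap

#' Per-pixel class map
#'
#' @slot codes integer matrix of class codes 0..4.
#' @slot masked logical matrix; TRUE where a pixel is excluded (e.g. by the
#'   optically-deep depth mask) from downstream area accounting.
#' @export
setClass("ClassMap", representation(codes = "matrix", masked = "matrix"))

setValidity("ClassMap", function(object) {
  msg <- character()
  if (!identical(dim(object@codes), dim(object@masked)))
    msg <- c(msg, "codes and masked must share one shape")
  if (!all(object@codes %in% 0:4))
    msg <- c(msg, "codes must lie in 0..4")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------- ExtentResult

#' Seagrass areal extent
#'
#' @slot nPixels integer, unmasked seagrass pixel count.
#' @slot areaKm2 numeric, nPixels x pixelSize^2 x 1e-6.
#' @slot pixelSize numeric (m).
#' @export
setClass("ExtentResult", representation(
  nPixels = "numeric", areaKm2 = "numeric", pixelSize = "numeric"))

setValidity("ExtentResult", function(object) {
  ok <- abs(object@areaKm2 -
            object@nPixels * object@pixelSize^2 * 1e-6) < 1e-9
  if (!ok) "areaKm2 must equal nPixels * pixelSize^2 * 1e-6" else TRUE
})

# ------------------------------------------------------------- BandImportance

#' Shapley band attribution
#'
#' @slot percent named numeric, per-band percent contribution (sums to 100).
#' @slot meanAbs named numeric, mean absolute per-sample Shapley value.
#' @slot phi numeric matrix, per-sample Shapley values (samples x bands).
#' @slot baseValue numeric, model value at the all-background input.
#' @slot method attribution method tag.
#' @export
setClass("BandImportance", representation(
  percent = "numeric", meanAbs = "numeric", phi = "matrix",
  baseValue = "numeric", method = "character"))

setValidity("BandImportance", function(object) {
  msg <- character()
  if (any(object@percent < -1e-9)) msg <- c(msg, "percentages must be >= 0")
  if (abs(sum(object@percent) - 100) > 1e-6)
    msg <- c(msg, "percentages must sum to 100")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------ optics / carbon

#' Water-column optics for one scene
#'
#' @slot kd,klu numeric 1/m at 560 nm, both > 0.
#' @slot date acquisition date.
#' @export
setClass("OpticsRecord", representation(
  kd = "numeric", klu = "numeric", date = "Date"))

setValidity("OpticsRecord", function(object) {
  if (object@kd <= 0 || object@klu <= 0) "kd and klu must be > 0" else TRUE
})

#' @rdname OpticsRecord-class
#' @param kd downwelling diffuse attenuation (1/m).
#' @param klu upwelling diffuse attenuation (1/m), default kd / 2 pi.
#' @param date acquisition date.
#' @return An \linkS4class{OpticsRecord}.
#' @export
opticsRecord <- function(kd, klu = kluFromKd(kd), date = Sys.Date()) {
  new("OpticsRecord", kd = kd, klu = klu, date = as.Date(date))
}

#' Log-linear LAI inversion coefficients
#'
#' The retrieval model is LAI = max(a + b * ln(Rb) + c, 0) with b < 0 (LAI
#' decreases as the bottom brightens). The additive term c carries the
#' cross-sensor brightness correction estimated by
#' \code{\link{calibrateOffset}}.
#'
#' @slot a intercept.
#' @slot b slope per ln(Rb), strictly negative.
#' @slot c additive offset correction.
#' @export
setClass("LAICoefficients", representation(
  a = "numeric", b = "numeric", c = "numeric"))

setValidity("LAICoefficients", function(object) {
  if (object@b >= 0) "slope b must be negative" else TRUE
})

#' @rdname LAICoefficients-class
#' @param a intercept (default -0.8).
#' @param b slope per ln(Rb), must be < 0 (default -1.6). The defaults map
#'   bottom reflectance in roughly (0.06, 0.6) onto LAI in [0, 4].
#' @param c additive offset correction (default 0).
#' @return A \linkS4class{LAICoefficients}.
#' @export
laiCoefficients <- function(a = -0.8, b = -1.6, c = 0) {
  new("LAICoefficients", a = a, b = b, c = c)
}

#' Per-pixel LAI grid
#'
#' @slot lai numeric matrix, LAI (unitless) on valid pixels, NA elsewhere.
#' @slot valid logical matrix of pixels with a defined retrieval.
#' @export
setClass("LAIGrid", representation(lai = "matrix", valid = "matrix"))

setValidity("LAIGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@lai), dim(object@valid)))
    msg <- c(msg, "lai and valid must share one shape")
  if (any(object@lai[object@valid] < 0, na.rm = TRUE))
    msg <- c(msg, "LAI must be >= 0 on valid pixels")
  if (length(msg)) msg else TRUE
})

#' Biomass and carbon aggregates
#'
#' Bay-integrated totals from the LAI-to-carbon transfer chain:
#' fresh biomass = 500 g m-2 per unit LAI, dry = 0.2 x fresh, aboveground
#' carbon = 0.34 x dry, belowground carbon = 3 x aboveground (the 1:3
#' aboveground:belowground biomass ratio), total = aboveground +
#' belowground. Totals in Gg; bgcDensity in g C m-2.
#'
#' @slot freshGg,dryGg,agCarbonGg,bgCarbonGg,totalCarbonGg numeric totals (Gg).
#' @slot bgcDensity numeric, mean belowground carbon density (g C m-2).
#' @slot meanLai numeric, mean LAI over seagrass pixels.
#' @slot areaKm2 numeric, seagrass area used for the integration.
#' @export
setClass("CarbonSummary", representation(
  freshGg = "numeric", dryGg = "numeric", agCarbonGg = "numeric",
  bgCarbonGg = "numeric", totalCarbonGg = "numeric",
  bgcDensity = "numeric", meanLai = "numeric", areaKm2 = "numeric"))

setValidity("CarbonSummary", function(object) {
  msg <- character()
  rel <- function(x, y) abs(x - y) <= 1e-9 * max(1, abs(y))
  if (!rel(object@dryGg, 0.2 * object@freshGg))
    msg <- c(msg, "dry biomass must be 0.2 x fresh")
  if (!rel(object@agCarbonGg, 0.34 * object@dryGg))
    msg <- c(msg, "aboveground carbon must be 0.34 x dry")
  if (!rel(object@bgCarbonGg, 3 * object@agCarbonGg))
    msg <- c(msg, "belowground carbon must be 3 x aboveground")
  if (!rel(object@totalCarbonGg, object@agCarbonGg + object@bgCarbonGg))
    msg <- c(msg, "total carbon must be aboveground + belowground")
  if (any(c(object@freshGg, object@dryGg, object@agCarbonGg,
            object@bgCarbonGg, object@totalCarbonGg) < 0))
    msg <- c(msg, "carbon quantities must be >= 0")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------------- trends

#' Trend statistics for one annual series
#'
#' @slot tau Kendall's tau in [-1, 1].
#' @slot pValue two-sided p from the tie-corrected normal approximation.
#' @slot senSlope Theil-Sen slope (metric units per year).
#' @slot percentChange percent change per year, 100 x slope / mean.
#' @slot gammaYears years of record needed for the trend to emerge from the
#'   noise; NA (undefined) when the slope is exactly 0.
#' @slot strengthLabel one of none/weak/moderate/strong.
#' @slot n number of observations.
#' @export
setClass("TrendResult", representation(
  tau = "numeric", pValue = "numeric", senSlope = "numeric",
  percentChange = "numeric", gammaYears = "numeric",
  strengthLabel = "character", n = "integer"))

setValidity("TrendResult", function(object) {
  msg <- character()
  if (is.finite(object@tau) && abs(object@tau) > 1 + 1e-12)
    msg <- c(msg, "|tau| must be <= 1")
  if (is.finite(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-pixel seagrass frequency grid
#'
#' @slot freq numeric matrix in [0, 1]: fraction of co-valid scenes in
#'   which the pixel was classified seagrass.
#' @slot nScenes integer matrix, per-pixel denominator (unmasked scenes).
#' @slot nStack integer, scenes in the stack.
#' @export
setClass("FrequencyGrid", representation(
  freq = "matrix", nScenes = "matrix", nStack = "integer"))

setValidity("FrequencyGrid", function(object) {
  f <- object@freq
  if (any(f < 0 | f > 1, na.rm = TRUE))
    "frequencies must lie in [0, 1]" else TRUE
})

#' Multiple linear regression summary
#'
#' @slot coefficients data.frame with term, beta, se, t, p.
#' @slot adjR2 adjusted r-squared.
#' @slot n observations used.
#' @export
setClass("MLRResult", representation(
  coefficients = "data.frame", adjR2 = "numeric", n = "integer"))

# ------------------------------------------------------------------ agreement

#' Paired presence/absence confusion table
#'
#' Counts over co-valid pixels: a = both present, b = A only, c = B only,
#' d = both absent.
#'
#' @slot a,b,c,d numeric cell counts (>= 0).
#' @export
setClass("ConfusionTable", representation(
  a = "numeric", b = "numeric", c = "numeric", d = "numeric"))

setValidity("ConfusionTable", function(object) {
  if (any(c(object@a, object@b, object@c, object@d) < 0))
    "counts must be >= 0" else TRUE
})

#' @rdname ConfusionTable-class
#' @param a,b,c,d cell counts.
#' @return A \linkS4class{ConfusionTable}.
#' @export
confusionCounts <- function(a, b, c, d) {
  new("ConfusionTable", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

#' Map-agreement metric suite
#'
#' @slot presence,absence named numeric: precision, recall, f. Undefined
#'   ratios (zero denominators) are NA, never silently 0.
#' @slot overallAccuracy numeric in [0, 1].
#' @slot kappa chance-corrected agreement in [-1, 1].
#' @slot n co-valid pixel count.
#' @export
setClass("AgreementReport", representation(
  presence = "numeric", absence = "numeric",
  overallAccuracy = "numeric", kappa = "numeric", n = "numeric"))

#' McNemar test on the discordant cells
#'
#' @slot chiSquare (b - c)^2 / (b + c), or the continuity-corrected form.
#' @slot pValue upper-tail chi-squared p with 1 df.
#' @slot b,c discordant counts.
#' @slot corrected logical, whether the continuity correction was applied.
#' @export
setClass("McNemarResult", representation(
  chiSquare = "numeric", pValue = "numeric", b = "numeric", c = "numeric",
  corrected = "logical"))
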