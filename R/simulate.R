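# Synthetic scene generation: bathymetry, truth maps, forward optical
# rendering and training ROIs. All generators are pure functions of
# (config, seed): the same configuration yields bit-identical output.

# Library of class mean spectra (reflectance). Optically-deep water is a
# true dark object (zero in every band) so the darkest NIR pixel carries
# exactly the atmospheric path signal; the green band of submerged classes
# is overwritten by the water-column forward model in renderScene().
.SPECTRA <- rbind(
  land       = c(blue = 0.060, green = 0.090, red = 0.110, nir = 0.320,
                 swir1 = 0.280, swir2 = 0.220),
  deep_water = c(blue = 0.000, green = 0.000, red = 0.000, nir = 0.000,
                 swir1 = 0.000, swir2 = 0.000),
  seagrass   = c(blue = 0.018, green = 0.030, red = 0.016, nir = 0.006,
                 swir1 = 0.002, swir2 = 0.001),
  sand       = c(blue = 0.060, green = 0.080, red = 0.070, nir = 0.014,
                 swir1 = 0.005, swir2 = 0.003),
  intertidal = c(blue = 0.050, green = 0.070, red = 0.085, nir = 0.150,
                 swir1 = 0.120, swir2 = 0.100))

# Depth separating the shallow shelf from optically-deep water (m); also
# the default analysis depth mask.
.DEEP_THRESHOLD <- 2.5
# Depths at or below this are treated as intertidal transition (m).
.INTERTIDAL_DEPTH <- 0.15

.classSpectra <- function(config) {
  s <- .SPECTRA[, config@bands, drop = FALSE]
  centre <- matrix(colMeans(s), nrow(s), ncol(s), byrow = TRUE)
  out <- centre + config@separation * (s - centre)
  pmax(out, 0)
}

#' Generate a bathymetric DEM
#'
#' Builds the depth grid (m, positive down, NA over land) for a scene.
#' The default \code{"coast"} template emulates a lagoon margin: a land
#' strip, a narrow intertidal fringe, a shallow vegetated shelf and an
#' optically-deep basin, with a smoothly meandering shoreline.
#' \code{"constant"} gives a uniform depth and \code{"gradient"} a
#' monotone deepening along columns; both are useful for calibration
#' checks.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return Numeric matrix of depths, NA over land.
#' @export
#' @examples
#' dem <- generateDem(sceneConfig(nRows = 32, nCols = 32, seed = 7))
#' range(dem, na.rm = TRUE)
generateDem <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  nr <- config@nRows
  nc <- config@nCols
  if (nr < 8L || nc < 8L) stop("grid too small: need at least 8 x 8 pixels")
  .withSeed(config@seed + 1L, {
    if (config@demShape == "constant") {
      return(matrix(config@demDepth, nr, nc))
    }
    if (config@demShape == "gradient") {
      prof <- seq(0.1, config@basinDepth, length.out = nc)
      return(matrix(prof, nr, nc, byrow = TRUE))
    }
    # coast: column bands sized from the class area targets
    landW <- round(config@classTargets[["land"]] * nc)
    intW <- max(1L, round(config@classTargets[["intertidal"]] * nc))
    deepW <- round(config@classTargets[["deep_water"]] * nc)
    shelfW <- nc - landW - intW - deepW
    if (shelfW < 1L) stop("class targets leave no room for the shelf")
    prof <- c(rep(NA_real_, landW),
              seq(0.05, .INTERTIDAL_DEPTH - 0.01, length.out = intW),
              seq(config@shelfDepthRange[1], config@shelfDepthRange[2],
                  length.out = shelfW),
              seq(.DEEP_THRESHOLD + 0.2, config@basinDepth,
                  length.out = deepW))
    dem <- matrix(prof, nr, nc, byrow = TRUE)
    # meandering shoreline: shift each row's profile by a smooth,
    # zero-mean integer offset so band widths are preserved
    wig <- .gsmooth(matrix(stats::rnorm(nr), nr, 1), 2)
    wig <- round(2 * (wig - mean(wig)) / max(stats::sd(wig), 1e-12) / 2)
    wig <- pmin(pmax(as.vector(wig), -2L), 2L)
    for (r in seq_len(nr)) {
      k <- wig[r]
      if (k != 0) {
        idx <- pmin(pmax(seq_len(nc) - k, 1L), nc)
        dem[r, ] <- dem[r, idx]
      }
    }
    # mild smooth relief on the submerged part, kept well inside the
    # class depth margins so morphology does not flip classes
    relief <- .gsmooth(matrix(stats::rnorm(nr * nc, sd = 1), nr, nc), 3)
    relief <- 0.03 * relief / max(stats::sd(as.vector(relief)), 1e-12)
    wet <- !is.na(dem) & dem > .INTERTIDAL_DEPTH
    dem[wet] <- pmax(dem[wet] + relief[wet], .INTERTIDAL_DEPTH + 0.02)
    dem
  })
}

#' Generate ground-truth class and LAI maps
#'
#' Classifies the DEM into the five surface classes (land where depth is
#' absent, intertidal at depths up to 0.15 m, optically-deep water beyond
#' 2.5 m, and a shelf split into seagrass and submerged sand) and lays a
#' spatially smooth LAI field over the seagrass. The seagrass/sand split
#' thresholds a smooth random field at the configured fraction, so patch
#' shapes are organic but the areal fraction is exact.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param dem depth grid from \code{\link{generateDem}}.
#' @return A \linkS4class{TruthMaps}.
#' @export
generateTruth <- function(config, dem) {
  stopifnot(is(config, "SceneConfig"))
  .assertSameDim(dem, matrix(0, config@nRows, config@nCols),
                 "dem and config grid")
  .withSeed(config@seed + 2L, {
    cls <- matrix(.codeOf("sand"), config@nRows, config@nCols)
    land <- is.na(dem)
    cls[land] <- .codeOf("land")
    cls[!land & dem <= .INTERTIDAL_DEPTH] <- .codeOf("intertidal")
    cls[!land & dem > .DEEP_THRESHOLD] <- .codeOf("deep_water")
    shelf <- cls == .codeOf("sand")
    if (any(shelf) && config@seagrassFraction >= 1) {
      cls[shelf] <- .codeOf("seagrass")
    } else if (any(shelf) && config@seagrassFraction > 0) {
      field <- .gsmooth(matrix(stats::rnorm(length(dem)), nrow(dem)), 3)
      thr <- stats::quantile(field[shelf], 1 - config@seagrassFraction,
                             names = FALSE, type = 7)
      cls[shelf & field > thr] <- .codeOf("seagrass")
    }
    sg <- cls == .codeOf("seagrass")
    lai <- matrix(0, nrow(dem), ncol(dem))
    if (any(sg)) {
      if (is.finite(config@laiConstant)) {
        lai[sg] <- config@laiConstant
      } else {
        f <- .gsmooth(matrix(stats::rnorm(length(dem)), nrow(dem)), 4)
        f <- f - min(f[sg])
        m0 <- mean(f[sg])
        if (m0 > 0) f <- f * (config@laiMean / m0)
        lai[sg] <- pmin(f[sg], config@laiMax)
      }
    }
    new("TruthMaps", classGrid = cls, laiGrid = lai, dem = dem)
  })
}

# Forward LAI -> bottom reflectance law: the exact inverse of the
# retrieval's log-linear model LAI = a + b ln(Rb) + c.
.rbFromLai <- function(lai, coeffs) {
  exp((lai - coeffs@a - coeffs@c) / coeffs@b)
}

#' Render a multiband scene from truth maps
#'
#' The forward optical model. Over submerged pixels the green band is the
#' two-path single-scattering form
#' \deqn{R_{rs} = (R_b/\pi)\, e^{-(K_d + K_{Lu}) H} + \mathrm{path} + \epsilon,}
#' where H is the tide-adjusted water depth and the bottom reflectance
#' R_b follows the configured LAI law under seagrass (a fixed sand albedo
#' under bare sand, zero under optically-deep water). All other bands, and
#' all bands of emergent classes, are class mean spectra plus the additive
#' path offset and Gaussian sensor noise. Negative values after noise are
#' clipped to zero; the clipped count is reported via a message and the
#' \code{"clipped"} attribute.
#'
#' @param truth a \linkS4class{TruthMaps}.
#' @param config a \linkS4class{SceneConfig}.
#' @param coeffs \linkS4class{LAICoefficients} shared with the retrieval.
#' @param rbSand bottom reflectance of bare submerged sand.
#' @return A \linkS4class{SceneStack}.
#' @export
renderScene <- function(truth, config, coeffs = laiCoefficients(),
                        rbSand = 0.45) {
  stopifnot(is(truth, "TruthMaps"), is(config, "SceneConfig"))
  .assertSameDim(truth@classGrid, matrix(0, config@nRows, config@nCols),
                 "truth and config grid")
  .withSeed(config@seed + 3L, {
    nr <- nrow(truth@classGrid)
    nc <- ncol(truth@classGrid)
    bands <- config@bands
    spectra <- .classSpectra(config)
    cls <- truth@classGrid
    refl <- array(0, dim = c(nr, nc, length(bands)),
                  dimnames = list(NULL, NULL, bands))
    for (b in seq_along(bands)) {
      base <- matrix(0, nr, nc)
      for (cl in rownames(spectra)) {
        base[cls == .codeOf(cl)] <- spectra[cl, b]
      }
      refl[, , b] <- base
    }
    # water-column physics in the green band over submerged bottoms
    H <- tideAdjust(truth@dem, config@tideHeight)
    k <- config@kd + config@klu
    g <- which(bands == config@greenBand)
    green <- refl[, , g]
    sg <- cls == .codeOf("seagrass")
    sd_ <- cls == .codeOf("sand")
    green[sg] <- .rbFromLai(truth@laiGrid[sg], coeffs) / pi *
      exp(-k * H[sg])
    green[sd_] <- rbSand / pi * exp(-k * H[sd_])
    green[cls == .codeOf("deep_water")] <- 0
    refl[, , g] <- green
    # additive path offset and sensor noise
    for (b in seq_along(bands)) {
      layer <- refl[, , b] + config@pathOffset[[bands[b]]]
      if (config@noiseSd > 0) {
        layer <- layer + stats::rnorm(length(layer), sd = config@noiseSd)
      }
      refl[, , b] <- layer
    }
    clipped <- sum(refl < 0)
    if (clipped > 0) {
      message("renderScene: clipped ", clipped, " negative value(s) to 0")
      refl[refl < 0] <- 0
    }
    out <- new("SceneStack", reflectance = refl, config = config)
    attr(out@reflectance, "clipped") <- clipped
    out
  })
}

#' Place training regions of interest
#'
#' Draws 3--6 homogeneous, mutually disjoint rectangles per class from the
#' truth map. The default per-class region counts (deep water 3, sand 5,
#' seagrass 6, land 3, intertidal 3) mirror a typical manual ROI campaign
#' over a lagoon scene. Placement is deterministic per seed, so the same
#' ROI locations can be reused across a scene time series.
#'
#' @param truth a \linkS4class{TruthMaps}.
#' @param config a \linkS4class{SceneConfig}.
#' @param nPerClass named integer, regions per class (each in 3..6).
#' @return A \linkS4class{ROISet}.
#' @export
makeRois <- function(truth, config,
                     nPerClass = c(land = 3, deep_water = 3, seagrass = 6,
                                   sand = 5, intertidal = 3)) {
  stopifnot(is(truth, "TruthMaps"), is(config, "SceneConfig"))
  cls <- truth@classGrid
  for (cl in .CLASS_LEVELS) {
    if (!any(cls == .codeOf(cl))) {
      stop("class '", cl, "' is absent from the truth map")
    }
  }
  .withSeed(config@seed + 4L, {
    used <- matrix(FALSE, nrow(cls), ncol(cls))
    rows <- list()
    id <- 0L
    for (cl in .CLASS_LEVELS) {
      want <- nPerClass[[cl]]
      code <- .codeOf(cl)
      inClass <- which(cls == code, arr.ind = TRUE)
      got <- 0L
      attempts <- 0L
      maxDim <- 10L
      while (got < want && attempts < 4000L) {
        attempts <- attempts + 1L
        if (attempts %% 1000L == 0L && maxDim > 3L) maxDim <- maxDim - 3L
        at <- inClass[sample.int(nrow(inClass), 1L), ]
        h <- sample.int(maxDim, 1L)
        w <- sample.int(maxDim, 1L)
        if (h * w < 4L) next
        r1 <- at[1]; c1 <- at[2]
        r2 <- r1 + h - 1L; c2 <- c1 + w - 1L
        if (r2 > nrow(cls) || c2 > ncol(cls)) next
        block <- cls[r1:r2, c1:c2]
        if (any(block != code) || any(used[r1:r2, c1:c2])) next
        used[r1:r2, c1:c2] <- TRUE
        id <- id + 1L
        got <- got + 1L
        rows[[id]] <- data.frame(roi = id, class = cl, row0 = r1, col0 = c1,
                                 h = h, w = w)
      }
      if (got < 3L) {
        stop("could not place 3 homogeneous regions for class '", cl, "'")
      }
    }
    new("ROISet", table = do.call(rbind, rows),
        gridDim = dim(cls))
  })
}

#' Linear pixel indices of one ROI
#'
#' @param rois a \linkS4class{ROISet}.
#' @param roi the roi id (row of \code{roiTable(rois)}).
#' @return Integer vector of column-major linear indices into the grid.
#' @export
roiIndices <- function(rois, roi) {
  tab <- rois@table[rois@table$roi == roi, ]
  if (nrow(tab) != 1) stop("unknown roi id: ", roi)
  r <- tab$row0 + seq_len(tab$h) - 1L
  cc <- tab$col0 + seq_len(tab$w) - 1L
  as.vector(outer(r, (cc - 1L) * rois@gridDim[1], `+`))
}

#' @rdname roiIndices
#' @return \code{roiTable} returns the region table (one row per ROI).
#' @export
roiTable <- function(rois) rois@table

#' Simulate a climate covariate table
#'
#' One row per scene year: season tag, ENSO and NAO indices (AR(1)
#' standardised anomalies) and a sea-surface temperature with a mild
#' warming drift.
#'
#' @param years integer vector of scene years.
#' @param seed integer seed.
#' @param season season tag recycled over years (default "autumn").
#' @return data.frame with columns year, season, enso, nao, sst.
#' @export
simulateCovariates <- function(years, seed = 1L, season = "autumn") {
  .withSeed(seed + 5L, {
    ar1 <- function(n, phi = 0.6) {
      x <- numeric(n)
      x[1] <- stats::rnorm(1)
      for (i in seq_len(n)[-1]) {
        x[i] <- phi * x[i - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
      }
      x
    }
    n <- length(years)
    data.frame(year = years, season = rep_len(season, n),
               enso = ar1(n), nao = ar1(n, phi = 0.3),
               sst = 24 + 0.02 * (years - years[1]) +
                 stats::rnorm(n, sd = 0.5))
  })
}
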