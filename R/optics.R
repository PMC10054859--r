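# Water-column optics: bottom-reflectance retrieval, LAI inversion and
# cross-sensor brightness calibration.

#' Upwelling attenuation from downwelling attenuation
#'
#' The upwelling diffuse attenuation coefficient is derived from the
#' downwelling one as K_Lu = K_d / 2 pi (the upwelling stream integrates
#' bottom-leaving radiance over the hemisphere).
#'
#' @param kd downwelling diffuse attenuation at 560 nm (1/m), > 0.
#' @return K_Lu in 1/m.
#' @export
#' @examples
#' kluFromKd(0.734) # ~0.117
kluFromKd <- function(kd) {
  if (!is.numeric(kd) || any(kd <= 0)) stop("kd must be > 0")
  kd / (2 * pi)
}

#' Tide-adjust a depth grid
#'
#' Water column height at acquisition is the charted depth plus the tide
#' height. Negative results (bottom exposed at low tide) are clipped to 0
#' and flagged in the \code{"emergent"} attribute.
#'
#' @param dem depth grid (m, positive down, NA over land).
#' @param tideHeight tide height (m), may be negative.
#' @return Depth grid H (m) with attribute \code{"emergent"}.
#' @export
tideAdjust <- function(dem, tideHeight) {
  H <- dem + tideHeight
  emergent <- !is.na(H) & H < 0
  H[emergent] <- 0
  attr(H, "emergent") <- emergent
  H
}

#' Retrieve bottom reflectance through the water column
#'
#' Inverts the two-path attenuation model: R_b = pi * R_rs *
#' exp((K_d + K_Lu) * H). Pixels whose exponent would overflow are
#' invalidated (NA) rather than propagated as Inf.
#'
#' @param green corrected green-band reflectance grid (>= 0).
#' @param H tide-adjusted depth grid (m, >= 0; NA over land).
#' @param optics an \linkS4class{OpticsRecord}.
#' @return Bottom-reflectance grid; NA where invalid, with the count of
#'   overflow-invalidated pixels in attribute \code{"invalidated"}.
#' @export
retrieveRb <- function(green, H, optics) {
  stopifnot(is(optics, "OpticsRecord"))
  .assertSameDim(green, H, "green band and depth grid")
  if (any(green < 0, na.rm = TRUE)) stop("green reflectance must be >= 0")
  if (any(H < 0, na.rm = TRUE)) stop("depths must be >= 0")
  expo <- (optics@kd + optics@klu) * H
  over <- !is.na(expo) & expo > 700 # exp() overflow guard
  rb <- pi * green * exp(expo)
  rb[over] <- NA_real_
  attr(rb, "invalidated") <- sum(over)
  rb
}

#' Invert bottom reflectance to LAI
#'
#' Applies the log-linear retrieval LAI = max(a + b ln(R_b) + c, 0). The
#' slope b is negative: denser canopies are darker. Pixels with R_b <= 0
#' or undefined R_b are marked invalid.
#'
#' @param rb bottom-reflectance grid.
#' @param coeffs \linkS4class{LAICoefficients}.
#' @return A \linkS4class{LAIGrid}.
#' @export
invertLai <- function(rb, coeffs = laiCoefficients()) {
  stopifnot(is(coeffs, "LAICoefficients"))
  validObject(coeffs)
  valid <- !is.na(rb) & rb > 0
  lai <- matrix(NA_real_, nrow(rb), ncol(rb))
  lai[valid] <- pmax(coeffs@a + coeffs@b * log(rb[valid]) + coeffs@c, 0)
  new("LAIGrid", lai = lai, valid = valid)
}

#' Cross-sensor LAI brightness calibration
#'
#' Ordinary least squares of a reference-sensor LAI grid on a target-sensor
#' LAI grid over their shared valid pixels. When the fitted slope's 95%
#' confidence interval includes 1, the brightness difference between the
#' sensors is a pure additive offset and the intercept can be folded into
#' the retrieval's additive correction term c (see
#' \code{\link{updateCoefficients}}).
#'
#' @param laiRef reference \linkS4class{LAIGrid} (e.g. from the brighter,
#'   higher-resolution sensor).
#' @param laiTarget target \linkS4class{LAIGrid} to be corrected.
#' @return List with slope, offset, slopeCI (95%), n and offsetApplicable
#'   (TRUE when the slope CI includes 1).
#' @export
calibrateOffset <- function(laiRef, laiTarget) {
  stopifnot(is(laiRef, "LAIGrid"), is(laiTarget, "LAIGrid"))
  .assertSameDim(laiRef@lai, laiTarget@lai, "LAI grids")
  shared <- laiRef@valid & laiTarget@valid
  n <- sum(shared)
  if (n < 10) stop("need at least 10 shared valid pixels, got ", n)
  x <- laiTarget@lai[shared]
  y <- laiRef@lai[shared]
  fit <- stats::lm(y ~ x)
  est <- stats::coef(fit)
  if (stats::sd(x) < 1e-12 || any(!is.finite(est))) {
    stop("target LAI grid is degenerate; slope is not identifiable")
  }
  resVar <- sum(stats::residuals(fit)^2) / (n - 2)
  seSlope <- sqrt(resVar / sum((x - mean(x))^2))
  ci <- est[["x"]] + c(-1, 1) * stats::qt(0.975, n - 2) * seSlope
  # exact fits have zero residual variance: the slope is known, CI is a point
  if (!all(is.finite(ci))) ci <- rep(est[["x"]], 2)
  tol <- 1e-8 * max(1, abs(est[["x"]])) # float guard for exact fits
  list(slope = unname(est[["x"]]), offset = unname(est[["(Intercept)"]]),
       slopeCI = ci, n = n,
       offsetApplicable = ci[1] - tol <= 1 && 1 <= ci[2] + tol)
}

#' Fold a calibration offset into the inversion coefficients
#'
#' Adds the calibrated additive offset to the retrieval's correction term
#' c when the calibration found a unit slope; otherwise warns and returns
#' the coefficients unchanged (an offset is not a valid correction for a
#' multiplicative brightness difference).
#'
#' @param coeffs \linkS4class{LAICoefficients}.
#' @param calibration result of \code{\link{calibrateOffset}}.
#' @return Updated \linkS4class{LAICoefficients}.
#' @export
updateCoefficients <- function(coeffs, calibration) {
  stopifnot(is(coeffs, "LAICoefficients"))
  if (!isTRUE(calibration$offsetApplicable)) {
    warning("slope CI excludes 1; offset not applied")
    return(coeffs)
  }
  laiCoefficients(a = coeffs@a, b = coeffs@b,
                  c = coeffs@c + calibration$offset)
}

#' Biomass and carbon from LAI
#'
#' The LAI-to-carbon transfer chain, integrated over the seagrass area:
#' per-pixel fresh biomass density is 500 g m-2 per unit LAI; dry biomass
#' is 0.2 x fresh; aboveground carbon is 0.34 x dry; belowground carbon is
#' 3 x aboveground via the 1:3 aboveground:belowground biomass ratio of
#' large rhizomatous seagrasses; total carbon is their sum. Totals are in
#' Gg (1e9 g); the belowground carbon density is 500 x 0.2 x 0.34 x 3 =
#' 102 g C m-2 per unit LAI.
#'
#' @param lai a \linkS4class{LAIGrid} (mean taken over valid pixels) or a
#'   single numeric mean LAI.
#' @param extent an \linkS4class{ExtentResult}, or a numeric seagrass area
#'   in km^2.
#' @param pixelSize pixel edge length (m), used only for bookkeeping when
#'   \code{extent} is numeric.
#' @return A \linkS4class{CarbonSummary}.
#' @export
#' @examples
#' carbonSummary(1.6, 23) # the bay-scale worked example
carbonSummary <- function(lai, extent, pixelSize = 30) {
  meanLai <- if (is(lai, "LAIGrid")) {
    vals <- lai@lai[lai@valid]
    if (length(vals) == 0) 0 else mean(vals)
  } else {
    as.numeric(lai)
  }
  if (is.na(meanLai) || meanLai < 0) {
    stop("mean LAI must be a nonnegative number")
  }
  areaKm2 <- if (is(extent, "ExtentResult")) extent@areaKm2
             else as.numeric(extent)
  areaM2 <- areaKm2 * 1e6
  freshGg <- 500 * meanLai * areaM2 * 1e-9
  dryGg <- 0.2 * freshGg
  agGg <- 0.34 * dryGg
  bgGg <- 3 * agGg
  new("CarbonSummary", freshGg = freshGg, dryGg = dryGg,
      agCarbonGg = agGg, bgCarbonGg = bgGg,
      totalCarbonGg = agGg + bgGg,
      bgcDensity = 102 * meanLai, meanLai = meanLai, areaKm2 = areaKm2)
}

#' Full LAI retrieval for one scene
#'
#' Convenience chain: tide-adjust the DEM, retrieve bottom reflectance
#' from the corrected green band, and invert to LAI on the unmasked
#' seagrass pixels of the class map.
#'
#' @param scene corrected \linkS4class{SceneStack}.
#' @param cmap \linkS4class{ClassMap} (after depth masking).
#' @param dem depth grid (m, NA over land).
#' @param optics \linkS4class{OpticsRecord}; defaults to the scene's
#'   configured kd/klu.
#' @param coeffs \linkS4class{LAICoefficients}.
#' @param tideHeight tide height (m); defaults to the scene's metadata.
#' @return A \linkS4class{LAIGrid} valid only on unmasked seagrass pixels.
#' @export
retrieveLai <- function(scene, cmap, dem,
                        optics = opticsRecord(scene@config@kd,
                                              scene@config@klu,
                                              scene@config@date),
                        coeffs = laiCoefficients(),
                        tideHeight = scene@config@tideHeight) {
  stopifnot(is(scene, "SceneStack"), is(cmap, "ClassMap"))
  H <- tideAdjust(dem, tideHeight)
  green <- scene@reflectance[, , scene@config@greenBand]
  rb <- retrieveRb(green, H, optics)
  grid <- invertLai(rb, coeffs)
  keep <- cmap@codes == .codeOf("seagrass") & !cmap@masked
  grid@valid <- grid@valid & keep
  grid@lai[!grid@valid] <- NA_real_
  grid
}
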