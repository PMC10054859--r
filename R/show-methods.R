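# Compact show() methods for the user-facing classes.

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@nRows, "x", object@nCols, "pixels @",
      object@pixelSize, "m |", length(object@bands), "bands |",
      as.character(object@date), object@sensorTag, "\n")
  cat("  tide", object@tideHeight, "m | kd", object@kd,
      "klu", signif(object@klu, 4), "1/m | noise sd", object@noiseSd,
      "| seed", object@seed, "\n")
})

setMethod("show", "SceneStack", function(object) {
  d <- dim(object@reflectance)
  cat("SceneStack:", d[1], "x", d[2], "pixels,", d[3], "bands (",
      paste(object@config@bands, collapse = ", "), ")\n")
  cat("  reflectance range:",
      paste(signif(range(object@reflectance), 4), collapse = " - "), "\n")
})

setMethod("show", "TruthMaps", function(object) {
  tab <- table(factor(.CLASS_LEVELS[object@classGrid + 1L],
                      levels = .CLASS_LEVELS))
  cat("TruthMaps:", nrow(object@classGrid), "x", ncol(object@classGrid),
      "pixels\n")
  print(tab)
  sg <- object@classGrid == .codeOf("seagrass")
  if (any(sg)) {
    cat("  seagrass LAI: mean", signif(mean(object@laiGrid[sg]), 4),
        "range", paste(signif(range(object@laiGrid[sg]), 3),
                       collapse = " - "), "\n")
  }
})

setMethod("show", "ROISet", function(object) {
  cat("ROISet:", nrow(object@table), "regions on a",
      paste(object@gridDim, collapse = " x "), "grid\n")
  agg <- stats::aggregate(cbind(n = h * w) ~ class, object@table, sum)
  print(agg, row.names = FALSE)
})

setMethod("show", "DarkOffset", function(object) {
  cat("DarkOffset from", object@sourceBand, "dark pixel at (",
      paste(object@darkPixel, collapse = ", "), ")\n")
  print(signif(object@offsets, 4))
})

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", nrow(object@spectra), "samples x",
      ncol(object@spectra), "bands\n")
  print(table(droplevels(object@labels)))
})

setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel:", length(object@levels), "classes,",
      length(object@bands), "bands, hidden size",
      object@config$size, "\n")
  cat("  training accuracy:", signif(object@log$trainAccuracy, 4))
  if (!is.null(object@log$heldoutAccuracy)) {
    cat(" | held-out accuracy:", signif(object@log$heldoutAccuracy, 4))
  }
  cat("\n")
})

setMethod("show", "ClassMap", function(object) {
  cat("ClassMap:", nrow(object@codes), "x", ncol(object@codes),
      "pixels,", sum(object@masked), "masked\n")
  print(table(factor(.CLASS_LEVELS[object@codes + 1L],
                     levels = .CLASS_LEVELS)))
})

setMethod("show", "ExtentResult", function(object) {
  cat("Seagrass extent:", object@nPixels, "pixels =",
      signif(object@areaKm2, 6), "km^2 (",
      object@pixelSize^2, "m^2/pixel )\n")
})

setMethod("show", "BandImportance", function(object) {
  cat("BandImportance (", object@method, "):\n")
  print(round(object@percent, 2))
})

setMethod("show", "LAIGrid", function(object) {
  v <- object@lai[object@valid]
  cat("LAIGrid:", sum(object@valid), "valid pixels")
  if (length(v)) {
    cat(" | mean", signif(mean(v), 4), "range",
        paste(signif(range(v), 3), collapse = " - "))
  }
  cat("\n")
})

setMethod("show", "CarbonSummary", function(object) {
  cat("CarbonSummary over", signif(object@areaKm2, 5), "km^2, mean LAI",
      signif(object@meanLai, 4), "\n")
  cat(sprintf("  fresh %.3f Gg | dry %.3f Gg | AG C %.4f Gg | BG C %.4f Gg | total C %.4f Gg\n",
              object@freshGg, object@dryGg, object@agCarbonGg,
              object@bgCarbonGg, object@totalCarbonGg))
  cat("  BGC density:", signif(object@bgcDensity, 5), "g C m-2\n")
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf("TrendResult (n = %d): tau = %.3f (%s), p = %.3g\n",
              object@n, object@tau, object@strengthLabel, object@pValue))
  cat(sprintf("  Sen slope = %.4g /yr | %%change = %.3g %%/yr | gamma = %s yr\n",
              object@senSlope, object@percentChange,
              ifelse(is.na(object@gammaYears), "undefined",
                     format(signif(object@gammaYears, 4)))))
})

setMethod("show", "FrequencyGrid", function(object) {
  cat("FrequencyGrid over", object@nStack, "scenes;",
      sum(!is.na(object@freq)), "pixels with data\n")
})

setMethod("show", "MLRResult", function(object) {
  cat("MLRResult (n =", object@n, ", adjusted r^2 =",
      signif(object@adjR2, 3), ")\n")
  print(object@coefficients, row.names = FALSE, digits = 4)
})

setMethod("show", "ConfusionTable", function(object) {
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(A = c("present", "absent"),
                              B = c("present", "absent")))
  cat("ConfusionTable (n =", object@a + object@b + object@c + object@d,
      ")\n")
  print(m)
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport (n =", object@n, ")\n")
  m <- rbind(presence = object@presence, absence = object@absence)
  print(round(m, 4))
  cat("  overall accuracy:", signif(object@overallAccuracy, 4),
      "| kappa:", signif(object@kappa, 4), "\n")
})

setMethod("show", "McNemarResult", function(object) {
  cat(sprintf("McNemar: chi^2 = %.4g, p = %.4g (b = %g, c = %g%s)\n",
              object@chiSquare, object@pValue, object@b, object@c,
              if (object@corrected) ", continuity-corrected" else ""))
})
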