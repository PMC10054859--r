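# Shared fixtures: small synthetic scenes built in code at test time.

# Default small coastal scene pack; noiseSd = 0 gives the exact-roundtrip
# regime, the default 0.002 the realistic-noise regime.
scenePack <- function(seed = 3L, noiseSd = 0, ...) {
  cfg <- sceneConfig(seed = seed, noiseSd = noiseSd, ...)
  dem <- generateDem(cfg)
  truth <- generateTruth(cfg, dem)
  scene <- renderScene(truth, cfg)
  list(cfg = cfg, dem = dem, truth = truth, scene = scene)
}

# ClassMap holding the truth labels, optionally depth-masked.
truthClassMap <- function(pack, depthMask = TRUE) {
  cm <- new("ClassMap", codes = pack$truth@classGrid,
            masked = matrix(FALSE, pack$cfg@nRows, pack$cfg@nCols))
  if (depthMask) cm <- applyDepthMask(cm, pack$dem, pack$cfg@tideHeight)
  cm
}

# Full retrieval chain: dark-object subtraction, water-column correction,
# LAI inversion on unmasked seagrass pixels.
pipelineLai <- function(pack, coeffs = laiCoefficients()) {
  water <- !is.na(pack$dem)
  corr <- dosCorrect(pack$scene, findDarkOffset(pack$scene, water))
  retrieveLai(corr, truthClassMap(pack), pack$dem, coeffs = coeffs)
}

# A SceneStack built directly from a band-named list of matrices.
sceneFromBands <- function(bandList, cfg) {
  refl <- array(0, dim = c(nrow(bandList[[1]]), ncol(bandList[[1]]),
                           length(bandList)),
                dimnames = list(NULL, NULL, names(bandList)))
  for (b in names(bandList)) refl[, , b] <- bandList[[b]]
  new("SceneStack", reflectance = refl, config = cfg)
}

# Uniform-depth seagrass-only truth for forward-model scalar checks.
flatSeagrassTruth <- function(n, depth, lai) {
  new("TruthMaps",
      classGrid = matrix(classCodes()[["seagrass"]], n, n),
      laiGrid = matrix(lai, n, n),
      dem = matrix(depth, n, n))
}
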