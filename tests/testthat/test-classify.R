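# Training-set assembly, classifier behaviour, depth masking, extent.

test_that("extractTraining yields one labelled sample per ROI pixel", {
  pack <- scenePack(seed = 6L, noiseSd = 0.002)
  rois <- makeRois(pack$truth, pack$cfg)
  ts <- extractTraining(pack$scene, rois)
  tab <- roiTable(rois)
  expect_equal(nrow(ts@spectra), sum(tab$h * tab$w))
  expect_equal(as.vector(table(ts@labels)[tab$class[1]]),
               sum((tab$h * tab$w)[tab$class == tab$class[1]]))

  # spot-check 100 random samples against direct scene lookup
  flatIdx <- unlist(lapply(tab$roi, function(r) roiIndices(rois, r)))
  set.seed(42)
  for (i in sample(seq_along(flatIdx), 100)) {
    rc <- arrayInd(flatIdx[i], dim(pack$truth@classGrid))
    expect_equal(unname(ts@spectra[i, ]),
                 unname(pack$scene@reflectance[rc[1], rc[2], ]))
  }

  # a crop that excludes ROI pixels is rejected with the ROI named
  cropped <- cropScene(pack$scene, 1:20, 1:20)
  expect_error(extractTraining(cropped, rois), "ROI")
})

test_that("balanceClasses equalises counts by resampling within class", {
  set.seed(1)
  spectra <- matrix(runif(5 * 37 * 6), ncol = 6,
                    dimnames = list(NULL, letters[1:6]))
  labels <- factor(rep(names(classCodes()), times = c(10, 25, 60, 50, 40)),
                   levels = names(classCodes()))
  ts <- new("TrainingSet", spectra = spectra[seq_along(labels), ],
            labels = labels)
  bal <- balanceClasses(ts, nPerClass = 500L, seed = 9L)
  expect_true(all(table(bal@labels) == 500L))
  expect_equal(nrow(bal@spectra), 2500L)

  # every balanced spectrum exists among its source class spectra
  for (cl in levels(labels)) {
    src <- apply(ts@spectra[ts@labels == cl, , drop = FALSE], 1, paste,
                 collapse = "|")
    out <- apply(bal@spectra[bal@labels == cl, , drop = FALSE], 1, paste,
                 collapse = "|")
    expect_true(all(out %in% src), label = cl)
  }

  # deterministic per seed; a class with zero samples is an error
  expect_identical(balanceClasses(ts, 500L, seed = 9L)@spectra, bal@spectra)
  tsEmpty <- new("TrainingSet", spectra = spectra[1:10, ],
                 labels = factor(rep("land", 10),
                                 levels = names(classCodes())))
  expect_error(balanceClasses(tsEmpty, 100L), "deep_water")
})

test_that("splitTrainTest is stratified, exact and disjoint", {
  set.seed(2)
  ts <- new("TrainingSet",
            spectra = matrix(runif(600), ncol = 3),
            labels = factor(rep(c("seagrass", "sand"), each = 100)))
  sp <- splitTrainTest(ts, 0.9, seed = 4L)
  expect_true(all(table(sp$train@labels) == 90L))
  expect_true(all(table(sp$test@labels) == 10L))

  # set algebra on the spectra rows: union = source, intersection empty
  key <- function(m) apply(m, 1, paste, collapse = "|")
  expect_setequal(c(key(sp$train@spectra), key(sp$test@spectra)),
                  key(ts@spectra))
  expect_equal(nrow(sp$train@spectra) + nrow(sp$test@spectra), 200L)

  expect_error(splitTrainTest(ts, 1.0), "between 0 and 1")
  expect_error(splitTrainTest(ts, 0), "between 0 and 1")
})

test_that("classifier separates the synthetic classes and fails on permuted labels", {
  pack <- scenePack(seed = 8L, noiseSd = 0.002)
  ts <- extractTraining(pack$scene, makeRois(pack$truth, pack$cfg))
  bal <- balanceClasses(ts, nPerClass = 1200L, seed = 1L)
  sp <- splitTrainTest(bal, 0.9, seed = 2L)
  model <- trainClassifier(sp$train,
                           config = list(size = 12L, maxit = 120L, seed = 3L),
                           test = sp$test)
  expect_gt(model@log$heldoutAccuracy, 0.98)

  # labels carrying no information leave only chance accuracy (~0.2 for
  # five classes); featureless uniform spectra remove any cluster
  # structure a permutation of real labels would retain
  set.seed(7)
  nullSpectra <- matrix(runif(3000 * 6), ncol = 6,
                        dimnames = list(NULL, pack$cfg@bands))
  nullLabels <- factor(sample(names(classCodes()), 3000, replace = TRUE),
                       levels = names(classCodes()))
  spNull <- splitTrainTest(new("TrainingSet", spectra = nullSpectra,
                               labels = nullLabels), 0.9, seed = 8L)
  suppressWarnings(
    modelNull <- trainClassifier(spNull$train,
                                 config = list(size = 12L, maxit = 60L,
                                               seed = 3L),
                                 test = spNull$test))
  expect_lt(abs(modelNull@log$heldoutAccuracy - 0.2), 0.05)
})

test_that("predictMap agrees with a per-pixel loop and is deterministic", {
  pack <- scenePack(seed = 8L, nRows = 48, nCols = 48, noiseSd = 0.002)
  ts <- extractTraining(pack$scene, makeRois(pack$truth, pack$cfg))
  bal <- balanceClasses(ts, nPerClass = 400L, seed = 1L)
  model <- trainClassifier(bal, config = list(size = 8L, maxit = 80L,
                                              seed = 5L))
  cmap <- predictMap(model, pack$scene)

  # loop oracle: classify 50 random pixels one at a time
  set.seed(11)
  for (k in 1:50) {
    r <- sample.int(48, 1); cc <- sample.int(48, 1)
    x <- matrix(pack$scene@reflectance[r, cc, ], nrow = 1,
                dimnames = list(NULL, pack$cfg@bands))
    p <- predictProb(model, x)
    lab <- model@levels[which.max(p)]
    expect_equal(unname(cmap@codes[r, cc]), unname(classCodes()[[lab]]))
  }

  # identical pixels get identical labels
  expect_identical(predictMap(model, pack$scene)@codes, cmap@codes)
  i <- which(!is.na(pack$dem))[1:2]
  sceneDup <- pack$scene
  for (b in seq_len(6)) {
    layer <- sceneDup@reflectance[, , b]
    layer[i[2]] <- layer[i[1]]
    sceneDup@reflectance[, , b] <- layer
  }
  cmapDup <- predictMap(model, sceneDup)
  expect_equal(cmapDup@codes[i[1]], cmapDup@codes[i[2]])

  # band-order mismatch with the training layout is rejected
  badScene <- pack$scene
  badScene@config@bands <- pack$cfg@bands[c(2:6, 1)]
  expect_error(predictMap(model, badScene), "bands")
})

test_that("depth mask uses tide-adjusted depth with a strict threshold", {
  codes <- matrix(classCodes()[["seagrass"]], 4, 4)
  cm <- new("ClassMap", codes = codes, masked = matrix(FALSE, 4, 4))

  shallow <- applyDepthMask(cm, matrix(1, 4, 4), tideHeight = 0)
  expect_false(any(shallow@masked))

  # exactly at 2.5 m: retained (strict inequality)
  boundary <- applyDepthMask(cm, matrix(2.5, 4, 4), tideHeight = 0)
  expect_false(any(boundary@masked))
  over <- applyDepthMask(cm, matrix(2.5, 4, 4), tideHeight = 0.01)
  expect_true(all(over@masked))

  # a seagrass pixel at 3 m drops out of the extent
  dem <- matrix(1, 4, 4); dem[2, 2] <- 3
  masked <- applyDepthMask(cm, dem, tideHeight = 0)
  expect_equal(computeExtent(masked)@nPixels, 15)

  # land (NA depth) is never depth-masked
  demL <- matrix(NA_real_, 4, 4)
  expect_false(any(applyDepthMask(cm, demL, 0)@masked))
})

test_that("extent converts pixel counts at pixelSize^2 per pixel", {
  empty <- new("ClassMap", codes = matrix(classCodes()[["sand"]], 5, 5),
               masked = matrix(FALSE, 5, 5))
  expect_equal(computeExtent(empty)@areaKm2, 0)

  one <- new("ClassMap",
             codes = matrix(c(classCodes()[["seagrass"]],
                              rep(classCodes()[["sand"]], 24)), 5, 5),
             masked = matrix(FALSE, 5, 5))
  expect_equal(computeExtent(one)@areaKm2, 0.0009)

  # extent is monotone nonincreasing under additional masking
  pack <- scenePack(seed = 3L)
  cm <- truthClassMap(pack, depthMask = FALSE)
  before <- computeExtent(cm)@areaKm2
  after <- computeExtent(applyDepthMask(cm, pack$dem,
                                        pack$cfg@tideHeight))@areaKm2
  expect_lte(after, before)
})
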