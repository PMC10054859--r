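# Five-class per-pixel classification: training-set assembly, the neural
# classifier, depth masking and areal extent.

#' Extract a training set from ROI pixels
#'
#' One sample per ROI pixel: the pixel's full band vector, labelled with
#' the ROI's class.
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param rois a \linkS4class{ROISet} laid out on the same grid.
#' @return A \linkS4class{TrainingSet}.
#' @export
extractTraining <- function(scene, rois) {
  stopifnot(is(scene, "SceneStack"), is(rois, "ROISet"))
  d <- dim(scene@reflectance)
  tab <- rois@table
  bad <- tab$row0 + tab$h - 1L > d[1] | tab$col0 + tab$w - 1L > d[2]
  if (!identical(as.integer(rois@gridDim), as.integer(d[1:2])) ||
      any(bad)) {
    culprit <- if (any(bad)) tab$roi[bad][1] else tab$roi[1]
    stop("ROI ", culprit, " lies outside the scene grid")
  }
  flat <- matrix(scene@reflectance, d[1] * d[2], d[3])
  colnames(flat) <- scene@config@bands
  idx <- lapply(tab$roi, function(r) roiIndices(rois, r))
  spectra <- flat[unlist(idx), , drop = FALSE]
  labels <- factor(rep(tab$class, lengths(idx)), levels = .CLASS_LEVELS)
  new("TrainingSet", spectra = spectra, labels = labels)
}

#' Balance classes by resampling
#'
#' Randomly resamples each class with replacement to exactly
#' \code{nPerClass} samples, so every class contributes the same amount of
#' spectral information to training.
#'
#' @param ts a \linkS4class{TrainingSet}.
#' @param nPerClass samples per class after balancing (default 20000).
#' @param seed integer seed; resampling is deterministic per seed.
#' @return A balanced \linkS4class{TrainingSet}.
#' @export
balanceClasses <- function(ts, nPerClass = 20000L, seed = 1L) {
  stopifnot(is(ts, "TrainingSet"))
  present <- levels(droplevels(ts@labels))
  empty <- setdiff(levels(ts@labels), present)
  if (length(empty)) {
    stop("cannot balance: class(es) with no samples: ",
         paste(empty, collapse = ", "))
  }
  .withSeed(seed, {
    pick <- unlist(lapply(present, function(cl) {
      pool <- which(ts@labels == cl)
      pool[sample.int(length(pool), nPerClass, replace = TRUE)]
    }))
    new("TrainingSet", spectra = ts@spectra[pick, , drop = FALSE],
        labels = ts@labels[pick])
  })
}

#' Stratified train/test split
#'
#' Splits each class independently so the class balance carries over:
#' round(trainFraction * n) samples per class go to training, the rest to
#' testing, with disjoint indices.
#'
#' @param ts a \linkS4class{TrainingSet}.
#' @param trainFraction fraction in (0, 1), default 0.9.
#' @param seed integer seed.
#' @return List with elements \code{train} and \code{test}
#'   (\linkS4class{TrainingSet}s).
#' @export
splitTrainTest <- function(ts, trainFraction = 0.9, seed = 1L) {
  stopifnot(is(ts, "TrainingSet"))
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  counts <- table(droplevels(ts@labels))
  if (any(counts < 10)) stop("need at least 10 samples per class to split")
  .withSeed(seed, {
    trainIdx <- unlist(lapply(names(counts), function(cl) {
      pool <- which(ts@labels == cl)
      pool[sample.int(length(pool), round(trainFraction * length(pool)))]
    }))
    testIdx <- setdiff(seq_along(ts@labels), trainIdx)
    list(train = new("TrainingSet",
                     spectra = ts@spectra[trainIdx, , drop = FALSE],
                     labels = ts@labels[trainIdx]),
         test = new("TrainingSet",
                    spectra = ts@spectra[testIdx, , drop = FALSE],
                    labels = ts@labels[testIdx]))
  })
}

#' Train the per-pixel classifier
#'
#' Fits a small fully-connected network (single hidden layer, softmax
#' output) on per-pixel band vectors. At 30 m the class signal lives in
#' the per-pixel spectrum, so a compact network suffices; the
#' architecture is a configuration knob, not part of the contract. A
#' rough non-convergence check (training accuracy at chance level) emits
#' a warning but still returns the model.
#'
#' @param train a balanced \linkS4class{TrainingSet}.
#' @param config list of hyperparameters: \code{size} (hidden units,
#'   default 16), \code{decay} (L2, default 5e-4), \code{maxit}
#'   (default 200), \code{seed}.
#' @param test optional held-out \linkS4class{TrainingSet}; its accuracy
#'   is recorded in the training log.
#' @return A \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(train, config = list(), test = NULL) {
  stopifnot(is(train, "TrainingSet"))
  cfg <- utils::modifyList(
    list(size = 16L, decay = 5e-4, maxit = 200L, seed = 1L), config)
  labs <- droplevels(train@labels)
  if (nlevels(labs) < 2) stop("training set must contain at least 2 classes")
  y <- nnet::class.ind(labs)
  fit <- .withSeed(cfg$seed,
    nnet::nnet(train@spectra, y, size = cfg$size, decay = cfg$decay,
               maxit = cfg$maxit, softmax = TRUE, trace = FALSE,
               MaxNWts = 100000L))
  predClass <- function(x) {
    p <- stats::predict(fit, x)
    factor(colnames(p)[max.col(p, ties.method = "first")],
           levels = levels(labs))
  }
  trainAcc <- mean(predClass(train@spectra) == labs)
  log <- list(trainAccuracy = trainAcc, finalLoss = fit$value)
  if (trainAcc < 1 / nlevels(labs) + 0.1) {
    warning("classifier may not have converged (training accuracy ",
            round(trainAcc, 3), ")")
  }
  if (!is.null(test)) {
    testLabs <- factor(test@labels, levels = levels(labs))
    log$heldoutAccuracy <- mean(predClass(test@spectra) == testLabs)
  }
  new("ClassifierModel", fit = fit, bands = colnames(train@spectra),
      levels = levels(labs), config = cfg, log = log)
}

#' Predict class probabilities for a sample matrix
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param x numeric matrix, samples x bands in the model's band order.
#' @return Matrix of class probabilities (samples x classes).
#' @export
predictProb <- function(model, x) {
  stopifnot(is(model, "ClassifierModel"))
  if (ncol(x) != length(model@bands)) {
    stop("band count mismatch: model expects ", length(model@bands),
         " bands, got ", ncol(x))
  }
  p <- stats::predict(model@fit, x)
  colnames(p) <- model@levels[seq_len(ncol(p))]
  p
}

#' Classify every pixel of a scene
#'
#' Flattens the scene to a pixel x band matrix, scores it with the fitted
#' network and assigns each pixel the argmax class. Deterministic given
#' the model.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param scene a \linkS4class{SceneStack} with matching bands.
#' @return A \linkS4class{ClassMap} (nothing masked yet).
#' @export
predictMap <- function(model, scene) {
  stopifnot(is(model, "ClassifierModel"), is(scene, "SceneStack"))
  if (!identical(model@bands, scene@config@bands)) {
    stop("scene bands do not match the bands the model was trained on")
  }
  d <- dim(scene@reflectance)
  flat <- matrix(scene@reflectance, d[1] * d[2], d[3])
  colnames(flat) <- scene@config@bands
  p <- predictProb(model, flat)
  lab <- model@levels[max.col(p, ties.method = "first")]
  codes <- matrix(.CLASS_CODES[lab], d[1], d[2])
  new("ClassMap", codes = codes,
      masked = matrix(FALSE, d[1], d[2]))
}

#' Mask optically-deep pixels
#'
#' Flags pixels whose tide-adjusted depth strictly exceeds the threshold
#' (default 2.5 m) as masked, excluding them from extent and carbon
#' accounting; pixels exactly at the threshold are retained. Land pixels
#' (absent depth) are never depth-masked.
#'
#' @param cmap a \linkS4class{ClassMap}.
#' @param dem depth grid (m, NA over land).
#' @param tideHeight tide height (m).
#' @param threshold masking depth (m), strict inequality.
#' @return The \linkS4class{ClassMap} with updated mask flags.
#' @export
applyDepthMask <- function(cmap, dem, tideHeight = 0, threshold = 2.5) {
  stopifnot(is(cmap, "ClassMap"))
  .assertSameDim(cmap@codes, dem, "class map and DEM")
  H <- tideAdjust(dem, tideHeight)
  deep <- !is.na(H) & H > threshold
  new("ClassMap", codes = cmap@codes, masked = cmap@masked | deep)
}

#' Seagrass areal extent
#'
#' Counts unmasked seagrass pixels and converts to km^2: each pixel
#' contributes pixelSize^2 m^2 (900 m^2 at 30 m).
#'
#' @param cmap a \linkS4class{ClassMap}.
#' @param pixelSize pixel edge length (m), default 30.
#' @return An \linkS4class{ExtentResult}.
#' @export
#' @examples
#' m <- new("ClassMap", codes = matrix(2L, 4, 4),
#'          masked = matrix(FALSE, 4, 4))
#' computeExtent(m) # 16 pixels x 900 m^2
computeExtent <- function(cmap, pixelSize = 30) {
  stopifnot(is(cmap, "ClassMap"))
  n <- sum(cmap@codes == .codeOf("seagrass") & !cmap@masked)
  new("ExtentResult", nPixels = as.numeric(n),
      areaKm2 = n * pixelSize^2 * 1e-6, pixelSize = pixelSize)
}
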