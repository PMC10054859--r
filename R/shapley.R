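# Exact Shapley attribution of band importance by coalition enumeration.

#' Exact Shapley band importance
#'
#' Computes, for each sample, the exact Shapley value of every band by
#' enumerating all band coalitions (feasible for <= 8 bands: at most 256
#' coalitions). Bands absent from a coalition are replaced by their
#' per-band background value (by default the training mean). For a
#' classifier the per-sample model value is the predicted probability of
#' the class the full-band model assigns to that sample; any plain
#' function of a sample matrix returning one numeric per row can be
#' attributed the same way. Per-sample values satisfy the efficiency
#' identity exactly: they sum to f(all bands) - f(background).
#'
#' Reported importance is the mean absolute per-sample Shapley value,
#' normalised to percentages summing to 100.
#'
#' @param model a \linkS4class{ClassifierModel}, or a function mapping a
#'   numeric samples x bands matrix to one numeric value per row.
#' @param data a \linkS4class{TrainingSet} or numeric samples x bands
#'   matrix to attribute over.
#' @param background per-band replacement values for absent bands;
#'   defaults to the column means of \code{data}.
#' @param nSamples maximum number of samples to attribute (subsampled
#'   deterministically per \code{seed} when \code{data} is larger).
#' @param seed integer seed for the subsample.
#' @return A \linkS4class{BandImportance}.
#' @export
bandImportance <- function(model, data, background = NULL,
                           nSamples = 200L, seed = 1L) {
  x <- if (is(data, "TrainingSet")) data@spectra else as.matrix(data)
  nb <- ncol(x)
  if (nb > 8L) {
    stop("exact coalition enumeration supports at most 8 bands; ",
         "got ", nb, " - subset the bands or use a sampling approximation")
  }
  if (is.null(background)) background <- colMeans(x)
  if (nrow(x) > nSamples) {
    x <- .withSeed(seed, x[sample.int(nrow(x), nSamples), , drop = FALSE])
  }
  n <- nrow(x)

  f <- if (is(model, "ClassifierModel")) {
    pFull <- predictProb(model, x)
    target <- max.col(pFull, ties.method = "first")
    function(xs) {
      p <- predictProb(model, xs)
      p[cbind(seq_len(nrow(p)), rep_len(target, nrow(p)))]
    }
  } else {
    match.fun(model)
  }

  # model value under every coalition: v[s, i] for coalition bitmask s-1
  nS <- 2L^nb
  v <- matrix(NA_real_, nS, n)
  bg <- matrix(background, n, nb, byrow = TRUE)
  members <- function(s) which(bitwAnd(s, 2L^(seq_len(nb) - 1L)) != 0L)
  for (s in 0:(nS - 1L)) {
    xs <- bg
    inS <- members(s)
    if (length(inS)) xs[, inS] <- x[, inS, drop = FALSE]
    colnames(xs) <- colnames(x)
    v[s + 1L, ] <- f(xs)
  }

  sizes <- vapply(0:(nS - 1L), function(s) length(members(s)), integer(1))
  wt <- factorial(0:(nb - 1L)) * factorial(nb - 1L - 0:(nb - 1L)) /
    factorial(nb)
  phi <- matrix(0, n, nb,
                dimnames = list(NULL, colnames(x)))
  for (j in seq_len(nb)) {
    bit <- 2L^(j - 1L)
    without <- which(bitwAnd(0:(nS - 1L), bit) == 0L) # masks excluding j
    for (s in without) {
      w <- wt[sizes[s] + 1L]
      phi[, j] <- phi[, j] + w * (v[s + bit, ] - v[s, ])
    }
  }

  meanAbs <- colMeans(abs(phi))
  tot <- sum(meanAbs)
  percent <- if (tot > 0) 100 * meanAbs / tot
             else stats::setNames(rep(100 / nb, nb), colnames(x))
  new("BandImportance", percent = percent, meanAbs = meanAbs, phi = phi,
      baseValue = mean(v[1L, ]), method = "exact Shapley enumeration")
}
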