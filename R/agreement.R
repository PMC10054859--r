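# Presence/absence map comparison: confusion counts, the agreement metric
# suite (precision/recall/F, overall accuracy, kappa) and the McNemar test.

#' Binarize a class map to seagrass presence
#'
#' Seagrass pixels become TRUE, every other unmasked class FALSE, and
#' masked pixels NA (excluded from all agreement accounting).
#'
#' @param cmap a \linkS4class{ClassMap}.
#' @return Logical matrix with NA where masked.
#' @export
binarizePresence <- function(cmap) {
  stopifnot(is(cmap, "ClassMap"))
  out <- cmap@codes == .codeOf("seagrass")
  out[cmap@masked] <- NA
  out
}

#' Paired confusion counts for two presence grids
#'
#' Counts over pixels valid in both maps: a = present in both, b = A only,
#' c = B only, d = absent in both.
#'
#' @param mapA,mapB co-registered logical presence grids (NA = excluded).
#' @return A \linkS4class{ConfusionTable}.
#' @export
confusionTable <- function(mapA, mapB) {
  .assertSameDim(mapA, mapB, "presence grids")
  ok <- !is.na(mapA) & !is.na(mapB)
  a <- sum(mapA[ok] & mapB[ok])
  b <- sum(mapA[ok] & !mapB[ok])
  c <- sum(!mapA[ok] & mapB[ok])
  d <- sum(!mapA[ok] & !mapB[ok])
  confusionCounts(a, b, c, d)
}

#' F-measure from precision and recall
#'
#' The harmonic mean 2PR / (P + R); NA when either input is NA or both
#' are zero.
#'
#' @param precision,recall metric values in [0, 1].
#' @return The F-measure.
#' @export
#' @examples
#' fMeasure(0.93, 0.52)
fMeasure <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

.safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Agreement metric suite
#'
#' From the paired confusion counts: presence precision a/(a+b), recall
#' a/(a+c) and their harmonic mean F; the symmetric absence metrics on d;
#' overall accuracy (a+d)/n; and Cohen's kappa
#' (p_o - p_e) / (1 - p_e) with expected agreement p_e from the marginal
#' products. Zero-denominator ratios are reported as NA, never as 0.
#'
#' @param conf a \linkS4class{ConfusionTable}.
#' @return An \linkS4class{AgreementReport}.
#' @export
agreementReport <- function(conf) {
  stopifnot(is(conf, "ConfusionTable"))
  a <- conf@a; b <- conf@b; c <- conf@c; d <- conf@d
  n <- a + b + c + d
  if (n == 0) stop("empty confusion table")
  presP <- .safeRatio(a, a + b)
  presR <- .safeRatio(a, a + c)
  absP <- .safeRatio(d, d + c)
  absR <- .safeRatio(d, d + b)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) NA_real_
           else (po - pe) / (1 - pe)
  new("AgreementReport",
      presence = c(precision = presP, recall = presR,
                   f = fMeasure(presP, presR)),
      absence = c(precision = absP, recall = absR,
                  f = fMeasure(absP, absR)),
      overallAccuracy = po, kappa = kappa, n = n)
}

#' McNemar test on discordant pixels
#'
#' Tests whether the two maps disagree symmetrically, using only the
#' discordant cells: chi^2 = (b - c)^2 / (b + c), or
#' (|b - c| - 1)^2 / (b + c) with the continuity correction; p from the
#' chi-squared distribution with 1 df.
#'
#' @param conf a \linkS4class{ConfusionTable}.
#' @param corrected apply the continuity correction (default FALSE).
#' @return A \linkS4class{McNemarResult}; chi-squared and p are NA when
#'   there are no discordant pixels.
#' @export
mcnemarTest <- function(conf, corrected = FALSE) {
  stopifnot(is(conf, "ConfusionTable"))
  b <- conf@b; c <- conf@c
  if (b + c == 0) {
    warning("no discordant pixels; McNemar statistic undefined")
    return(new("McNemarResult", chiSquare = NA_real_, pValue = NA_real_,
               b = b, c = c, corrected = corrected))
  }
  num <- if (corrected) (abs(b - c) - 1)^2 else (b - c)^2
  chi <- num / (b + c)
  new("McNemarResult", chiSquare = chi,
      pValue = stats::pchisq(chi, df = 1, lower.tail = FALSE),
      b = b, c = c, corrected = corrected)
}

#' Difference map of two presence grids
#'
#' Codes each co-valid pixel: 0 = absent in both, 1 = A only, 2 = B only,
#' 3 = present in both; NA where either map is excluded.
#'
#' @param mapA,mapB co-registered logical presence grids.
#' @return Integer matrix of difference codes.
#' @export
differenceMap <- function(mapA, mapB) {
  .assertSameDim(mapA, mapB, "presence grids")
  out <- mapA * 0L
  out[mapA & !mapB] <- 1L
  out[!mapA & mapB] <- 2L
  out[mapA & mapB] <- 3L
  out[is.na(mapA) | is.na(mapB)] <- NA_integer_
  mode(out) <- "integer"
  out
}
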