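# Dark-object-subtraction atmospheric correction and scene conditioning.

#' Locate the dark pixel and per-band offsets
#'
#' Scans the NIR band within the supplied water mask for its strict
#' minimum (clear water absorbs NIR almost completely, so the darkest NIR
#' water pixel carries essentially pure atmospheric path signal). Ties are
#' broken by row-major scan order from the top-left. The returned offsets
#' are that pixel's values in every band.
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param waterMask logical matrix, TRUE over water; masking out land and
#'   inland water bodies keeps the dark pixel marine.
#' @return A \linkS4class{DarkOffset}.
#' @export
findDarkOffset <- function(scene, waterMask) {
  stopifnot(is(scene, "SceneStack"))
  .assertSameDim(waterMask, scene@reflectance, "water mask and scene")
  if (!any(waterMask, na.rm = TRUE)) {
    stop("water mask is empty: no pixels to search for a dark object")
  }
  waterMask[is.na(waterMask)] <- FALSE
  nir <- scene@reflectance[, , scene@config@nirBand]
  minVal <- min(nir[waterMask])
  dark <- .firstInScanOrder(waterMask & nir == minVal)
  offsets <- scene@reflectance[dark["row"], dark["col"], ]
  new("DarkOffset", offsets = offsets,
      darkPixel = as.integer(dark), sourceBand = scene@config@nirBand)
}

#' Apply dark-object subtraction
#'
#' Subtracts each band's offset and clips negatives to zero (a pixel
#' darker than the dark object is sensor noise, not signal). Metadata is
#' preserved. Re-running the correction on its own output recovers zero
#' offsets, so the operation is idempotent.
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param offsets a \linkS4class{DarkOffset} from \code{\link{findDarkOffset}},
#'   or a named per-band numeric vector.
#' @return The corrected \linkS4class{SceneStack}; the number of clipped
#'   pixels is attached as attribute \code{"clipped"} on the reflectance.
#' @export
dosCorrect <- function(scene, offsets) {
  stopifnot(is(scene, "SceneStack"))
  off <- if (is(offsets, "DarkOffset")) offsets@offsets else offsets
  bands <- scene@config@bands
  if (!all(bands %in% names(off))) {
    stop("offsets do not cover the scene bands: missing ",
         paste(setdiff(bands, names(off)), collapse = ", "))
  }
  refl <- scene@reflectance
  clipped <- 0L
  for (b in bands) {
    layer <- refl[, , b] - off[[b]]
    clipped <- clipped + sum(layer < 0)
    refl[, , b] <- pmax(layer, 0)
  }
  out <- new("SceneStack", reflectance = refl, config = scene@config)
  attr(out@reflectance, "clipped") <- clipped
  out
}

#' Fill data gaps by iterative neighbourhood means
#'
#' Replaces gap pixels (scanline stripes, dropouts) with the mean of their
#' non-gap 8-neighbours, iterating from the gap edges inwards until every
#' gap is filled, then relaxing the filled values to the stable
#' neighbourhood-mean (harmonic) solution so stripes on smooth gradients
#' interpolate rather than copy their nearest edge. Non-gap pixels are
#' never touched. This is a deliberately simple in-painting of narrow
#' stripes, not a geostatistical reconstruction.
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param gapMask logical matrix, TRUE where data are missing.
#' @return The filled \linkS4class{SceneStack}.
#' @export
fillGaps <- function(scene, gapMask) {
  stopifnot(is(scene, "SceneStack"))
  .assertSameDim(gapMask, scene@reflectance, "gap mask and scene")
  if (!any(gapMask)) return(scene)
  if (all(gapMask)) stop("gap mask covers the whole scene: nothing to fill from")
  refl <- scene@reflectance
  for (b in seq_len(dim(refl)[3])) {
    refl[, , b] <- .fillBand(refl[, , b], gapMask)
  }
  new("SceneStack", reflectance = refl, config = scene@config)
}

# 8-neighbour iterative mean fill of a single band: fill inwards from the
# gap edges, then Jacobi-relax the gap values to the neighbourhood-mean
# fixed point (non-gap pixels are Dirichlet boundary data).
.fillBand <- function(m, gap) {
  nr <- nrow(m); nc <- ncol(m)
  m[gap] <- NA_real_
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  neighbourStats <- function(x, weightMask) {
    acc <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      rt <- rs - dr; ct <- cs - dc
      acc[rt, ct] <- acc[rt, ct] + x[rs, cs]
      cnt[rt, ct] <- cnt[rt, ct] + weightMask[rs, cs]
    }
    list(acc = acc, cnt = cnt)
  }
  while (anyNA(m)) {
    known <- !is.na(m)
    x <- m
    x[!known] <- 0
    ns <- neighbourStats(x, known)
    fill <- !known & ns$cnt > 0
    if (!any(fill)) stop("gap region has no data neighbours; cannot fill")
    m[fill] <- ns$acc[fill] / ns$cnt[fill]
  }
  # Relax gap pixels to the stable neighbourhood-mean solution, using a
  # symmetric (paired) stencil: a neighbour only counts when its mirror
  # across the centre is also on the grid. Pairing cancels the first-order
  # gradient term, so smooth ramps interpolate without drift at the grid
  # edges, where a one-sided stencil would pull values toward the interior.
  pairStats <- function(x) {
    acc <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    pairs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (p in pairs) {
      dr <- p[1]; dc <- p[2]
      if (1 + abs(dr) > nr - abs(dr) || 1 + abs(dc) > nc - abs(dc)) next
      rs <- (1 + abs(dr)):(nr - abs(dr))
      cs <- (1 + abs(dc)):(nc - abs(dc))
      acc[rs, cs] <- acc[rs, cs] + x[rs + dr, cs + dc, drop = FALSE] +
        x[rs - dr, cs - dc, drop = FALSE]
      cnt[rs, cs] <- cnt[rs, cs] + 2
    }
    list(acc = acc, cnt = cnt)
  }
  for (it in seq_len(500L)) {
    ns <- pairStats(m)
    relax <- gap & ns$cnt > 0
    newVals <- ns$acc[relax] / ns$cnt[relax]
    delta <- max(abs(newVals - m[relax]))
    m[relax] <- newVals
    if (delta < 1e-10) break
  }
  m
}

#' Crop a scene to a rectangular window
#'
#' Utility used when restricting analysis to a region of interest; keeps
#' the configuration in step with the new grid size.
#'
#' @param scene a \linkS4class{SceneStack}.
#' @param rows,cols integer index vectors (contiguous ranges).
#' @return The cropped \linkS4class{SceneStack}.
#' @export
cropScene <- function(scene, rows, cols) {
  stopifnot(is(scene, "SceneStack"))
  refl <- scene@reflectance[rows, cols, , drop = FALSE]
  cfg <- scene@config
  cfg@nRows <- length(rows)
  cfg@nCols <- length(cols)
  new("SceneStack", reflectance = refl, config = cfg)
}
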