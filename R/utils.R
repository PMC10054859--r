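# Internal helpers shared across modules.

# Integer codes for the five bottom/land classes. Order is part of the
# on-disk contract for class-map rasters.
.CLASS_LEVELS <- c("land", "deep_water", "seagrass", "sand", "intertidal")
.CLASS_CODES <- stats::setNames(0:4, .CLASS_LEVELS)

#' Class code table
#'
#' The five surface classes used throughout the pipeline and their integer
#' raster codes: land = 0, optically-deep water = 1, seagrass = 2,
#' submerged sand = 3, intertidal = 4.
#'
#' @return Named integer vector of length five.
#' @export
#' @examples
#' classCodes()
classCodes <- function() .CLASS_CODES

.codeOf <- function(class) {
  class <- match.arg(class, .CLASS_LEVELS)
  unname(.CLASS_CODES[class])
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian smoothing of a matrix. NA cells are ignored and the
# kernel renormalised, so smoothing never bleeds land (NA) into water.
.gsmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  na <- is.na(m)
  x <- m
  x[na] <- 0
  mask <- 1 - na
  smooth1 <- function(v, along) {
    acc <- 0 * v
    n <- if (along == 1L) nrow(v) else ncol(v)
    for (k in -h:h) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n) # replicate edges
      acc <- acc + w[k + h + 1L] * (if (along == 1L) v[idx, , drop = FALSE]
                                    else v[, idx, drop = FALSE])
    }
    acc
  }
  num <- smooth1(smooth1(x, 1L), 2L)
  den <- smooth1(smooth1(mask, 1L), 2L)
  out <- num / den
  out[na] <- NA_real_
  out
}

# Row-major (top-left origin) scan rank of every cell of an nr x nc grid,
# used for deterministic tie-breaking.
.scanRank <- function(nr, nc) {
  matrix(seq_len(nr * nc), nrow = nr, ncol = nc, byrow = TRUE)
}

# First (row, col) in row-major scan order among TRUE cells.
.firstInScanOrder <- function(hit) {
  stopifnot(any(hit))
  rank <- .scanRank(nrow(hit), ncol(hit))
  rank[!hit] <- NA_integer_
  at <- which(rank == min(rank, na.rm = TRUE), arr.ind = TRUE)
  c(row = as.integer(at[1, 1]), col = as.integer(at[1, 2]))
}

.assertSameDim <- function(a, b, what = "grids") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(what, " have mismatched dimensions: ",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}
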