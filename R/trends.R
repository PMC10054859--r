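# Trend detection for annual series: seasonal Mann-Kendall, Theil-Sen,
# trend detectability (gamma), frequency maps and climate-driver MLR.

#' Build an annual series
#'
#' @param year integer years (strictly increasing within each season).
#' @param value numeric metric values (extent km^2, mean LAI, BGC, ...).
#' @param season season tags (one block per tag); default one season.
#' @return data.frame with columns year, season, value, ordered by season
#'   then year.
#' @export
annualSeries <- function(year, value, season = "annual") {
  stopifnot(length(year) == length(value))
  df <- data.frame(year = as.numeric(year),
                   season = rep_len(as.character(season), length(year)),
                   value = as.numeric(value))
  df <- df[order(df$season, df$year), ]
  dup <- stats::aggregate(year ~ season, df, anyDuplicated)
  if (any(dup$year > 0)) {
    stop("years must be strictly increasing within a season")
  }
  rownames(df) <- NULL
  df
}

# Kendall S, tie-corrected variance and tau-b denominator for one block.
.mkBlock <- function(value) {
  n <- length(value)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(value[(i + 1):n] - value[i]))
  }
  ties <- table(value)
  t <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
           sum(t * (t - 1) * (2 * t + 5))) / 18
  d0 <- n * (n - 1) / 2
  denom <- sqrt((d0 - sum(t * (t - 1) / 2)) * d0) # times are untied
  list(s = s, varS = varS, denom = denom)
}

#' Seasonal Mann-Kendall test
#'
#' Rank-based test for a monotonic trend. The Kendall S statistic is
#' computed within each season and summed across seasons, with
#' tie-corrected variance; the two-sided p-value uses the
#' continuity-corrected normal approximation. With a single season this is
#' the ordinary Mann-Kendall test, and tau reduces to Kendall's tau-b.
#'
#' @param series an annual series from \code{\link{annualSeries}}.
#' @return List with tau, p, S and varS.
#' @export
mannKendall <- function(series) {
  blocks <- split(series$value, series$season)
  if (any(vapply(blocks, length, integer(1)) < 4)) {
    stop("need at least 4 observations per season")
  }
  parts <- lapply(blocks, .mkBlock)
  S <- sum(vapply(parts, `[[`, numeric(1), "s"))
  varS <- sum(vapply(parts, `[[`, numeric(1), "varS"))
  denom <- sum(vapply(parts, `[[`, numeric(1), "denom"))
  if (varS == 0 || denom == 0) {
    warning("all values tied; no trend information")
    return(list(tau = 0, p = 1, S = S, varS = varS))
  }
  tau <- S / denom
  z <- (S - sign(S)) / sqrt(varS)
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p = min(p, 1), S = S, varS = varS)
}

#' Theil-Sen slope
#'
#' Median of all within-season pairwise slopes
#' (value_j - value_i) / (year_j - year_i); pairs sharing a year are
#' skipped. Robust to outliers; with one season this is the classic
#' Theil-Sen estimator.
#'
#' @param series an annual series from \code{\link{annualSeries}}.
#' @return Slope in metric units per year.
#' @export
theilSen <- function(series) {
  slopes <- unlist(lapply(split(series, series$season), function(blk) {
    n <- nrow(blk)
    if (n < 2) return(numeric(0))
    out <- numeric(0)
    for (i in seq_len(n - 1)) {
      dy <- blk$value[(i + 1):n] - blk$value[i]
      dx <- blk$year[(i + 1):n] - blk$year[i]
      out <- c(out, dy[dx != 0] / dx[dx != 0])
    }
    out
  }))
  if (!length(slopes)) stop("no valid pairs to estimate a slope from")
  stats::median(slopes)
}

#' Percent change per year
#'
#' 100 x slope / mean(series value); sign follows the slope.
#'
#' @param slope Theil-Sen slope (units per year).
#' @param series the annual series the slope came from.
#' @return Percent change per year, NA with a warning for a zero-mean
#'   series.
#' @export
percentChange <- function(slope, series) {
  m <- mean(series$value)
  if (m == 0) {
    warning("series mean is zero; percent change undefined")
    return(NA_real_)
  }
  100 * slope / m
}

#' Years of record needed for a trend to emerge from noise
#'
#' The detectability form
#' \deqn{n^* = \left[\frac{3.3\,\sigma_N}{|\omega|}
#'   \sqrt{\frac{1+\phi}{1-\phi}}\right]^{2/3},}
#' the number of years needed for a trend of magnitude omega (units/yr)
#' to be detected, at roughly 90% power, against noise with standard
#' deviation sigma_N and lag-1 autocorrelation phi.
#'
#' @param sigma residual (noise) standard deviation, >= 0.
#' @param phi lag-1 autocorrelation in (-1, 1).
#' @param slope trend magnitude omega in units per year.
#' @return Years (numeric); NA for a zero slope.
#' @export
#' @examples
#' detectabilityYears(1, 0, 0.1) # 33^(2/3) ~ 10.30 years
detectabilityYears <- function(sigma, phi, slope) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  if (slope == 0) return(NA_real_)
  (3.3 * sigma / abs(slope) * sqrt((1 + phi) / (1 - phi)))^(2 / 3)
}

#' Years of record needed to detect the trend (gamma)
#'
#' Applies \code{\link{detectabilityYears}} to one annual series: sigma_N
#' is the standard deviation of the residuals about the Sen line and phi
#' their lag-1 autocorrelation. A zero slope leaves gamma undefined (NA).
#'
#' @param series an annual series from \code{\link{annualSeries}}.
#' @param slope the Theil-Sen slope; computed from the series if missing.
#' @return Years (numeric), or NA when the slope is exactly zero.
#' @export
gammaYears <- function(series, slope = theilSen(series)) {
  if (nrow(series) < 4) stop("need at least 4 observations")
  if (slope == 0) return(NA_real_)
  ord <- order(series$year)
  resid <- series$value[ord] - slope * series$year[ord]
  sigma <- stats::sd(resid)
  if (sigma == 0) return(0)
  phi <- stats::cor(resid[-1], resid[-length(resid)])
  if (!is.finite(phi)) phi <- 0
  phi <- min(max(phi, -0.99), 0.99)
  detectabilityYears(sigma, phi, slope)
}

#' Percent decline between two extent estimates
#'
#' The before/after arithmetic used when differencing extent across a
#' disturbance: 100 x (before - after) / before. Positive values are
#' declines.
#'
#' @param before,after extents (km^2 or any common unit), before > 0.
#' @return Percent change relative to \code{before}.
#' @export
#' @examples
#' percentDecline(26, 16) # the 38% post-storm drop
percentDecline <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be > 0")
  100 * (before - after) / before
}

#' Trend-strength label from tau
#'
#' |tau| >= 0.5 is a strong trend, 0.3 <= |tau| < 0.5 moderate,
#' 0.1 <= |tau| < 0.3 weak, below 0.1 none.
#'
#' @param tau Kendall's tau in [-1, 1].
#' @return One of "none", "weak", "moderate", "strong".
#' @export
strengthLabel <- function(tau) {
  if (abs(tau) > 1 + 1e-12) stop("|tau| must be <= 1")
  a <- abs(tau)
  if (a >= 0.5) "strong"
  else if (a >= 0.3) "moderate"
  else if (a >= 0.1) "weak"
  else "none"
}

#' Full trend analysis of one annual series
#'
#' Bundles the seasonal Mann-Kendall test, the Theil-Sen slope, percent
#' change per year, the gamma detectability statistic and the tau strength
#' label into one result.
#'
#' @param series an annual series from \code{\link{annualSeries}}.
#' @return A \linkS4class{TrendResult}.
#' @export
trendAnalysis <- function(series) {
  mk <- mannKendall(series)
  slope <- theilSen(series)
  new("TrendResult", tau = mk$tau, pValue = mk$p, senSlope = slope,
      percentChange = percentChange(slope, series),
      gammaYears = gammaYears(series, slope),
      strengthLabel = strengthLabel(mk$tau), n = nrow(series))
}

#' Per-pixel seagrass frequency across a scene stack
#'
#' For every pixel, the fraction of scenes in which it was classified
#' seagrass, counting only scenes where the pixel was unmasked (masked
#' scenes drop out of both numerator and denominator).
#'
#' @param classmaps list of co-registered \linkS4class{ClassMap}s.
#' @return A \linkS4class{FrequencyGrid}; pixels masked in every scene
#'   have frequency NA.
#' @export
frequencyMap <- function(classmaps) {
  if (!length(classmaps)) stop("empty class-map stack")
  stopifnot(all(vapply(classmaps, is, logical(1), "ClassMap")))
  d <- dim(classmaps[[1]]@codes)
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  for (cm in classmaps) {
    .assertSameDim(cm@codes, classmaps[[1]]@codes, "class maps")
    ok <- !cm@masked
    num <- num + (ok & cm@codes == .codeOf("seagrass"))
    den <- den + ok
  }
  freq <- num / den
  freq[den == 0] <- NA_real_
  new("FrequencyGrid", freq = freq, nScenes = matrix(as.integer(den), d[1]),
      nStack = length(classmaps))
}

#' Climate-driver multiple linear regression
#'
#' Ordinary least squares of an annual metric on an intercept plus
#' climate predictors (by default the ENSO and NAO indices), with
#' per-coefficient t statistics and two-sided p-values on n - k - 1
#' degrees of freedom, and the adjusted r-squared.
#'
#' @param series an annual series from \code{\link{annualSeries}}.
#' @param covariates data.frame with a \code{year} column and one column
#'   per predictor (see \code{\link{simulateCovariates}}).
#' @param predictors character vector of covariate columns to use.
#' @return An \linkS4class{MLRResult}.
#' @export
mlrDrivers <- function(series, covariates,
                       predictors = c("enso", "nao")) {
  missing <- setdiff(predictors, names(covariates))
  if (length(missing)) {
    stop("covariates lack column(s): ", paste(missing, collapse = ", "))
  }
  df <- merge(series, covariates[, c("year", predictors)], by = "year")
  n <- nrow(df)
  if (n <= length(predictors) + 1) {
    stop("need more observations than predictors plus one")
  }
  fml <- stats::as.formula(paste("value ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  new("MLRResult",
      coefficients = data.frame(term = rownames(co), beta = co[, 1],
                                se = co[, 2], t = co[, 3], p = co[, 4],
                                row.names = NULL),
      adjR2 = sm$adj.r.squared, n = as.integer(n))
}
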