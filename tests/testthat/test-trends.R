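# Trend statistics: Mann-Kendall, Theil-Sen, gamma, frequency, MLR.

# Brute-force Kendall S and tau over all pairs (independent of the
# package's blocked implementation).
bruteMK <- function(value) {
  n <- length(value)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(value[j] - value[i])
    }
  }
  list(S = s, tau = s / (n * (n - 1) / 2))
}

test_that("Mann-Kendall handles monotone, constant and small enumerated series", {
  up <- annualSeries(2001:2010, 1:10)
  expect_equal(mannKendall(up)$tau, 1)

  flat <- annualSeries(2001:2010, rep(3, 10))
  expect_warning(mk0 <- mannKendall(flat), "tied")
  expect_equal(mk0$tau, 0)
  expect_equal(mk0$p, 1)

  # n = 6, no ties: exhaustive pair-sign enumeration as the oracle
  vals <- c(2.3, 1.1, 3.7, 0.4, 2.9, 2.0)
  s <- annualSeries(1:6, vals)
  mk <- mannKendall(s)
  oracle <- bruteMK(vals)
  expect_equal(mk$S, oracle$S, tolerance = 1e-12)
  expect_equal(mk$tau, oracle$tau, tolerance = 1e-12)

  # independent p formula: continuity-corrected normal approximation with
  # untied variance n(n-1)(2n+5)/18
  varS <- 6 * 5 * 17 / 18
  pOracle <- 2 * pnorm(-abs((oracle$S - sign(oracle$S)) / sqrt(varS)))
  expect_equal(mk$p, pOracle, tolerance = 1e-12)

  # cross-check tau against the standard correlation implementation
  expect_equal(mk$tau, unname(cor(1:6, vals, method = "kendall")),
               tolerance = 1e-12)

  # exact permutation p (all 720 orderings) brackets the approximation
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  sNull <- vapply(perms(vals), function(p) bruteMK(p)$S, numeric(1))
  pExact <- mean(abs(sNull) >= abs(oracle$S))
  expect_lt(abs(mk$p - pExact), 0.1)
})

test_that("seasonal blocking sums S within seasons and reduces to ordinary MK", {
  a <- c(1.2, 3.1, 2.2, 4.0, 3.9)
  b <- c(5.0, 4.2, 6.1, 6.3, 7.2)
  two <- annualSeries(rep(2001:2005, 2), c(a, b),
                      season = rep(c("autumn", "summer"), each = 5))
  mk <- mannKendall(two)
  expect_equal(mk$S, bruteMK(a)$S + bruteMK(b)$S)

  one <- annualSeries(2001:2005, a)
  expect_equal(mannKendall(one)$S, bruteMK(a)$S)
  expect_error(mannKendall(annualSeries(2001:2003, 1:3)), "at least 4")
})

test_that("Theil-Sen is the median pairwise slope and robust to outliers", {
  line <- annualSeries(0:9, 2 * (0:9) + 1)
  expect_equal(theilSen(line), 2)
  expect_equal(theilSen(annualSeries(1:5, rep(7, 5))), 0)

  # n = 4 scrambled: enumerate all C(4,2) = 6 pairwise slopes by hand
  yr <- c(1, 2, 3, 4)
  v <- c(3.0, 1.0, 4.0, 2.0)
  slopes <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    slopes <- c(slopes, (v[j] - v[i]) / (yr[j] - yr[i]))
  }
  expect_equal(theilSen(annualSeries(yr, v)), median(slopes),
               tolerance = 1e-12)

  # duplicate years within a season contribute no pairs
  dup <- data.frame(year = c(1, 1, 2), season = "s", value = c(0, 10, 2))
  expect_equal(theilSen(dup), median(c(2, -8)))

  # 20% gross outliers move the slope by < 10%
  set.seed(9)
  n <- 30
  y <- 1.5 * (1:n) + rnorm(n, sd = 0.3)
  y[sample(n, 6)] <- y[sample(n, 6)] + 40
  est <- theilSen(annualSeries(1:n, y))
  expect_lt(abs(est - 1.5) / 1.5, 0.10)
})

test_that("percent change scales the slope by the series mean", {
  s <- annualSeries(1:10, rep(23, 10))
  expect_equal(percentChange(0, s), 0)
  expect_equal(percentChange(0.23, s), 1.0)
  expect_lt(percentChange(-0.1, s), 0)
  zero <- annualSeries(1:4, c(-1, 1, -1, 1))
  expect_warning(pc <- percentChange(0.5, zero), "zero")
  expect_true(is.na(pc))
})

test_that("storm decline arithmetic follows 100 (before - after) / before", {
  expect_equal(percentDecline(26, 16), 100 * 10 / 26)
  expect_equal(percentDecline(20, 22), -10)
  expect_error(percentDecline(0, 5), "> 0")
})

test_that("gamma detectability matches the closed form and is monotone in slope", {
  expect_equal(detectabilityYears(1, 0, 0.1), 33^(2 / 3), tolerance = 1e-12)
  expect_equal(detectabilityYears(1, 0, 0.1), 10.29, tolerance = 1e-3)
  expect_true(is.na(detectabilityYears(1, 0, 0)))

  # strictly decreasing in |slope| at fixed sigma, phi
  g <- vapply(seq(0.05, 2, length.out = 30),
              function(w) detectabilityYears(1.3, 0.4, w), numeric(1))
  expect_true(all(diff(g) < 0))

  # positive autocorrelation inflates the record needed
  expect_gt(detectabilityYears(1, 0.6, 0.1), detectabilityYears(1, 0, 0.1))

  # series wrapper: zero Sen slope leaves gamma undefined
  s <- annualSeries(1:8, rep(c(1, 2), 4))
  expect_true(is.na(gammaYears(s, slope = 0)))
  sTrend <- annualSeries(1:12, 0.4 * (1:12) + c(0.2, -0.1, 0, 0.3, -0.2,
                                                0.1, 0, -0.3, 0.2, 0.1,
                                                -0.1, 0))
  expect_gt(gammaYears(sTrend), 0)
})

test_that("tau strength labels follow the fixed thresholds", {
  expect_identical(strengthLabel(0.09), "none")
  expect_identical(strengthLabel(-0.5), "strong")
  expect_identical(strengthLabel(0.3), "moderate")
  expect_identical(strengthLabel(0.1), "weak")
  expect_identical(strengthLabel(-0.29), "weak")
  expect_identical(strengthLabel(1), "strong")
  expect_error(strengthLabel(1.2), "<= 1")
})

test_that("frequency map counts seagrass presence over unmasked scenes", {
  mk <- function(code, maskAt = NULL) {
    codes <- matrix(code, 4, 4)
    masked <- matrix(FALSE, 4, 4)
    if (!is.null(maskAt)) masked[maskAt] <- TRUE
    new("ClassMap", codes = codes, masked = masked)
  }
  sgCode <- classCodes()[["seagrass"]]
  always <- frequencyMap(replicate(5, mk(sgCode), simplify = FALSE))
  expect_true(all(always@freq == 1))
  never <- frequencyMap(replicate(5, mk(classCodes()[["sand"]]),
                                  simplify = FALSE))
  expect_true(all(never@freq == 0))

  # 13 seagrass scenes of 31
  stack31 <- c(replicate(13, mk(sgCode), simplify = FALSE),
               replicate(18, mk(classCodes()[["sand"]]), simplify = FALSE))
  f31 <- frequencyMap(stack31)
  expect_equal(f31@freq[1, 1], 13 / 31, tolerance = 1e-12)

  # permutation invariance of the stack order
  set.seed(3)
  expect_identical(frequencyMap(sample(stack31))@freq, f31@freq)

  # masked scenes leave both numerator and denominator at that pixel
  stackM <- list(mk(sgCode), mk(classCodes()[["sand"]]),
                 mk(sgCode, maskAt = cbind(2, 2)))
  fM <- frequencyMap(stackM)
  expect_equal(fM@freq[2, 2], 1 / 2)
  expect_equal(fM@freq[1, 1], 2 / 3)
  expect_equal(fM@nScenes[2, 2], 2L)

  allMasked <- list(mk(sgCode, maskAt = cbind(1, 1)),
                    mk(sgCode, maskAt = cbind(1, 1)))
  expect_true(is.na(frequencyMap(allMasked)@freq[1, 1]))

  expect_error(frequencyMap(list()), "empty")
})

test_that("driver regression matches closed-form OLS and flags collinearity", {
  cov <- simulateCovariates(1991:2021, seed = 5L)
  # exact linear response: beta recovered, adjusted r^2 = 1
  exact <- annualSeries(cov$year, 2 * cov$enso)
  res <- suppressWarnings(mlrDrivers(exact, cov)) # exact fit: lm notes it
  expect_equal(res@coefficients$beta[res@coefficients$term == "enso"], 2,
               tolerance = 1e-9)
  expect_equal(res@adjR2, 1, tolerance = 1e-9)

  # small fixed dataset against the normal-equations oracle
  set.seed(8)
  y <- 23 + 0.9 * cov$enso - 0.4 * cov$nao + rnorm(31)
  s <- annualSeries(cov$year, y)
  res2 <- mlrDrivers(s, cov)
  X <- cbind(1, cov$enso, cov$nao)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res2@coefficients$beta, as.vector(beta), tolerance = 1e-10)

  # t and p consistent with the coefficient table identity t = beta / se
  expect_equal(res2@coefficients$t,
               res2@coefficients$beta / res2@coefficients$se,
               tolerance = 1e-12)

  cov$dup <- cov$enso
  expect_error(mlrDrivers(s, cov, predictors = c("enso", "dup")),
               "collinear|rank")
  expect_error(mlrDrivers(s, cov, predictors = "missing_col"), "lack")
})

test_that("regression p-values are uniform under the null", {
  cov <- simulateCovariates(1990:2020, seed = 7L)
  set.seed(12)
  ps <- replicate(1000, {
    s <- annualSeries(cov$year, rnorm(31))
    res <- mlrDrivers(s, cov)
    res@coefficients$p[res@coefficients$term == "enso"]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MK power at the gamma-implied record length is reported", {
  # informational: the detectability form calibrates to monthly sampling,
  # so for annual series it understates the record needed; record the
  # empirical power rather than asserting a level
  set.seed(5)
  slope <- 0.3
  g <- ceiling(detectabilityYears(1, 0, slope))
  pow <- mean(replicate(200, {
    y <- slope * seq_len(g) + rnorm(g)
    mannKendall(annualSeries(2000 + seq_len(g), y))$p < 0.05
  }))
  expect_true(pow >= 0 && pow <= 1)
  message(sprintf("MK power at n = gamma = %d (slope %.2f, sd 1): %.3f",
                  g, slope, pow))
})
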