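# Profile-curve fitting: noiseless parameter recovery, noisy-estimator
# behaviour, family selection, closed-form evaluation, percentile bands.

test_that("noiseless data are a fixed point of the fit for every family", {
  # gaussian
  y <- 0.8 * exp(-(flightDays - 170)^2 / (2 * 30^2))
  cv <- fitProfile(flightDays, y, "gaussian")
  expect_equal(unname(curveParams(cv)), c(0.8, 170, 30),
               tolerance = 1e-6)
  expect_true(cv@converged)
  # weibull
  yw <- 0.9 * (1 - exp(-(flightDays / 120)^5))
  cw <- fitProfile(flightDays, yw, "weibull")
  expect_equal(unname(curveParams(cw)[c("L", "b", "x0")]),
               c(0.9, 5, 120), tolerance = 1e-6)
  # fourier (order 3, linear fit is exact)
  L <- diff(range(flightDays))
  k <- c(a1 = 0.3, b1 = 0.1, a2 = -0.05, b2 = 0.2, a3 = 0.01, b3 = -0.02)
  yf <- as.vector(wheatNRES:::fourierBasis(flightDays, L, 3) %*% k)
  cf <- fitProfile(flightDays, yf, "fourier", order = 3)
  expect_equal(curveParams(cf)[names(k)], k, tolerance = 1e-6)
  expect_equal(curveParams(cf)[["L"]], L)
})

test_that("constant series with weibull is flagged degenerate", {
  expect_warning(fitProfile(flightDays, rep(0.5, 10), "weibull"),
                 "degenerate")
})

test_that("too few observations is an error", {
  expect_error(fitProfile(c(30, 60, 90), c(0.1, 0.2, 0.3), "gaussian"),
               "at least")
})

test_that("weibull plateau is recovered within 0.02 median error under 1% noise", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- 0.9 * (1 - exp(-(flightDays / 120)^5)) + rnorm(10, 0, 0.01)
    fit <- fitProfile(flightDays, y, "weibull")
    abs(curveParams(fit)[["L"]] - 0.9)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("estimator error shrinks as noise shrinks (3-level ladder)", {
  medErr <- vapply(c(0.03, 0.01, 0.002), function(sdn) {
    errs <- vapply(1:20, function(s) {
      set.seed(1000 * sdn * 1e3 + s)
      y <- 0.8 * exp(-(flightDays - 170)^2 / (2 * 30^2)) +
        rnorm(10, 0, sdn)
      abs(curveParams(fitProfile(flightDays, y, "gaussian"))[["a"]] - 0.8)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(medErr) < 0))
})

test_that("the generating family wins AIC selection on noiseless draws", {
  set.seed(42)
  wins <- 0L; tries <- 0L
  for (i in 1:15) {
    a <- runif(1, 0.4, 0.9); b <- runif(1, 140, 185); cc <- runif(1, 25, 55)
    s <- selectFamily(flightDays, a * exp(-(flightDays - b)^2 / (2 * cc^2)))
    wins <- wins + (s$family == "gaussian")
    L <- runif(1, 0.6, 0.95); x0 <- runif(1, 90, 130); bb <- runif(1, 2.5, 6)
    s <- selectFamily(flightDays, L * (1 - exp(-(flightDays / x0)^bb)))
    wins <- wins + (s$family == "weibull")
    k <- rnorm(6, 0, 0.2)
    B <- wheatNRES:::fourierBasis(flightDays, diff(range(flightDays)), 3)
    s <- selectFamily(flightDays, as.vector(B %*% k), order = 3)
    wins <- wins + (s$family == "fourier")
    tries <- tries + 3L
  }
  expect_gte(wins / tries, 0.95)
})

test_that("selectFamily handles single candidates and the default mapping", {
  y <- 0.9 * (1 - exp(-(flightDays / 120)^4))
  s <- selectFamily(flightDays, y, candidates = "gaussian")
  expect_identical(s$family, "gaussian")
  expect_equal(nrow(s$table), 1L)
  expect_identical(defaultFamily("coverage"), "weibull")
  expect_identical(defaultFamily(c("height", "asm")),
                   c("gaussian", "fourier"))
  expect_error(defaultFamily("lodging"), "unknown")
})

test_that("evaluateCurve matches the closed forms", {
  g <- gaussCurve(0.7, 165, 25)
  expect_equal(evaluateCurve(g, 165), 0.7)                 # peak identity
  w <- new("ProfileCurve", family = "weibull",
           parameters = c(L = 0.9, b = 4, x0 = 110), domain = c(0, 200),
           metrics = c(r2 = 1, rmse = 0, aic = 0, n = 10),
           converged = TRUE)
  expect_lt(evaluateCurve(w, 1e-8), 1e-12)                 # limit at 0+
  f <- new("ProfileCurve", family = "fourier",
           parameters = c(L = 100, u = 1, a1 = 1, b1 = 0),
           domain = c(0, 100),
           metrics = c(r2 = 1, rmse = 0, aic = 0, n = 10),
           converged = TRUE)
  expect_equal(evaluateCurve(f, 100), cos(pi), tolerance = 1e-12)
  expect_warning(evaluateCurve(g, 500), "extrapolation")
})

test_that("confidence bands are pointwise empirical percentiles", {
  same <- replicate(5, gaussCurve(0.6, 160, 30), simplify = FALSE)
  b <- confidenceBand(same, 15, 85, grid = c(150, 160, 170))
  expect_equal(b$lower, b$upper)
  expect_equal(b$lower[2], 0.6, tolerance = 1e-9)
  # (0,100) band equals pointwise min/max
  set.seed(5)
  amps <- runif(10, 0.5, 1)
  curves <- lapply(amps, function(a) gaussCurve(a, 160, 30))
  b2 <- confidenceBand(curves, 0, 100, grid = 160)
  expect_equal(b2$lower, min(amps), tolerance = 1e-12)
  expect_equal(b2$upper, max(amps), tolerance = 1e-12)
  # 100 curves with a ~ U(0.5, 1): band limits near the amplitude quantiles
  set.seed(6)
  amps <- runif(100, 0.5, 1)
  curves <- lapply(amps, function(a) gaussCurve(a, 160, 30))
  b3 <- confidenceBand(curves, 15, 85, grid = 160)
  expect_equal(b3$lower, quantile(amps, 0.15)[[1]], tolerance = 0.02)
  expect_equal(b3$upper, quantile(amps, 0.85)[[1]], tolerance = 0.02)
  expect_error(confidenceBand(same[1:2]), "at least 3")
  # lower <= upper pointwise always
  b4 <- confidenceBand(curves, 25, 75)
  expect_true(all(b4$lower <= b4$upper + 1e-12))
})

test_that("fitTrialCurves fits replicate means for every design cell", {
  ds <- generateTrial(trialConfig(nVarieties = 2, seed = 19))
  curves <- fitTrialCurves(ds$series)
  expect_equal(nrow(curves), 2 * 3 * 6)
  expect_false(any(vapply(curves$curve, is.null, logical(1))))
  fams <- vapply(curves$curve, curveFamily, "")
  expect_identical(unname(fams), defaultFamily(curves$trait))
  r2 <- vapply(curves$curve, function(cv) curveMetrics(cv)[["r2"]],
               numeric(1))
  expect_true(all(r2 > 0.9))
})
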