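# Response-window dissection: DAF/DAS mapping, subcurve restriction,
# CGR closed-form values and sign, CGR matrix assembly, key phases.

test_that("DAF/DAS mapping and the default window are correct", {
  win <- responseWindow()
  expect_equal(dafToDas(1), 130)
  expect_equal(dafToDas(25), 154)
  expect_equal(dafToDas(14), 143)
  expect_equal(dasToDaf(143), 14)
  expect_identical(win$sections$section,
                   c("1-5", "6-10", "11-15", "16-20", "21-25"))
  expect_equal(win$sections$das_start, c(130, 135, 140, 145, 150))
  expect_equal(win$sections$das_end, c(134, 139, 144, 149, 154))
})

test_that("subcurve restriction preserves values and checks the domain", {
  g <- gaussCurve(0.8, 170, 30, domain = c(30, 196))
  sub <- extractSubcurve(g)
  expect_equal(curveDomain(sub), c(130, 154))
  expect_equal(evaluateCurve(sub, 130), evaluateCurve(g, 130))
  expect_equal(evaluateCurve(sub, 154), evaluateCurve(g, 154))
  narrow <- gaussCurve(0.8, 100, 30, domain = c(30, 140))
  expect_error(extractSubcurve(narrow), "outside")
})

test_that("CGR reproduces hand arithmetic for constant, doubling, halving", {
  # near-constant curve (gaussian with enormous spread): CGR ~ 0
  flat <- gaussCurve(0.5, 170, 1e9)
  expect_equal(cgr(flat, "1-5"), 0, tolerance = 1e-12)
  # f doubling over 130 -> 134: gaussian with b = 170,
  # c^2 = 304 / (2 log 2) makes f(134)/f(130) = 2 exactly
  dbl <- gaussCurve(0.5, 170, sqrt(304 / (2 * log(2))))
  expect_equal(cgr(dbl, "1-5"), 2^(1 / 5) - 1, tolerance = 1e-12)
  expect_equal(cgr(dbl, 1), 0.148698, tolerance = 1e-5)
  # f halving: b = 100, c^2 = 256 / (2 log 2)
  half <- gaussCurve(0.5, 100, sqrt(256 / (2 * log(2))))
  expect_equal(cgr(half, "1-5"), 2^(-1 / 5) - 1, tolerance = 1e-12)
  expect_equal(cgr(half, "1-5"), -0.129449, tolerance = 1e-5)
  expect_error(cgr(flat, "2-6"), "unknown section")
})

test_that("CGR sign matches the section's net change and compounds back", {
  set.seed(31)
  win <- responseWindow()
  for (i in 1:20) {
    g <- gaussCurve(runif(1, 0.3, 1), runif(1, 120, 180),
                    runif(1, 15, 60))
    for (s in win$sections$section) {
      row <- win$sections[win$sections$section == s, ]
      f0 <- evaluateCurve(g, row$das_start)
      f1 <- evaluateCurve(g, row$das_end)
      v <- cgr(g, s)
      expect_equal(sign(v), sign(f1 - f0))
      # compounding identity: (1 + CGR)^5 = f(end) / f(start)
      expect_equal((1 + v)^5, f1 / f0, tolerance = 1e-9)
    }
  }
})

test_that("non-positive curve values give an undefined-CGR error", {
  f <- new("ProfileCurve", family = "fourier",
           parameters = c(L = 166, u = 1, a1 = 1, b1 = 0),
           domain = c(30, 196),
           metrics = c(r2 = 1, rmse = 0, aic = 0, n = 10),
           converged = TRUE)
  # cos crosses zero inside the window for this configuration
  expect_error(cgr(f, "21-25"), "undefined")
})

test_that("the CGR matrix covers the full design and flags missing cells", {
  curves <- data.frame(
    variety = rep(c("V01", "V02"), each = 6),
    treatment = 180,
    trait = rep(nresTraits(), 2),
    stringsAsFactors = FALSE)
  curves$curve <- replicate(12, gaussCurve(0.8, 170, 30),
                            simplify = FALSE)
  m <- buildCGRMatrix(curves)
  expect_equal(nrow(m), 2 * 1 * 6 * 5)
  expect_false(anyNA(m$cgr))
  # near-constant curves give an all-(near-)zero matrix
  curves$curve <- replicate(12, gaussCurve(0.5, 170, 1e9),
                            simplify = FALSE)
  m0 <- buildCGRMatrix(curves)
  expect_true(all(abs(m0$cgr) < 1e-12))
  # a missing curve is NA with a warning, not dropped
  curves$curve[3] <- list(NULL)
  expect_warning(m2 <- buildCGRMatrix(curves), "missing")
  expect_equal(nrow(m2), 60)
  expect_equal(sum(is.na(m2$cgr)), 5)
})

test_that("synthetic-trial height CGR exceeds N0 under N270 at 11-15 DAF", {
  zero <- c(height = 0, coverage = 0, "3dci" = 0, asm = 0,
            vari = 0, ndyi = 0)
  ds <- generateTrial(trialConfig(nVarieties = 10, noiseSd = zero,
                                  seed = 23))
  # evaluate the generating curves directly over the section
  win <- responseWindow()
  row <- win$sections[win$sections$section == "11-15", ]
  rates <- sapply(c(0, 270), function(trt) {
    mean(vapply(sprintf("V%02d", 1:10), function(v) {
      f0 <- evaluateTrialCurve(ds, v, trt, "height", row$das_start)
      f1 <- evaluateTrialCurve(ds, v, trt, "height", row$das_end)
      (f1 / f0)^(1 / 5) - 1
    }, numeric(1)))
  })
  expect_gt(rates[2], rates[1])
})

test_that("key phases merge contiguous active sections", {
  base <- expand.grid(variety = c("V01", "V02"), treatment = 0,
                      trait = "height",
                      section = c("1-5", "6-10", "11-15", "16-20", "21-25"),
                      stringsAsFactors = FALSE)
  base$group <- "HYHN"
  base$cgr <- 0
  expect_equal(nrow(keyPhases(base, threshold = 0.01)), 0)
  # growth only in DAF 1-10: the flagged phase is exactly 1-10
  act <- base
  act$cgr[act$section %in% c("1-5", "6-10")] <- 0.05
  ph <- keyPhases(act, threshold = 0.01)
  expect_equal(nrow(ph), 1)
  expect_identical(ph$phase, "1-10")
  expect_identical(ph$sections, "1-5,6-10")
  # a single section above threshold is flagged alone
  one <- base
  one$cgr[one$section == "11-15"] <- 0.20
  ph2 <- keyPhases(one, threshold = 0.05)
  expect_identical(ph2$phase, "11-15")
  # group assignment is required
  expect_error(keyPhases(base[, setdiff(names(base), "group")]),
               "group")
})

test_that("CGR display binning saturates at +/-15%", {
  b <- binCGR(c(-0.5, -0.02, 0.002, 0.09, 0.5))
  expect_true(is.ordered(b))
  expect_identical(as.integer(b)[1], 1L)                  # < -15%
  expect_identical(as.integer(b)[5], nlevels(b))          # > +15%
})
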