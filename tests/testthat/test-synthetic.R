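# Synthetic-trial generators: design cardinality, determinism, planted
# structure and recorded ground truth.

test_that("trial dataset matches the factorial design and is seeded", {
  cfg <- trialConfig(seed = 41)
  ds <- generateTrial(cfg)
  expect_equal(length(unique(ds$series$plot_id)), 54 * 3 * 3)
  expect_equal(nrow(ds$series), 54 * 3 * 3 * 1 * 6 * 10)
  # every plot has all 6 traits at all flight days
  counts <- table(ds$series$plot_id)
  expect_true(all(counts == 6 * 10))
  perTrait <- table(ds$series$plot_id, ds$series$trait)
  expect_true(all(perTrait == 10))
  # bit-identical regeneration under the same seed
  ds2 <- generateTrial(trialConfig(seed = 41))
  expect_identical(ds$series, ds2$series)
  expect_identical(ds$truth, ds2$truth)
  # different seed changes values
  ds3 <- generateTrial(trialConfig(seed = 42))
  expect_false(identical(ds$series$value, ds3$series$value))
})

test_that("trial config validation rejects bad designs", {
  expect_error(trialConfig(nVarieties = 0), "counts")
  expect_error(trialConfig(flightDays = c(30, 30, 60)), "increasing")
  expect_error(trialConfig(fertilizationDas = 10), "within")
  expect_error(trialConfig(effectProfile = rep(2, 54)), "\\[0, 1\\]")
})

test_that("noiseless treatment effects order height and coverage by N", {
  zero <- c(height = 0, coverage = 0, "3dci" = 0, asm = 0,
            vari = 0, ndyi = 0)
  cfg <- trialConfig(nVarieties = 12, noiseSd = zero, seed = 5)
  ds <- generateTrial(cfg)
  for (tr in c("height", "coverage")) {
    sub <- ds$series[ds$series$trait == tr & ds$series$das == 154 &
                       ds$series$replicate == 1, ]
    m <- tapply(sub$value, sub$treatment, mean)
    expect_gt(m[["270"]], m[["0"]])
    expect_gte(m[["270"]], m[["180"]])
    expect_gte(m[["180"]], m[["0"]])
  }
  # treatment effect is zero at and before the fertilization day
  pre <- ds$series[ds$series$das <= 130 & ds$series$replicate == 1, ]
  spread <- tapply(pre$value,
                   paste(pre$variety, pre$trait, pre$das),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("generating curves are reachable and noiseless series lie on them", {
  zero <- c(height = 0, coverage = 0, "3dci" = 0, asm = 0,
            vari = 0, ndyi = 0)
  cfg <- trialConfig(nVarieties = 3, noiseSd = zero, seed = 8)
  ds <- generateTrial(cfg)
  sub <- ds$series[ds$series$variety == "V02" &
                     ds$series$treatment == 180 &
                     ds$series$replicate == 2 &
                     ds$series$trait == "vari", ]
  expect_equal(sub$value,
               evaluateTrialCurve(ds, "V02", 180, "vari", sub$das),
               tolerance = 1e-12)
})

test_that("Y&N table has 12 indices and planted labels honour the latents", {
  yn <- generateYNTable(nVarieties = 30, seed = 13)
  expect_identical(setdiff(names(yn$table), c("variety", "treatment")),
                   ynIndexNames())
  expect_equal(length(ynIndexNames()), 12L)
  # variety with both latents at the cohort maximum must be HYHN
  top <- which.max(yn$truth$yield_latent + yn$truth$n_latent)
  both <- yn$truth$yield_latent[top] == max(yn$truth$yield_latent) &
    yn$truth$n_latent[top] == max(yn$truth$n_latent)
  if (both) expect_identical(yn$truth$group[top], "HYHN")
  # labels are consistent with latents relative to the cohort mean
  expLab <- paste0(
    ifelse(yn$truth$yield_latent >= mean(yn$truth$yield_latent), "H", "L"),
    "Y",
    ifelse(yn$truth$n_latent >= mean(yn$truth$n_latent), "H", "L"), "N")
  expect_identical(yn$truth$group, expLab)
  expect_identical(generateYNTable(nVarieties = 30, seed = 13)$table,
                   yn$table)
})

test_that("genotype generator plants structure, MAF and missingness", {
  gg <- generateGenotypes(40, 400, kSubpops = 3, fst = 0.25, seed = 3)
  G <- genoMatrix(gg$genotypes)
  expect_true(all(G %in% c(0, 1, 2)))
  expect_equal(dim(G), c(40, 400))
  expect_equal(sort(unique(gg$truth$subpopulation)), 1:3)
  # zero planted missingness: QC removes nothing for missingness
  qc <- qcFilter(gg$genotypes)
  expect_false(any(grepl("missing", qc$report$reason)))
  # invalid specs
  expect_error(generateGenotypes(10, 50, mafRange = c(0.1, 0.7)),
               "mafRange")
  expect_error(generateGenotypes(10, 50, fst = 1), "fst")
  expect_identical(genoMatrix(generateGenotypes(40, 400, kSubpops = 3,
                                                fst = 0.25,
                                                seed = 3)$genotypes), G)
})

test_that("unstructured panels show no cluster separation above chance", {
  aris <- vapply(1:5, function(s) {
    gg <- generateGenotypes(36, 300, kSubpops = 1, fst = 0, seed = 60 + s)
    ps <- populationStructure(gg$genotypes, k = 3, seed = s)
    truth <- rep(1:3, length.out = 36)  # arbitrary labels: no structure
    mclust::adjustedRandIndex(ps$cluster, truth)
  }, numeric(1))
  expect_lt(mean(abs(aris)), 0.1)
})

test_that("strongly differentiated subpopulations are recovered (ARI > 0.9)", {
  aris <- vapply(1:10, function(s) {
    gg <- generateGenotypes(54, 400, kSubpops = 3, fst = 0.25,
                            seed = 500 + s)
    ps <- populationStructure(gg$genotypes, k = 3, seed = s)
    mclust::adjustedRandIndex(ps$cluster, gg$truth$subpopulation)
  }, numeric(1))
  expect_true(all(aris > 0.9))
})

test_that("causal-marker effects shift phenotype means monotonically", {
  cs <- data.frame(trait = "height", section = "11-15",
                   effect = c(0.01))
  gaps <- vapply(c(0.01, 0.05, 0.2), function(eff) {
    cs$effect <- eff
    gg <- generateGenotypes(54, 200, kSubpops = 1, fst = 0,
                            causal = cs, seed = 77)
    G <- genoMatrix(gg$genotypes)
    m <- gg$truth$causalMarkers$id[1]
    base <- data.frame(variety = rownames(G), treatment = 180,
                       trait = "height", section = "11-15", cgr = 0.01,
                       stringsAsFactors = FALSE)
    shifted <- attachCausalEffects(base, gg$genotypes, gg$truth)
    mean(shifted$cgr[G[, m] == 2]) - mean(shifted$cgr[G[, m] == 0])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("plot raster generator hits coverage targets and records truth", {
  # all-soil and all-vegetation limits (uniform palettes)
  soil <- generatePlotRaster(coverage = 0, colorJitter = 0, seed = 1)
  expect_equal(soil$truth$coverage, 0)
  veg <- generatePlotRaster(coverage = 1, colorJitter = 0, seed = 1)
  expect_equal(veg$truth$coverage, 1)
  # uniform green pixels: truth VARI equals the single-pixel value
  rgbv <- rasterRGB(veg$raster)
  px <- c(rgbv[1, 1, 1], rgbv[1, 1, 2], rgbv[1, 1, 3])
  expect_equal(veg$truth$vari,
               (px[2] - px[1]) / (px[2] + px[1] - px[3]),
               tolerance = 1e-12)
  # half coverage on 100x100: vegetation count within 1% of 5000
  half <- generatePlotRaster(coverage = 0.5, size = c(100, 100), seed = 4)
  expect_lt(abs(half$truth$coverage * 1e4 - 5000), 50)
  expect_error(generatePlotRaster(coverage = 1.2), "coverage")
  expect_error(generatePlotRaster(size = c(8, 8)), "16")
})
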