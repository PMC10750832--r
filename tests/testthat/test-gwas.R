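# Genotype QC, population structure, GLM association, significance
# filtering, candidate windows and the static/dynamic contrast.

test_that("QC removes markers by missingness and MAF, and is idempotent", {
  # 6 markers: missingness {0, .05, .2} x MAF {.02, .3} on 20 varieties
  n <- 20
  mkMarker <- function(maf, missFrac) {
    g <- c(rep(1, round(2 * maf * n)), rep(0, n - round(2 * maf * n)))
    g[seq_len(round(missFrac * n))] <- NA
    g
  }
  G <- cbind(
    m1 = mkMarker(0.02, 0), m2 = mkMarker(0.30, 0),
    m3 = mkMarker(0.02, 0.05), m4 = mkMarker(0.30, 0.05),
    m5 = mkMarker(0.02, 0.20), m6 = mkMarker(0.30, 0.20))
  gd <- makeGenotypes(G)
  qc <- qcFilter(gd)
  expect_identical(colnames(genoMatrix(qc$genotypes)), c("m2", "m4"))
  expect_equal(sum(qc$report$removed), 4)
  # a clean common marker is retained; MAF 0.04 is removed
  # (25 varieties, 2 minor alleles: 2/50 = 0.04)
  G2 <- cbind(common = rep(c(0, 2), length.out = 25),
              rare = c(1, 1, rep(0, 23)))
  qc2 <- qcFilter(makeGenotypes(G2))
  expect_identical(colnames(genoMatrix(qc2$genotypes)), "common")
  expect_identical(qc2$report$reason[qc2$report$id == "rare"], "maf")
  # idempotence
  qcTwice <- qcFilter(qc$genotypes)
  expect_identical(genoMatrix(qcTwice$genotypes),
                   genoMatrix(qc$genotypes))
  expect_error(qcFilter(makeGenotypes(cbind(m = rep(0, 20)))), "every")
})

test_that("population structure covariates separate planted populations", {
  ps1 <- populationStructure(
    generateGenotypes(30, 200, kSubpops = 1, fst = 0,
                      seed = 1)$genotypes, k = 1)
  expect_equal(ncol(ps1$Q), 0)
  expect_true(all(ps1$cluster == 1))
  # two populations with fixed alternative alleles: PC1 separates them
  G <- rbind(matrix(0, 10, 50), matrix(2, 10, 50))
  ps2 <- populationStructure(makeGenotypes(G), k = 2)
  pc1 <- ps2$Q[, 1]
  expect_gt(min(abs(mean(pc1[1:10]) - mean(pc1[11:20]))), 0)
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
                min(pc1[1:10]) > max(pc1[11:20]))
  expect_error(populationStructure(makeGenotypes(G), k = 50), "exceeds")
})

test_that("a perfectly linear phenotype yields P < 1e-10 at its marker", {
  gg <- generateGenotypes(54, 50, kSubpops = 1, fst = 0, seed = 7)
  G <- genoMatrix(gg$genotypes)
  m <- colnames(G)[which.max(apply(G, 2, var))]
  phe <- setNames(2 + 0.5 * G[, m], rownames(G))
  r <- glmAssociation(phe, gg$genotypes)
  expect_lt(r$p[r$id == m], 1e-10)
  expect_equal(r$effect[r$id == m], 0.5, tolerance = 1e-8)
})

test_that("small-instance P-values match a normal-equations oracle to 1e-8", {
  set.seed(13)
  n <- 10
  G <- matrix(sample(0:2, n * 5, replace = TRUE), n, 5)
  gd <- makeGenotypes(G)
  Q <- matrix(rnorm(n), n, 1, dimnames = list(rownames(genoMatrix(gd)),
                                              "Q1"))
  phe <- setNames(rnorm(n), rownames(genoMatrix(gd)))
  r <- glmAssociation(phe, gd, Q)
  for (m in seq_len(5)) {
    X <- cbind(1, Q[, 1], G[, m])
    if (sd(G[, m]) < 1e-12) next
    beta <- solve(t(X) %*% X, t(X) %*% phe)           # normal equations
    res <- phe - X %*% beta
    dfr <- n - ncol(X)
    s2 <- sum(res^2) / dfr
    seB <- sqrt(s2 * solve(t(X) %*% X)[3, 3])
    tstat <- beta[3] / seB
    pOracle <- 2 * pt(abs(tstat), dfr, lower.tail = FALSE)
    expect_equal(r$effect[m], beta[3], tolerance = 1e-8)
    expect_equal(r$p[m], pOracle, tolerance = 1e-8)
  }
})

test_that("null simulations are calibrated and uniform", {
  pv <- unlist(lapply(1:10, function(s) {
    gg <- generateGenotypes(54, 200, kSubpops = 1, fst = 0,
                            seed = 100 + s)
    phe <- withr::with_seed(200 + s,
      setNames(rnorm(54), rownames(genoMatrix(gg$genotypes))))
    glmAssociation(phe, gg$genotypes)$p
  }))
  pv <- pv[!is.na(pv)]
  expect_gte(length(pv), 2000)
  frac <- mean(pv < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("structure covariates deflate a confounded marker", {
  set.seed(21)
  gg <- generateGenotypes(60, 150, kSubpops = 2, fst = 0.4, seed = 33)
  G <- genoMatrix(gg$genotypes)
  sub <- gg$truth$subpopulation
  # phenotype driven purely by subpopulation membership
  phe <- setNames(2 * (sub == 1) + rnorm(60, 0, 0.1), rownames(G))
  ps <- populationStructure(gg$genotypes, k = 2, seed = 1)
  r0 <- glmAssociation(phe, gg$genotypes)
  r1 <- glmAssociation(phe, gg$genotypes, ps$Q)
  # pick the most structure-confounded marker under the naive scan
  m <- r0$id[which.min(r0$p)]
  expect_gt(r1$p[r1$id == m], r0$p[r0$id == m])
})

test_that("power for a planted effect is non-decreasing in effect size", {
  power <- vapply(c(0.5, 1.0, 2.0), function(eff) {
    det <- vapply(1:20, function(s) {
      cs <- data.frame(trait = "height", section = "11-15",
                       effect = eff)
      gg <- generateGenotypes(54, 150, kSubpops = 1, fst = 0,
                              causal = cs, seed = 700 + s)
      G <- genoMatrix(gg$genotypes)
      m <- gg$truth$causalMarkers$id[1]
      phe <- withr::with_seed(800 + s,
        setNames(eff * G[, m] + rnorm(54), rownames(G)))
      r <- glmAssociation(phe, gg$genotypes)
      !is.na(r$p[r$id == m]) && r$p[r$id == m] < 1e-5
    }, logical(1))
    mean(det)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gte(power[3], 0.9)
})

test_that("significant hits respect the cross-season intersection rule", {
  r1 <- data.frame(id = c("a", "b", "c"), p = c(9e-6, 9e-6, 0.5))
  r2 <- data.frame(id = c("a", "b", "c"), p = c(9e-6, 0.2, 1e-7))
  expect_identical(significantHits(list(r1, r2)), "a")
  expect_setequal(significantHits(list(r1, r2), requireAll = FALSE),
                  c("a", "b", "c"))
  expect_setequal(significantHits(list(r1, r2), alpha = 1),
                  c("a", "b", "c"))
  expect_error(significantHits(list()), "at least one")
})

test_that("candidate windows use same-chromosome interval overlap", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("1A", "1A", "2B"),
    start = c(1350000, 1600001, 1350000),
    end = c(1400000, 1650000, 1400000), stringsAsFactors = FALSE)
  hit <- list(chrom = "1A", pos = 1000000)
  cw <- candidateWindow(hit, ann)
  expect_identical(cw$gene_id, "g1")        # within 500 kb
  expect_equal(cw$distance, 350000)
  # gene starting 1 bp beyond the window and other-chromosome twin excluded
  expect_false("g2" %in% cw$gene_id)
  expect_false("g3" %in% cw$gene_id)
  # GRanges input path
  gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end), gene_id = ann$gene_id)
  cw2 <- candidateWindow(hit, gr)
  expect_identical(cw2$gene_id, "g1")
})

test_that("a section-CGR marker surfaces in dynamic scans only", {
  zero <- c(height = 0, coverage = 0, "3dci" = 0, asm = 0,
            vari = 0, ndyi = 0)
  ds <- generateTrial(trialConfig(noiseSd = zero, seed = 3))
  curves <- fitTrialCurves(ds$series[ds$series$treatment == 180, ])
  cs <- data.frame(trait = "height", section = "11-15", effect = 0.05)
  gg <- generateGenotypes(54, 150, kSubpops = 1, fst = 0, causal = cs,
                          seed = 5)
  cgrTab <- buildCGRMatrix(curves)
  cgrTab <- attachCausalEffects(cgrTab, gg$genotypes, gg$truth)
  dynamic <- lapply(split(cgrTab, paste(cgrTab$trait, cgrTab$section,
                                        sep = "_")), function(d)
    setNames(d$cgr, d$variety))
  static <- list()
  for (i in seq_len(nrow(curves))) {
    cv <- curves$curve[[i]]
    for (daf in c(5, 15, 25)) {
      nm <- paste0(curves$trait[i], "@", daf)
      static[[nm]] <- c(static[[nm]], setNames(
        evaluateCurve(cv, dafToDas(daf), warnExtrapolation = FALSE),
        curves$variety[i]))
    }
  }
  res <- compareStaticDynamic(static, dynamic, gg$genotypes)
  m <- gg$truth$causalMarkers$id[1]
  expect_true(m %in% res$dynamicHits)
  expect_false(m %in% res$staticHits)
  hit <- res$hits[res$hits$id == m, ]
  expect_true(all(hit$phenotype == "height_11-15"))
  # identical phenotype families give identical hit sets
  same <- compareStaticDynamic(dynamic, dynamic, gg$genotypes)
  expect_setequal(same$staticHits, same$dynamicHits)
})

test_that("LD r-squared is 1 on duplicated markers and bounded", {
  gg <- generateGenotypes(30, 20, seed = 9)
  G <- genoMatrix(gg$genotypes)
  first <- colnames(G)[1]
  G <- cbind(G, dup = G[, 1])
  ld <- ldR2(makeGenotypes(G))
  expect_equal(ld[first, "dup"], 1, tolerance = 1e-12)
  expect_true(all(ld >= -1e-12 & ld <= 1 + 1e-12, na.rm = TRUE))
})

test_that("Manhattan/QQ plot data are well-formed", {
  gg <- generateGenotypes(40, 100, seed = 15)
  phe <- withr::with_seed(1,
    setNames(rnorm(40), rownames(genoMatrix(gg$genotypes))))
  r <- glmAssociation(phe, gg$genotypes)
  pd <- gwasPlotData(r)
  expect_equal(nrow(pd$manhattan), sum(!is.na(r$p)))
  expect_true(all(diff(pd$qq$observed) >= 0))
  expect_true(all(pd$manhattan$neglog10p >= 0))
})
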