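# Seeded synthetic-trial generators: trait time-series, yield/N index
# tables, structured genotypes and plot rasters, each with planted ground
# truth for end-to-end recovery tests.

#' The six canopy traits handled by the pipeline
#' @return character vector of trait names.
#' @export
nresTraits <- function() c("height", "coverage", "3dci", "asm", "vari", "ndyi")

#' Default curve family per trait
#'
#' Peaked traits (height, the 3D canopy structure proxy, VARI) map to the
#' Gaussian family, the saturating canopy coverage to Weibull, and the
#' rise-then-fall textural/spectral traits (ASM, NDYI) to Fourier.
#'
#' @param trait character vector of trait names.
#' @return character vector of family names.
#' @export
defaultFamily <- function(trait) {
  map <- c(height = "gaussian", coverage = "weibull", "3dci" = "gaussian",
           asm = "fourier", vari = "gaussian", ndyi = "fourier")
  unknown <- setdiff(trait, names(map))
  if (length(unknown))
    stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  unname(map[trait])
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configure a synthetic N-response trial
#'
#' Defines the factorial design and generative settings of a synthetic
#' winter-wheat N-fertilization trial: varieties x N treatments x
#' replicates observed at a fixed set of flight days, with a jointing
#' fertilization applied mid-season after which treatments diverge.
#'
#' @param nVarieties number of varieties (default 54).
#' @param treatments N levels in kg N/ha (default \code{c(0, 180, 270)}).
#' @param nReplicates biological replicates per variety x treatment
#'   (default 3).
#' @param seasons season labels (default \code{"S1"}).
#' @param flightDays strictly increasing DAS of the phenotyping flights;
#'   must bracket \code{fertilizationDas}. Default: 10 days from 30 to
#'   196 DAS including 130 and 154.
#' @param fertilizationDas DAS of the jointing N fertilization
#'   (default 130).
#' @param noiseSd named per-trait observation noise standard deviations
#'   (same units as the trait).
#' @param responseBeta maximum proportional boost of post-fertilization
#'   growth at the highest N level for a fully responsive variety
#'   (default 0.6).
#' @param effectProfile optional numeric vector of per-variety latent
#'   responsiveness scores in [0, 1]; drawn uniformly when NULL.
#' @param seed integer RNG seed.
#' @return an object of class \code{TrialConfig} (validated list).
#' @export
trialConfig <- function(nVarieties = 54,
                        treatments = c(0, 180, 270),
                        nReplicates = 3,
                        seasons = "S1",
                        flightDays = c(30, 50, 70, 90, 110, 130,
                                       142, 154, 175, 196),
                        fertilizationDas = 130,
                        noiseSd = c(height = 0.02, coverage = 0.02,
                                    "3dci" = 0.02, asm = 0.01,
                                    vari = 0.02, ndyi = 0.01),
                        responseBeta = 0.6,
                        effectProfile = NULL,
                        seed = 1L) {
  if (nVarieties < 1 || nReplicates < 1 || length(treatments) < 1 ||
      length(seasons) < 1)
    stop("all design counts must be >= 1")
  if (any(diff(flightDays) <= 0))
    stop("flightDays must be strictly increasing")
  if (fertilizationDas < min(flightDays) ||
      fertilizationDas > max(flightDays))
    stop("fertilizationDas must lie within the flight-day range")
  if (!all(nresTraits() %in% names(noiseSd)))
    stop("noiseSd must name all six traits")
  if (any(noiseSd < 0)) stop("noiseSd must be non-negative")
  if (!is.null(effectProfile)) {
    if (length(effectProfile) != nVarieties)
      stop("effectProfile must have one score per variety")
    if (any(effectProfile < 0 | effectProfile > 1))
      stop("effectProfile scores must lie in [0, 1]")
  }
  structure(list(
    nVarieties = as.integer(nVarieties),
    treatments = as.numeric(treatments),
    nReplicates = as.integer(nReplicates),
    seasons = as.character(seasons),
    flightDays = as.numeric(flightDays),
    fertilizationDas = as.numeric(fertilizationDas),
    noiseSd = noiseSd[nresTraits()],
    responseBeta = responseBeta,
    effectProfile = effectProfile,
    seed = as.integer(seed)
  ), class = "TrialConfig")
}

# Fourier basis matrix on grid x for half-period L and order u (no
# intercept, matching the profile-curve closed form).
fourierBasis <- function(x, L, u) {
  cols <- lapply(seq_len(u), function(n)
    cbind(cos(n * pi * x / L), sin(n * pi * x / L)))
  B <- do.call(cbind, cols)
  colnames(B) <- as.vector(rbind(paste0("a", seq_len(u)),
                                 paste0("b", seq_len(u))))
  B
}

# Project a rise-then-fall bump onto an order-u Fourier basis so that
# ASM/NDYI generating curves are exactly Fourier-representable.
bumpFourierCoefs <- function(dasRange, peak, width, amplitude, baseline,
                             u = 3) {
  L <- diff(dasRange)
  grid <- seq(dasRange[1], dasRange[2], length.out = 201)
  z <- (grid - peak) / width
  target <- baseline + amplitude * exp(-z^2 / 2)
  B <- fourierBasis(grid, L, u)
  stats::lsfit(B, target, intercept = FALSE)$coefficients
}

# Per-variety noiseless generating curves for all traits; returns a list
# of closures keyed by trait. Treatment response multiplies the
# post-fertilization increment by 1 + dir * beta * (N/maxN) * score.
makeVarietyCurves <- function(config, score) {
  rng <- function(lo, hi) stats::runif(1, lo, hi)
  dasRange <- range(config$flightDays)
  L <- diff(dasRange)
  base <- list(
    height = local({
      a <- rng(0.70, 0.90); b <- rng(172, 184); cc <- rng(40, 50)
      function(x) a * exp(-(x - b)^2 / (2 * cc^2))
    }),
    coverage = local({
      Lm <- rng(0.85, 0.95); x0 <- rng(100, 115); bb <- rng(3, 4.2)
      function(x) Lm * (1 - exp(-(x / x0)^bb))
    }),
    "3dci" = local({
      a <- rng(0.75, 0.92); b <- rng(158, 172); cc <- rng(45, 55)
      function(x) a * exp(-(x - b)^2 / (2 * cc^2))
    }),
    asm = local({
      k <- bumpFourierCoefs(dasRange, peak = rng(140, 155),
                            width = rng(35, 45),
                            amplitude = rng(0.35, 0.5),
                            baseline = rng(0.15, 0.25))
      function(x) as.vector(fourierBasis(x, L, 3) %*% k)
    }),
    vari = local({
      a <- rng(0.40, 0.55); b <- rng(145, 158); cc <- rng(36, 46)
      function(x) a * exp(-(x - b)^2 / (2 * cc^2))
    }),
    ndyi = local({
      k <- bumpFourierCoefs(dasRange, peak = rng(160, 175),
                            width = rng(28, 38),
                            amplitude = rng(0.3, 0.45),
                            baseline = rng(0.05, 0.12))
      function(x) as.vector(fourierBasis(x, L, 3) %*% k)
    })
  )
  respDir <- c(height = 1, coverage = 1, "3dci" = 1, asm = 1,
               vari = 1, ndyi = -1)
  fDas <- config$fertilizationDas
  beta <- config$responseBeta
  maxN <- max(config$treatments)
  out <- list()
  for (tr in nresTraits()) {
    out[[tr]] <- local({
      f <- base[[tr]]; dir <- respDir[[tr]]
      function(x, nLevel) {
        r <- 1 + dir * beta * (if (maxN > 0) nLevel / maxN else 0) * score
        y <- f(x)
        post <- x > fDas
        if (any(post)) {
          y0 <- f(fDas)
          y[post] <- y0 + (f(x[post]) - y0) * r
        }
        pmax(y, 0)
      }
    })
  }
  out
}

#' Generate a seeded synthetic trial dataset
#'
#' Draws per-variety noiseless generating curves from the per-trait curve
#' families (Gaussian for height/3DCI/VARI, Weibull for coverage, Fourier
#' for ASM/NDYI), applies an N-treatment response that is zero before the
#' jointing fertilization and scales with the N level and the variety's
#' latent responsiveness afterwards, and samples observations at the
#' configured flight days with i.i.d. Gaussian noise. The expected
#' ordering N270 >= N180 >= N0 holds for height and coverage after
#' fertilization by construction.
#'
#' @param config a [trialConfig()].
#' @return a \code{TrialDataset}: list with \code{series} (long
#'   data.frame: plot_id, variety, treatment, replicate, season, trait,
#'   das, value), \code{truth} (variety, score), \code{curves} (nested
#'   list of noiseless generating functions, see
#'   [evaluateTrialCurve()]) and \code{config}.
#' @examples
#' ds <- generateTrial(trialConfig(nVarieties = 4, seed = 7))
#' head(ds$series)
#' @export
generateTrial <- function(config) {
  if (!inherits(config, "TrialConfig"))
    stop("config must be created by trialConfig()")
  withSeed(config$seed, {
    nv <- config$nVarieties
    varieties <- sprintf("V%02d", seq_len(nv))
    score <- config$effectProfile
    if (is.null(score)) score <- stats::runif(nv)
    names(score) <- varieties
    curves <- lapply(seq_len(nv), function(i)
      makeVarietyCurves(config, score[i]))
    names(curves) <- varieties

    des <- expand.grid(replicate = seq_len(config$nReplicates),
                       treatment = config$treatments,
                       variety = varieties,
                       season = config$seasons,
                       stringsAsFactors = FALSE)
    fd <- config$flightDays
    nT <- length(fd)
    rows <- vector("list", nrow(des) * length(nresTraits()))
    k <- 0L
    for (r in seq_len(nrow(des))) {
      v <- des$variety[r]; trt <- des$treatment[r]
      pid <- sprintf("%s_N%g_R%d_%s", v, trt, des$replicate[r],
                     des$season[r])
      for (tr in nresTraits()) {
        mu <- curves[[v]][[tr]](fd, trt)
        eps <- if (config$noiseSd[[tr]] > 0)
          stats::rnorm(nT, 0, config$noiseSd[[tr]]) else numeric(nT)
        k <- k + 1L
        rows[[k]] <- data.frame(
          plot_id = pid, variety = v, treatment = trt,
          replicate = des$replicate[r], season = des$season[r],
          trait = tr, das = fd, value = mu + eps,
          stringsAsFactors = FALSE)
      }
    }
    series <- do.call(rbind, rows)
    rownames(series) <- NULL
    structure(list(
      series = series,
      truth = data.frame(variety = varieties, score = unname(score),
                         stringsAsFactors = FALSE),
      curves = curves,
      config = config
    ), class = "TrialDataset")
  })
}

#' @export
print.TrialDataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "TrialDataset: %d varieties x %d treatments x %d replicates x %d season(s)\n",
    cfg$nVarieties, length(cfg$treatments), cfg$nReplicates,
    length(cfg$seasons)))
  cat(sprintf("  %d plots, %d series rows, flights at %s DAS\n",
              length(unique(x$series$plot_id)), nrow(x$series),
              paste(cfg$flightDays, collapse = ",")))
  invisible(x)
}

#' Evaluate a trial's noiseless generating curve
#'
#' @param dataset a \code{TrialDataset} from [generateTrial()].
#' @param variety,trait character(1) identifiers.
#' @param treatment N level in kg N/ha.
#' @param das numeric DAS values.
#' @return numeric vector of noiseless curve values.
#' @export
evaluateTrialCurve <- function(dataset, variety, treatment, trait, das) {
  f <- dataset$curves[[variety]][[trait]]
  if (is.null(f)) stop("no generating curve for ", variety, "/", trait)
  f(das, treatment)
}

# ---- yield / N-utilization table -----------------------------------------

#' Names of the twelve yield and N-utilization indices
#'
#' The first six are yield-production indices, the last six
#' N-utilization indices.
#' @return character(12).
#' @export
ynIndexNames <- function() {
  c("spike_number", "grain_number_per_spike", "thousand_grain_weight",
    "aboveground_biomass", "straw_biomass", "grain_yield",
    "n_aboveground", "n_straw", "grain_n_content", "nue", "nupe", "nhi")
}

#' @rdname ynIndexNames
#' @export
yieldIndexNames <- function() ynIndexNames()[1:6]

#' @rdname ynIndexNames
#' @export
nIndexNames <- function() ynIndexNames()[7:12]

#' Generate a synthetic yield / N-utilization index table
#'
#' Builds the twelve postharvest indices per variety x treatment as noisy
#' affine functions of two latent axes (yield potential and N
#' utilization), so that varieties fall into four planted quadrant
#' groups. All loadings on the latent axes are positive, so with zero
#' noise the quadrant classification of [classifyQuadrants()] recovers
#' the planted labels exactly.
#'
#' @param nVarieties number of varieties (default 54).
#' @param treatments N levels (default \code{c(0, 180, 270)}).
#' @param noiseSd noise scale as a fraction of each index's latent-driven
#'   spread (default 0.1; 0 gives a noiseless table).
#' @param proportions target proportions of the four groups in the order
#'   HYHN, LYHN, LYLN, HYLN (default balanced toward HYHN/LYLN as in
#'   field cohorts). Realized labels are always re-derived from the
#'   realized latents relative to the cohort mean, so proportions are
#'   approximate.
#' @param seed integer RNG seed.
#' @return list with \code{table} (data.frame: variety, treatment, the 12
#'   index columns) and \code{truth} (variety, group, yield_latent,
#'   n_latent).
#' @export
generateYNTable <- function(nVarieties = 54,
                            treatments = c(0, 180, 270),
                            noiseSd = 0.1,
                            proportions = c(HYHN = 0.35, LYHN = 0.15,
                                            LYLN = 0.35, HYLN = 0.15),
                            seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  withSeed(seed, {
    varieties <- sprintf("V%02d", seq_len(nVarieties))
    grp <- sample(names(proportions), nVarieties, replace = TRUE,
                  prob = proportions)
    sgnY <- ifelse(grp %in% c("HYHN", "HYLN"), 1, -1)
    sgnU <- ifelse(grp %in% c("HYHN", "LYHN"), 1, -1)
    Y <- sgnY * stats::runif(nVarieties, 0.15, 1)
    U <- sgnU * stats::runif(nVarieties, 0.15, 1)
    # planted truth relative to the cohort mean, matching the quadrant rule
    labY <- ifelse(Y >= mean(Y), "H", "L")
    labU <- ifelse(U >= mean(U), "H", "L")
    truthGroup <- paste0(labY, "Y", labU, "N")

    # index means per treatment (agronomically plausible scales) and
    # positive latent loadings
    baseMean <- c(spike_number = 450, grain_number_per_spike = 38,
                  thousand_grain_weight = 42, aboveground_biomass = 1400,
                  straw_biomass = 800, grain_yield = 600,
                  n_aboveground = 12, n_straw = 6, grain_n_content = 20,
                  nue = 30, nupe = 1.1, nhi = 0.72)
    loading <- c(spike_number = 60, grain_number_per_spike = 5,
                 thousand_grain_weight = 4, aboveground_biomass = 180,
                 straw_biomass = 90, grain_yield = 110,
                 n_aboveground = 2.0, n_straw = 1.0, grain_n_content = 2.5,
                 nue = 5, nupe = 0.15, nhi = 0.05)
    trtShift <- function(nLevel) 1 + 0.15 * nLevel / max(c(treatments, 1))

    rows <- list()
    for (trt in treatments) {
      vals <- sapply(ynIndexNames(), function(ix) {
        lat <- if (ix %in% yieldIndexNames()) Y else U
        mu <- baseMean[[ix]] * trtShift(trt) + loading[[ix]] * lat
        mu + stats::rnorm(nVarieties, 0, noiseSd * loading[[ix]])
      })
      rows[[as.character(trt)]] <- data.frame(
        variety = varieties, treatment = trt, vals,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab,
         truth = data.frame(variety = varieties, group = truthGroup,
                            yield_latent = Y, n_latent = U,
                            stringsAsFactors = FALSE))
  })
}

# ---- genotypes ------------------------------------------------------------

#' Generate a structured biallelic genotype panel with planted causal markers
#'
#' Simulates a varieties x markers 0/1/2 dosage matrix under a
#' Balding-Nichols model: each marker's ancestral allele frequency is
#' drawn from \code{mafRange}, subpopulation frequencies are drawn from a
#' Beta distribution with differentiation parameter \code{fst}, and
#' dosages are binomial within each subpopulation. Optional causal
#' markers are recorded in the returned truth object; their phenotypic
#' effects are applied downstream by [attachCausalEffects()].
#'
#' @param nVarieties number of varieties.
#' @param nMarkers number of markers.
#' @param kSubpops number of subpopulations (default 3).
#' @param fst differentiation parameter in [0, 1); 0 gives an
#'   unstructured panel.
#' @param missingRate per-call missing probability (default 0).
#' @param mafRange ancestral allele-frequency range, within (0, 0.5].
#' @param causal optional data.frame with columns \code{trait},
#'   \code{section} (e.g. \code{"11-15"}) and \code{effect}; one causal
#'   marker is planted per row at a marker with healthy frequency.
#' @param seed integer RNG seed.
#' @return list with \code{genotypes} (a \linkS4class{GenotypeData}) and
#'   \code{truth} (list: \code{causalMarkers} data.frame with marker ids,
#'   \code{subpopulation} named integer vector).
#' @export
generateGenotypes <- function(nVarieties = 54, nMarkers = 2000,
                              kSubpops = 3, fst = 0.15,
                              missingRate = 0,
                              mafRange = c(0.1, 0.5),
                              causal = NULL, seed = 1L) {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (!is.null(causal)) {
    if (!all(c("trait", "section", "effect") %in% names(causal)))
      stop("causal must have columns trait, section, effect")
    if (nrow(causal) > nMarkers)
      stop("more causal markers requested than markers")
  }
  withSeed(seed, {
    varieties <- sprintf("V%02d", seq_len(nVarieties))
    subpop <- rep(seq_len(kSubpops), length.out = nVarieties)
    names(subpop) <- varieties

    pAnc <- stats::runif(nMarkers, mafRange[1], mafRange[2])
    G <- matrix(NA_real_, nVarieties, nMarkers,
                dimnames = list(varieties, NULL))
    for (m in seq_len(nMarkers)) {
      if (fst > 0) {
        shape <- (1 - fst) / fst
        pk <- stats::rbeta(kSubpops, pAnc[m] * shape,
                           (1 - pAnc[m]) * shape)
        pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      } else pk <- rep(pAnc[m], kSubpops)
      G[, m] <- stats::rbinom(nVarieties, 2, pk[subpop])
    }

    chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
    chrom <- sort(sample(chroms, nMarkers, replace = TRUE))
    pos <- integer(nMarkers)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(8e8, length(idx)))
    }
    ids <- sprintf("M%05d", seq_len(nMarkers))
    colnames(G) <- ids
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, nMarkers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")

    causalMarkers <- NULL
    if (!is.null(causal) && nrow(causal)) {
      obsMaf <- colMeans(G, na.rm = TRUE) / 2
      obsMaf <- pmin(obsMaf, 1 - obsMaf)
      eligible <- which(obsMaf >= 0.2)
      if (length(eligible) < nrow(causal))
        stop("too few common markers to plant causal effects")
      pick <- sample(eligible, nrow(causal))
      causalMarkers <- data.frame(id = ids[pick], causal,
                                  stringsAsFactors = FALSE)
    }

    if (missingRate > 0) {
      drop <- which(stats::runif(length(G)) < missingRate)
      G[drop] <- NA_real_
    }

    gd <- methods::new("GenotypeData", geno = G,
                       map = data.frame(id = ids, chrom = chrom, pos = pos,
                                        ref = ref, alt = alt,
                                        stringsAsFactors = FALSE))
    list(genotypes = gd,
         truth = list(causalMarkers = causalMarkers,
                      subpopulation = subpop))
  })
}

#' Add planted causal-marker effects to dynamic phenotypes
#'
#' For each causal marker in \code{truth}, adds \code{effect x dosage} to
#' the matching (trait, section) CGR phenotype of each variety. Static
#' phenotypes are untouched, so a marker planted on one section's CGR is
#' visible to dynamic-phenotype association scans only.
#'
#' @param cgrTable tidy CGR table (columns variety, treatment, trait,
#'   section, cgr), as from [buildCGRMatrix()].
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param truth truth list from [generateGenotypes()].
#' @return the CGR table with effects added.
#' @export
attachCausalEffects <- function(cgrTable, genotypes, truth) {
  cm <- truth$causalMarkers
  if (is.null(cm) || !nrow(cm)) return(cgrTable)
  G <- genoMatrix(genotypes)
  for (r in seq_len(nrow(cm))) {
    dose <- G[, cm$id[r]]
    dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    hit <- cgrTable$trait == cm$trait[r] & cgrTable$section == cm$section[r]
    cgrTable$cgr[hit] <- cgrTable$cgr[hit] +
      cm$effect[r] * dose[cgrTable$variety[hit]]
  }
  cgrTable
}

# ---- plot rasters ---------------------------------------------------------

#' Generate a synthetic plot raster with recorded ground truth
#'
#' Builds an RGB canopy raster with a controlled fraction of vegetation
#' pixels (fixed green palette with jitter) over a soil background (brown
#' palette with jitter), plus a height raster where vegetation pixels
#' carry Gaussian heights and soil is at ground level. The recorded truth
#' (true coverage, mean VARI/NDYI over vegetation pixels, height
#' quantiles) is the oracle for the trait-extraction tests.
#'
#' @param coverage target vegetation fraction in [0, 1].
#' @param size integer(2) raster height and width in pixels (>= 16).
#' @param meanHeight,heightSd vegetation height distribution in meters
#'   (clipped to [0, 1.2]).
#' @param colorJitter sd of per-pixel channel jitter (default 0.02; 0
#'   gives uniform palettes).
#' @param plotId,das identifiers stored on the raster.
#' @param seed integer RNG seed.
#' @return list with \code{raster} (a \linkS4class{PlotRaster}) and
#'   \code{truth} (list: coverage, vari, ndyi, height_q50, height_q95).
#' @export
generatePlotRaster <- function(coverage = 0.5, size = c(64, 64),
                               meanHeight = 0.8, heightSd = 0.05,
                               colorJitter = 0.02,
                               plotId = "P001", das = 130L, seed = 1L) {
  if (coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]")
  if (any(size < 16)) stop("raster must be at least 16 x 16")
  withSeed(seed, {
    H <- size[1]; W <- size[2]
    npix <- H * W
    nveg <- round(coverage * npix)
    vegIdx <- if (nveg > 0) sample.int(npix, nveg) else integer(0)
    mask <- rep(FALSE, npix); mask[vegIdx] <- TRUE

    vegBase <- c(0.20, 0.55, 0.15)   # ExG = 0.75
    soilBase <- c(0.45, 0.32, 0.28)  # ExG = -0.09
    rgb <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- ifelse(mask, vegBase[ch], soilBase[ch])
      if (colorJitter > 0)
        plane <- plane + stats::rnorm(npix, 0, colorJitter)
      rgb[, , ch] <- matrix(pmin(pmax(plane, 0), 1), H, W)
    }
    hplane <- rep(0, npix)
    if (nveg > 0)
      hplane[vegIdx] <- pmin(pmax(
        stats::rnorm(nveg, meanHeight, heightSd), 0), 1.2)
    height <- matrix(hplane, H, W)

    R <- as.vector(rgb[, , 1]); Gc <- as.vector(rgb[, , 2])
    B <- as.vector(rgb[, , 3])
    variPix <- (Gc - R) / (Gc + R - B)
    ndyiPix <- (Gc - B) / (Gc + B)
    truth <- list(
      coverage = nveg / npix,
      vari = if (nveg > 0) mean(variPix[mask]) else NA_real_,
      ndyi = if (nveg > 0) mean(ndyiPix[mask]) else NA_real_,
      height_q50 = if (nveg > 0)
        unname(stats::quantile(hplane[vegIdx], 0.5)) else NA_real_,
      height_q95 = if (nveg > 0)
        unname(stats::quantile(hplane[vegIdx], 0.95)) else NA_real_)
    raster <- methods::new("PlotRaster", rgb = rgb, height = height,
                           plotId = plotId, das = as.integer(das))
    list(raster = raster, truth = truth)
  })
}
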