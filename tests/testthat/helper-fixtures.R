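# Shared in-code fixtures for the suite.

flightDays <- c(30, 50, 70, 90, 110, 130, 142, 154, 175, 196)

# A uniform-color raster (optionally with a uniform height layer).
uniformRaster <- function(r, g, b, height = NULL, size = c(16, 16)) {
  rgb <- array(0, c(size[1], size[2], 3))
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  h <- if (is.null(height)) matrix(numeric(0), 0, 0)
       else matrix(height, size[1], size[2])
  new("PlotRaster", rgb = rgb, height = h, plotId = "fix", das = 100L)
}

# Tiny GenotypeData built from an explicit dosage matrix.
makeGenotypes <- function(G, chrom = NULL, pos = NULL) {
  n <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("M%03d", seq_len(n))
  if (is.null(rownames(G))) rownames(G) <- sprintf("V%02d", seq_len(nrow(G)))
  new("GenotypeData", geno = G,
      map = data.frame(id = colnames(G),
                       chrom = if (is.null(chrom)) rep("1A", n) else chrom,
                       pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
                       ref = "A", alt = "T", stringsAsFactors = FALSE))
}

# Gaussian ProfileCurve constructed directly (no fitting).
gaussCurve <- function(a, b, c, domain = c(30, 196)) {
  new("ProfileCurve", family = "gaussian",
      parameters = c(a = a, b = b, c = c), domain = domain,
      metrics = c(r2 = 1, rmse = 0, aic = -Inf, n = 10), converged = TRUE)
}

# Separable four-class CGR-shaped feature matrix (30 named columns).
cgrFeatureNames <- function() {
  secs <- c("1-5", "6-10", "11-15", "16-20", "21-25")
  as.vector(t(outer(nresTraits(), secs, paste, sep = "_")))
}

separableFeatures <- function(nPerClass = 40, sdNoise = 0.2,
                              sdCenters = 3, seed = 1) {
  set.seed(seed)
  classes <- rep(c("HYHN", "LYHN", "LYLN", "HYLN"), each = nPerClass)
  mu <- matrix(rnorm(4 * 30, sd = sdCenters), 4, 30)
  X <- mu[rep(1:4, each = nPerClass), ] +
    matrix(rnorm(4 * nPerClass * 30, sd = sdNoise), 4 * nPerClass, 30)
  colnames(X) <- cgrFeatureNames()
  list(x = X, y = classes)
}
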