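# Plot-level trait extraction from canopy rasters: vegetation masking,
# spectral indices, GLCM texture, height statistics.

# Otsu threshold on a numeric vector, with the separability measure
# eta = between-class variance / total variance. Returns list(threshold,
# eta). 256-bin histogram implementation. For a unimodal Gaussian
# image eta is about 0.64 (2/pi), while genuinely bimodal soil/canopy
# images score close to 1, so the mask fallback cut sits between the two.
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps)
    return(list(threshold = rng[1], eta = 0))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  kStar <- which.max(sigmaB)
  sigmaT <- sum(p * (mids - muT)^2)
  list(threshold = mids[kStar],
       eta = if (sigmaT > 0) sigmaB[kStar] / sigmaT else 0)
}

#' Vegetation mask of a plot raster
#'
#' Classifies pixels as vegetation by Otsu autothresholding of the
#' excess-green transform ExG = 2G - R - B. When the Otsu separability
#' (between-class over total variance) falls below \code{minEta} the
#' image is treated as effectively single-class — a unimodal Gaussian
#' image scores about 0.64, a genuine soil/canopy mixture close to 1 —
#' and the decision falls back to a fixed greenness floor
#' (\code{ExG > floor}), so all-soil and all-vegetation plots are
#' classified by majority rather than split in half.
#'
#' @param raster a \linkS4class{PlotRaster}.
#' @param minEta minimum Otsu separability to trust the data-driven
#'   threshold (default 0.8).
#' @param floor greenness floor in ExG units (default 0.05).
#' @return logical matrix, TRUE for vegetation pixels.
#' @export
vegetationMask <- function(raster, minEta = 0.8, floor = 0.05) {
  stopifnot(is(raster, "PlotRaster"))
  rgb <- rasterRGB(raster)
  exg <- 2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
  ot <- otsuThreshold(as.vector(exg))
  thr <- if (ot$eta >= minEta) max(ot$threshold, floor) else floor
  exg > thr
}

#' Canopy coverage: vegetation pixel fraction
#'
#' @inheritParams vegetationMask
#' @param ... passed to [vegetationMask()].
#' @return numeric(1) in [0, 1].
#' @export
canopyCoverage <- function(raster, ...) {
  mask <- vegetationMask(raster, ...)
  mean(mask)
}

# Mean of a per-pixel index over the vegetation mask, excluding pixels
# with near-zero denominator; maskAll = FALSE averages vegetation-only
# pixels (the default convention), TRUE averages all pixels.
indexMean <- function(num, den, mask, maskAll = FALSE, tol = 1e-9) {
  keep <- abs(den) >= tol
  if (!maskAll) keep <- keep & mask
  if (!any(keep)) {
    warning("empty vegetation mask; index undefined")
    return(NA_real_)
  }
  mean(num[keep] / den[keep])
}

#' Visible atmospherically resistant index (VARI)
#'
#' Per-pixel VARI = (G - R) / (G + R - B), averaged over the vegetation
#' mask (canopy-level greenness). Pixels with |denominator| < 1e-9 are
#' excluded.
#'
#' @inheritParams vegetationMask
#' @param maskAll average over all pixels instead of vegetation-only
#'   (default FALSE).
#' @param ... passed to [vegetationMask()].
#' @return numeric(1) in [-1, 1], or NA with a warning on an empty mask.
#' @export
vari <- function(raster, maskAll = FALSE, ...) {
  rgb <- rasterRGB(raster)
  mask <- vegetationMask(raster, ...)
  v <- indexMean(rgb[, , 2] - rgb[, , 1],
                 rgb[, , 2] + rgb[, , 1] - rgb[, , 3], mask, maskAll)
  min(max(v, -1), 1)
}

#' Normalized difference yellowness index (NDYI)
#'
#' Per-pixel NDYI = (G - B) / (G + B), averaged over the vegetation mask
#' (flowering/senescence yellowness).
#'
#' @inheritParams vari
#' @return numeric(1) in [-1, 1], or NA with a warning on an empty mask.
#' @export
ndyi <- function(raster, maskAll = FALSE, ...) {
  rgb <- rasterRGB(raster)
  mask <- vegetationMask(raster, ...)
  v <- indexMean(rgb[, , 2] - rgb[, , 3],
                 rgb[, , 2] + rgb[, , 3], mask, maskAll)
  min(max(v, -1), 1)
}

#' Angular second moment (ASM) canopy texture
#'
#' Quantizes the grayscale image (channel mean) to \code{levels} gray
#' levels, accumulates a symmetric normalized gray-level co-occurrence
#' matrix at each offset, and returns the mean over offsets of
#' \eqn{\sum_{ij} p(i,j)^2}. Constant images give ASM = 1; the default
#' offsets \{(0,1), (1,0)\} form a rotation-balanced pair.
#'
#' @param raster a \linkS4class{PlotRaster}.
#' @param levels number of gray levels (default 8, >= 2).
#' @param offsets list of integer(2) (row, col) offsets.
#' @return numeric(1) in (0, 1].
#' @export
asm <- function(raster, levels = 8L,
                offsets = list(c(0L, 1L), c(1L, 0L))) {
  stopifnot(is(raster, "PlotRaster"), levels >= 2)
  rgb <- rasterRGB(raster)
  gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  rng <- range(gray)
  q <- if (diff(rng) <= .Machine$double.eps)
    matrix(1L, nrow(gray), ncol(gray))
  else
    matrix(pmin(as.integer(floor((gray - rng[1]) / diff(rng) * levels)) + 1L,
                levels), nrow(gray), ncol(gray))
  H <- nrow(q); W <- ncol(q)
  vals <- vapply(offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    if (abs(dr) >= H || abs(dc) >= W)
      stop("offset larger than the image")
    r1 <- seq_len(H - abs(dr)); c1 <- seq_len(W - abs(dc))
    a <- q[r1 + max(dr, 0), c1 + max(dc, 0)]
    b <- q[r1 + max(-dr, 0), c1 + max(-dc, 0)]
    glcm <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = 1:levels),
                 factor(b, levels = 1:levels))
    glcm <- tab + t(tab)           # symmetric
    p <- glcm / sum(glcm)
    sum(p^2)
  }, numeric(1))
  mean(vals)
}

#' Plot-level plant height
#'
#' Upper quantile (default 95th percentile) of the canopy height model
#' over the vegetation mask.
#'
#' @param raster a \linkS4class{PlotRaster} with a height layer.
#' @param probs quantile (default 0.95).
#' @param ... passed to [vegetationMask()].
#' @return numeric(1) in meters, or NA with a warning when the mask is
#'   empty.
#' @export
plantHeight <- function(raster, probs = 0.95, ...) {
  h <- rasterHeight(raster)
  if (is.null(h)) stop("raster has no height layer")
  mask <- vegetationMask(raster, ...)
  if (!any(mask)) {
    warning("empty vegetation mask; height undefined")
    return(NA_real_)
  }
  unname(stats::quantile(h[mask], probs))
}

#' 3D canopy structure index (height-uniformity proxy)
#'
#' A documented proxy for the 3D Canopy Index: one minus the coefficient
#' of variation of height over the vegetation mask, clipped to [0, 1].
#' Higher values indicate a more uniform canopy surface; a perfectly flat
#' canopy scores 1. The function is an interface point: a different
#' structural definition can be swapped in without touching downstream
#' code, which only consumes the trait value.
#'
#' @inheritParams plantHeight
#' @return numeric(1) in [0, 1], or NA with a warning on an empty mask.
#' @export
canopyStructureIndex <- function(raster, ...) {
  h <- rasterHeight(raster)
  if (is.null(h)) stop("raster has no height layer")
  mask <- vegetationMask(raster, ...)
  if (!any(mask)) {
    warning("empty vegetation mask; 3DCI undefined")
    return(NA_real_)
  }
  hv <- h[mask]
  m <- mean(hv)
  if (m <= 0) return(0)
  cv <- sqrt(mean((hv - m)^2)) / m   # population CV
  min(max(1 - cv, 0), 1)
}

#' Extract all six traits from a plot raster
#'
#' @param raster a \linkS4class{PlotRaster}; traits requiring the height
#'   layer are NA when it is absent.
#' @param heightQuantile quantile for [plantHeight()].
#' @return data.frame with columns plot_id, das, trait, value.
#' @export
extractTraits <- function(raster, heightQuantile = 0.95) {
  hasH <- !is.null(rasterHeight(raster))
  vals <- c(
    height = if (hasH) plantHeight(raster, heightQuantile) else NA_real_,
    coverage = canopyCoverage(raster),
    "3dci" = if (hasH) canopyStructureIndex(raster) else NA_real_,
    asm = asm(raster),
    vari = vari(raster),
    ndyi = ndyi(raster))
  data.frame(plot_id = raster@plotId, das = raster@das,
             trait = names(vals), value = unname(vals),
             stringsAsFactors = FALSE, row.names = NULL)
}
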