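#' @import methods
NULL

#' ProfileCurve: a fitted seasonal trajectory for one trait
#'
#' A \code{ProfileCurve} holds the fitted functional form of one trait's
#' seasonal trajectory for one variety under one N treatment: the curve
#' family, its parameters, the days-after-sowing (DAS) domain the data
#' covered, and goodness-of-fit metrics. Evaluation outside the domain is
#' permitted but flagged as extrapolation by [evaluateCurve()].
#'
#' Families and their closed forms (x in DAS):
#' \describe{
#'   \item{gaussian}{\eqn{a \exp(-(x-b)^2 / (2c^2))} with amplitude
#'     \code{a > 0}, peak day \code{b}, spread \code{c > 0}. Used for
#'     plant height, the 3D canopy structure proxy, and VARI.}
#'   \item{fourier}{\eqn{\sum_{n=1}^{u} a_n \cos(n\pi x/L) + b_n \sin(n\pi x/L)}
#'     with fixed half-period \code{L} (the DAS span of the data) and
#'     order \code{u}. Used for ASM and NDYI.}
#'   \item{weibull}{\eqn{L (1 - \exp(-(x/x_0)^b))}, a saturating sigmoid
#'     with plateau \code{L > 0}, scale day \code{x0 > 0} and shape
#'     \code{b > 0}. Used for canopy coverage.}
#' }
#'
#' @slot family character(1), one of \code{"gaussian"}, \code{"fourier"},
#'   \code{"weibull"}.
#' @slot parameters named numeric vector of curve parameters
#'   (gaussian: a, b, c; weibull: L, b, x0; fourier: L, u, a1..au, b1..bu).
#' @slot domain numeric(2), DAS range covered by the fitted observations.
#' @slot metrics named numeric vector with at least \code{r2},
#'   \code{rmse}, \code{aic}, \code{n}.
#' @slot converged logical(1), whether the optimizer converged.
#' @slot meta list of identifying metadata (trait, variety, treatment,
#'   season); may be empty.
#'
#' @seealso [fitProfile()], [evaluateCurve()], [extractSubcurve()]
#' @exportClass ProfileCurve
setClass("ProfileCurve",
  representation(
    family = "character",
    parameters = "numeric",
    domain = "numeric",
    metrics = "numeric",
    converged = "logical",
    meta = "list"
  ),
  prototype(
    family = "gaussian",
    parameters = c(a = 1, b = 100, c = 30),
    domain = c(0, 200),
    metrics = c(r2 = NA_real_, rmse = NA_real_, aic = NA_real_, n = 0),
    converged = NA,
    meta = list()
  )
)

setValidity("ProfileCurve", function(object) {
  msg <- character()
  if (length(object@family) != 1L ||
      !object@family %in% c("gaussian", "fourier", "weibull"))
    msg <- c(msg, "family must be one of 'gaussian', 'fourier', 'weibull'")
  if (length(object@domain) != 2L || any(!is.finite(object@domain)) ||
      object@domain[1] > object@domain[2])
    msg <- c(msg, "domain must be a finite increasing numeric(2)")
  p <- object@parameters
  if (object@family == "gaussian") {
    if (!all(c("a", "b", "c") %in% names(p)))
      msg <- c(msg, "gaussian parameters must be named a, b, c")
    else if (isTRUE(p[["a"]] <= 0) || isTRUE(p[["c"]] <= 0))
      msg <- c(msg, "gaussian requires a > 0 and c > 0")
  } else if (object@family == "weibull") {
    if (!all(c("L", "b", "x0") %in% names(p)))
      msg <- c(msg, "weibull parameters must be named L, b, x0")
    else if (isTRUE(p[["L"]] <= 0) || isTRUE(p[["b"]] <= 0) ||
             isTRUE(p[["x0"]] <= 0))
      msg <- c(msg, "weibull requires L > 0, b > 0, x0 > 0")
  } else if (object@family == "fourier") {
    if (!all(c("L", "u") %in% names(p)))
      msg <- c(msg, "fourier parameters must include L and u")
  }
  if (length(msg)) msg else TRUE
})

#' PlotRaster: a plot-level canopy image with optional height layer
#'
#' Container for one pre-cropped plot observation: an RGB reflectance
#' raster with values in [0, 1] and, optionally, a per-pixel canopy
#' height model (CHM) in meters on the same pixel grid.
#'
#' @slot rgb numeric array H x W x 3, values in [0, 1].
#' @slot height numeric matrix H x W in meters, or a 0 x 0 matrix when no
#'   height layer is available.
#' @slot plotId character(1) plot identifier.
#' @slot das integer(1) days after sowing of the acquisition.
#'
#' @seealso [generatePlotRaster()], [extractTraits()]
#' @exportClass PlotRaster
setClass("PlotRaster",
  representation(
    rgb = "array",
    height = "matrix",
    plotId = "character",
    das = "integer"
  ),
  prototype(
    rgb = array(0, c(16, 16, 3)),
    height = matrix(numeric(0), 0, 0),
    plotId = NA_character_,
    das = NA_integer_
  )
)

setValidity("PlotRaster", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "rgb must be an H x W x 3 array")
  else {
    if (d[1] < 16L || d[2] < 16L)
      msg <- c(msg, "raster must be at least 16 x 16 pixels")
    if (any(object@rgb < 0 | object@rgb > 1, na.rm = TRUE))
      msg <- c(msg, "rgb values must lie in [0, 1]")
  }
  if (length(object@height) > 0L) {
    if (!identical(dim(object@height), d[1:2]))
      msg <- c(msg, "height layer must match the rgb pixel grid")
    if (any(object@height < 0, na.rm = TRUE))
      msg <- c(msg, "height values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeData: a biallelic marker matrix with a marker map
#'
#' Varieties x markers dosage matrix coded 0/1/2 on the minor allele,
#' with \code{NA} for missing calls, plus a marker map giving chromosome,
#' 1-based physical position and alleles for each marker.
#'
#' @slot geno numeric matrix, rows = varieties (rownames), columns =
#'   markers (colnames), entries in \{0, 1, 2, NA\}.
#' @slot map data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}; one row per marker, ids unique and matching
#'   \code{colnames(geno)}.
#'
#' @seealso [generateGenotypes()], [qcFilter()], [glmAssociation()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(geno = "matrix", map = "data.frame"),
  prototype(
    geno = matrix(numeric(0), 0, 0),
    map = data.frame(id = character(), chrom = character(),
                     pos = integer(), ref = character(),
                     alt = character())
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  g <- object@geno
  if (!all(g %in% c(0, 1, 2) | is.na(g)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  m <- object@map
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(m)))
    msg <- c(msg, sprintf("map must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(m$id))
      msg <- c(msg, "marker ids must be unique")
    if (nrow(m) != ncol(g))
      msg <- c(msg, "map rows must match genotype columns")
    else if (ncol(g) > 0 && !identical(as.character(m$id), colnames(g)))
      msg <- c(msg, "map ids must match genotype column names in order")
    if (any(m$pos < 0, na.rm = TRUE))
      msg <- c(msg, "positions must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "ProfileCurve", function(object) {
  cat(sprintf("ProfileCurve [%s] on DAS [%g, %g]\n",
              object@family, object@domain[1], object@domain[2]))
  p <- object@parameters
  cat("  parameters:",
      paste(sprintf("%s=%.4g", names(p), p), collapse = ", "), "\n")
  m <- object@metrics
  if (all(c("r2", "rmse") %in% names(m)))
    cat(sprintf("  fit: R2=%.4f RMSE=%.4g AIC=%.4g (n=%d, converged=%s)\n",
                m[["r2"]], m[["rmse"]], m[["aic"]], as.integer(m[["n"]]),
                object@converged))
  if (length(object@meta))
    cat("  meta:", paste(sprintf("%s=%s", names(object@meta),
                                 unlist(object@meta)), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PlotRaster", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("PlotRaster %s (DAS %s): %d x %d px, height layer: %s\n",
              object@plotId, object@das, d[1], d[2],
              if (length(object@height)) "yes" else "no"))
  invisible(NULL)
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d varieties x %d markers (%.2f%% missing)\n",
              nrow(object@geno), ncol(object@geno),
              100 * mean(is.na(object@geno))))
  chs <- unique(object@map$chrom)
  if (length(chs))
    cat("  chromosomes:", paste(utils::head(chs, 8), collapse = ", "),
        if (length(chs) > 8) "..." else "", "\n")
  invisible(NULL)
})

# ---- accessors ------------------------------------------------------------

#' Accessors for ProfileCurve, PlotRaster and GenotypeData
#'
#' @param object a \linkS4class{ProfileCurve}, \linkS4class{PlotRaster}
#'   or \linkS4class{GenotypeData}.
#' @return \code{curveFamily}: character(1); \code{curveParams} and
#'   \code{curveMetrics}: named numeric; \code{curveDomain}: numeric(2);
#'   \code{genoMatrix}: the dosage matrix; \code{markerMap}: the marker
#'   map data.frame; \code{rasterRGB}/\code{rasterHeight}: array/matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveFamily", function(object) standardGeneric("curveFamily"))
#' @rdname accessors
#' @export
setMethod("curveFamily", "ProfileCurve", function(object) object@family)

#' @rdname accessors
#' @export
setGeneric("curveParams", function(object) standardGeneric("curveParams"))
#' @rdname accessors
#' @export
setMethod("curveParams", "ProfileCurve", function(object) object@parameters)

#' @rdname accessors
#' @export
setGeneric("curveDomain", function(object) standardGeneric("curveDomain"))
#' @rdname accessors
#' @export
setMethod("curveDomain", "ProfileCurve", function(object) object@domain)

#' @rdname accessors
#' @export
setGeneric("curveMetrics", function(object) standardGeneric("curveMetrics"))
#' @rdname accessors
#' @export
setMethod("curveMetrics", "ProfileCurve", function(object) object@metrics)

#' @rdname accessors
#' @export
setGeneric("genoMatrix", function(object) standardGeneric("genoMatrix"))
#' @rdname accessors
#' @export
setMethod("genoMatrix", "GenotypeData", function(object) object@geno)

#' @rdname accessors
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setMethod("markerMap", "GenotypeData", function(object) object@map)

#' @rdname accessors
#' @export
setGeneric("rasterRGB", function(object) standardGeneric("rasterRGB"))
#' @rdname accessors
#' @export
setMethod("rasterRGB", "PlotRaster", function(object) object@rgb)

#' @rdname accessors
#' @export
setGeneric("rasterHeight", function(object) standardGeneric("rasterHeight"))
#' @rdname accessors
#' @export
setMethod("rasterHeight", "PlotRaster", function(object) {
  if (length(object@height)) object@height else NULL
})
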