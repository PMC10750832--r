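# Seasonal profile-curve fitting: nonlinear least squares for the
# Gaussian and Weibull families (multi-start Levenberg-Marquardt), linear
# least squares for the Fourier family, AIC-based family selection, and
# empirical percentile bands over collections of curves.

# Gaussian-family residual model
gaussEval <- function(p, x) p[["a"]] * exp(-(x - p[["b"]])^2 /
                                             (2 * p[["c"]]^2))
weibullEval <- function(p, x)
  p[["L"]] * (1 - exp(-(x / p[["x0"]])^p[["b"]]))

fourierEval <- function(p, x) {
  u <- as.integer(p[["u"]]); L <- p[["L"]]
  coefs <- p[c(rbind(paste0("a", seq_len(u)), paste0("b", seq_len(u))))]
  as.vector(fourierBasis(x, L, u) %*% coefs)
}

# Gaussian-log AIC for a least-squares fit with k parameters
lsAIC <- function(rss, n, k) n * log(rss / n + 1e-300) + 2 * (k + 1)

fitMetrics <- function(y, yhat, k) {
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  c(r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    rmse = sqrt(rss / length(y)),
    aic = lsAIC(rss, length(y), k),
    n = length(y))
}

fitGaussianNLS <- function(das, value, nStarts = 5, maxEval = 5000,
                           tol = 1e-10) {
  a0 <- max(value); b0 <- das[which.max(value)]
  c0 <- diff(range(das)) / 4
  best <- NULL
  for (s in seq_len(nStarts)) {
    jit <- if (s == 1) c(1, 1, 1) else exp(stats::runif(3, -0.35, 0.35))
    start <- list(a = max(a0 * jit[1], 1e-6),
                  b = b0 * jit[2],
                  c = max(c0 * jit[3], 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ a * exp(-(das - b)^2 / (2 * c^2)),
                        start = start,
                        lower = c(a = 1e-9, b = -Inf, c = 1e-6),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, maxfev = maxEval,
                          ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  best
}

fitWeibullNLS <- function(das, value, nStarts = 5, maxEval = 5000,
                          tol = 1e-10) {
  L0 <- max(value)
  half <- which(value >= L0 / 2)
  x00 <- if (length(half)) das[half[1]] else stats::median(das)
  best <- NULL
  for (s in seq_len(nStarts)) {
    jit <- if (s == 1) c(1, 1, 1) else exp(stats::runif(3, -0.35, 0.35))
    start <- list(L = max(L0 * jit[1], 1e-6),
                  b = 2 * jit[2],
                  x0 = max(x00 * jit[3], 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ L * (1 - exp(-(das / x0)^b)),
                        start = start,
                        lower = c(L = 1e-9, b = 1e-6, x0 = 1e-6),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, maxfev = maxEval,
                          ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a seasonal profile curve to one trait series
#'
#' Fits a trait's (DAS, value) observations with the requested curve
#' family. Gaussian and Weibull fits use multi-start Levenberg-Marquardt
#' nonlinear least squares (data-driven initial values, 5 jittered
#' restarts); the Fourier family is linear in its coefficients given the
#' fixed half-period \code{L = max(das) - min(das)} and is solved by
#' ordinary least squares. The Fourier order is capped so the
#' coefficient count stays below the number of observations.
#'
#' @param das strictly increasing numeric DAS values (no duplicates).
#' @param value trait observations, same length as \code{das}.
#' @param family one of \code{"gaussian"}, \code{"fourier"},
#'   \code{"weibull"}.
#' @param order Fourier order u (default 6; capped at
#'   \code{floor((n - 2) / 2)}).
#' @param meta optional list of identifying metadata attached to the
#'   curve.
#' @return a \linkS4class{ProfileCurve}.
#' @examples
#' das <- c(30, 50, 70, 90, 110, 130, 142, 154, 175, 196)
#' y <- 0.8 * exp(-(das - 170)^2 / (2 * 30^2))
#' fitProfile(das, y, "gaussian")
#' @export
fitProfile <- function(das, value,
                       family = c("gaussian", "fourier", "weibull"),
                       order = 6L, meta = list()) {
  family <- match.arg(family)
  if (length(das) != length(value)) stop("das and value lengths differ")
  ok <- is.finite(das) & is.finite(value)
  das <- das[ok]; value <- value[ok]
  if (anyDuplicated(das)) stop("duplicate das values")
  if (is.unsorted(das)) { o <- order(das); das <- das[o]; value <- value[o] }
  n <- length(das)
  nPar <- switch(family, gaussian = 3L, weibull = 3L,
                 fourier = 2L * order)
  if (family == "fourier") {
    order <- min(order, max(1L, (n - 2L) %/% 2L))
    nPar <- 2L * order
  }
  if (n < nPar + 1L)
    stop(sprintf("need at least %d observations for a %d-parameter %s fit",
                 nPar + 1L, nPar, family))
  if (family %in% c("gaussian", "weibull") &&
      stats::sd(value) < .Machine$double.eps^0.5)
    warning("constant series: ", family, " fit is degenerate")

  if (family == "fourier") {
    L <- diff(range(das))
    B <- fourierBasis(das, L, order)
    # minimum-norm least squares via the pseudoinverse, robust to an
    # order-inflated (near rank-deficient) basis
    sv <- svd(B)
    keep <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], value)) / sv$d[keep])
    coefs <- as.vector(coefs)
    names(coefs) <- colnames(B)
    yhat <- as.vector(B %*% coefs)
    params <- c(L = L, u = as.numeric(order), coefs)
    converged <- TRUE
  } else {
    best <- if (family == "gaussian") fitGaussianNLS(das, value)
            else fitWeibullNLS(das, value)
    if (is.null(best))
      stop(family, " fit failed to converge from all starts")
    params <- stats::coef(best$fit)
    yhat <- stats::fitted(best$fit)
    converged <- best$fit$convInfo$isConv %||% TRUE
  }
  methods::new("ProfileCurve",
               family = family,
               parameters = params,
               domain = range(das),
               metrics = fitMetrics(value, yhat,
                                    if (family == "fourier") nPar else 3L),
               converged = isTRUE(converged),
               meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a profile curve at given DAS values
#'
#' Closed-form evaluation of the fitted family. Evaluation outside the
#' fitted domain is permitted but flagged with a warning (extrapolation).
#'
#' @param curve a \linkS4class{ProfileCurve}.
#' @param das numeric DAS values.
#' @param warnExtrapolation warn when \code{das} falls outside the fitted
#'   domain (default TRUE).
#' @return numeric vector of curve values.
#' @export
evaluateCurve <- function(curve, das, warnExtrapolation = TRUE) {
  stopifnot(is(curve, "ProfileCurve"))
  dom <- curveDomain(curve)
  if (warnExtrapolation && any(das < dom[1] - 1e-9 | das > dom[2] + 1e-9))
    warning("evaluating outside the fitted domain [",
            dom[1], ", ", dom[2], "] (extrapolation)")
  p <- curveParams(curve)
  switch(curveFamily(curve),
         gaussian = gaussEval(p, das),
         weibull = weibullEval(p, das),
         fourier = fourierEval(p, das))
}

#' Fit all candidate families and select the best by AIC
#'
#' Fits each candidate family and ranks by AIC with an RMSE tiebreak.
#' The per-trait default mapping (height/3DCI/VARI: gaussian, canopy
#' coverage: weibull, ASM/NDYI: fourier) is available through
#' [defaultFamily()] as an override of data-driven selection.
#'
#' @inheritParams fitProfile
#' @param candidates character vector of at least one family name.
#' @return list with \code{family} (winner), \code{curve} (its
#'   \linkS4class{ProfileCurve}) and \code{table} (data.frame of family,
#'   r2, rmse, aic for every candidate that fit).
#' @export
selectFamily <- function(das, value,
                         candidates = c("gaussian", "fourier", "weibull"),
                         order = 6L, meta = list()) {
  if (length(candidates) < 1) stop("at least one candidate required")
  fits <- list()
  for (fam in candidates) {
    fits[[fam]] <- tryCatch(
      fitProfile(das, value, fam, order = order, meta = meta),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all candidate families failed to fit")
  tab <- do.call(rbind, lapply(names(fits), function(fam) {
    m <- curveMetrics(fits[[fam]])
    data.frame(family = fam, r2 = m[["r2"]], rmse = m[["rmse"]],
               aic = m[["aic"]], stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$aic, tab$rmse), , drop = FALSE]
  rownames(tab) <- NULL
  list(family = tab$family[1], curve = fits[[tab$family[1]]], table = tab)
}

#' Fit profile curves for a whole trial
#'
#' Fits one curve per variety x treatment x trait x season from
#' replicate-mean values at each flight day (set \code{byPlot = TRUE} to
#' fit each plot separately). Families follow [defaultFamily()].
#'
#' @param series long trait table (columns variety, treatment,
#'   replicate, season, trait, das, value), e.g. from [generateTrial()].
#' @param byPlot fit per plot instead of per replicate-mean (default
#'   FALSE).
#' @param order Fourier order (default 6, capped by data size).
#' @return data.frame with identifying columns and a \code{curve}
#'   list-column of \linkS4class{ProfileCurve} objects.
#' @export
fitTrialCurves <- function(series, byPlot = FALSE, order = 6L) {
  keys <- c("variety", "treatment", "trait", "season",
            if (byPlot) "replicate")
  miss <- setdiff(c(keys, "das", "value"), names(series))
  if (length(miss))
    stop("series lacks columns: ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(series[keys], list(sep = "\r")))
  idx <- split(seq_len(nrow(series)), key)
  ids <- series[vapply(idx, `[`, 0L, 1L), keys, drop = FALSE]
  rownames(ids) <- NULL
  curves <- vector("list", nrow(ids))
  for (i in seq_len(nrow(ids))) {
    d <- series[idx[[i]], c("das", "value")]
    if (!byPlot)
      d <- stats::aggregate(value ~ das, data = d, FUN = mean)
    fam <- defaultFamily(ids$trait[i])
    curves[[i]] <- tryCatch(
      fitProfile(d$das, d$value, fam, order = order,
                 meta = as.list(ids[i, , drop = FALSE])),
      error = function(e) {
        warning(sprintf("fit failed for %s/%s/%s: %s", ids$variety[i],
                        ids$treatment[i], ids$trait[i], conditionMessage(e)))
        NULL
      })
  }
  ids$curve <- curves
  ids
}

#' Pointwise empirical percentile band over a collection of curves
#'
#' Evaluates every curve on a DAS grid and returns the pointwise
#' empirical percentiles, the representation behind the shaded
#' confidence ribbons of seasonal trait plots (e.g. 15th to 85th, or
#' 25th to 75th, percentile bands).
#'
#' @param curves list of \linkS4class{ProfileCurve} objects (>= 3).
#' @param lower,upper percentile bounds in [0, 100] (default 15 and 85).
#' @param grid numeric DAS grid; defaults to 101 points spanning the
#'   first curve's domain.
#' @return data.frame with columns das, lower, upper, median.
#' @export
confidenceBand <- function(curves, lower = 15, upper = 85, grid = NULL) {
  if (length(curves) < 3) stop("need at least 3 curves for a band")
  if (lower > upper) stop("lower percentile exceeds upper")
  if (is.null(grid)) {
    dom <- curveDomain(curves[[1]])
    grid <- seq(dom[1], dom[2], length.out = 101)
  }
  vals <- vapply(curves, function(cv)
    evaluateCurve(cv, grid, warnExtrapolation = FALSE),
    numeric(length(grid)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(grid))
  data.frame(
    das = grid,
    lower = apply(vals, 1, stats::quantile, probs = lower / 100),
    upper = apply(vals, 1, stats::quantile, probs = upper / 100),
    median = apply(vals, 1, stats::median))
}
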