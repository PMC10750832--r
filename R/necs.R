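# N efficiency comprehensive scores (NECS) from the twelve yield and
# N-utilization indices, four-quadrant N-responsiveness classification,
# and cross-treatment consistent performers.

#' PCA of the twelve Y&N indices under one treatment
#'
#' Z-standardizes the twelve indices for the requested treatment and
#' eigen-decomposes their correlation structure (PCA on the correlation
#' matrix). Each component is sign-oriented so that its grain-yield
#' loading is non-negative: the PCA sign is arbitrary but the NECS
#' composite is sign-sensitive. Contribution rates are eigenvalue shares
#' and sum to 1.
#'
#' @param table Y&N index table (columns variety, treatment and the 12
#'   indices of [ynIndexNames()]).
#' @param treatment N level to subset (NULL uses the whole table).
#' @return list with \code{scores} (varieties x components matrix),
#'   \code{loadings}, \code{rates} (contribution rates), \code{cumRates},
#'   \code{varieties}.
#' @export
pcaIndices <- function(table, treatment = NULL) {
  if (!is.null(treatment)) table <- table[table$treatment == treatment, ]
  idx <- ynIndexNames()
  miss <- setdiff(idx, names(table))
  if (length(miss))
    stop("table lacks index columns: ", paste(miss, collapse = ", "))
  if (nrow(table) < 3) stop("need at least 3 varieties")
  X <- as.matrix(table[idx])
  if (any(colSums(!is.na(X)) == 0)) stop("all-missing index column")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < .Machine$double.eps^0.5))
    stop("constant-only table: PCA undefined")
  if (any(sds < .Machine$double.eps^0.5))
    warning("constant index column(s); dropped from PCA rank")
  pc <- stats::prcomp(X, center = TRUE,
                      scale. = ifelse(sds > 0, sds, 1))
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12
  if (!all(keep)) {
    warning("rank-deficient table: dropping ", sum(!keep),
            " null component(s)")
  }
  ev <- ev[keep]
  rot <- pc$rotation[, keep, drop = FALSE]
  sc <- pc$x[, keep, drop = FALSE]
  flip <- ifelse(rot["grain_yield", ] < 0, -1, 1)
  rot <- sweep(rot, 2, flip, `*`)
  sc <- sweep(sc, 2, flip, `*`)
  rates <- ev / sum(ev)
  rownames(sc) <- table$variety
  list(scores = sc, loadings = rot, rates = rates,
       cumRates = cumsum(rates), varieties = table$variety)
}

#' Number of components reaching a cumulative contribution rate
#'
#' @param pca result of [pcaIndices()] (or any list with a
#'   \code{cumRates} element).
#' @param ccrThreshold cumulative contribution-rate threshold in (0, 1]
#'   (default 0.85).
#' @return integer, the smallest k whose cumulative contribution rate
#'   reaches the threshold.
#' @export
selectComponents <- function(pca, ccrThreshold = 0.85) {
  if (ccrThreshold <= 0 || ccrThreshold > 1)
    stop("ccrThreshold must lie in (0, 1]")
  k <- which(pca$cumRates >= ccrThreshold - 1e-12)[1]
  if (is.na(k)) k <- length(pca$cumRates)
  as.integer(k)
}

#' N efficiency comprehensive scores
#'
#' NECS for variety i is the contribution-rate-weighted sum of its
#' retained component scores: \eqn{NECS_i = \sum_{j \le k} \lambda_j
#' PC_{ij}}, with \eqn{\lambda_j} the contribution rates as fractions.
#'
#' @param pca result of [pcaIndices()].
#' @param k number of retained components (default from
#'   [selectComponents()]).
#' @return named numeric vector of NECS values per variety.
#' @export
necsScores <- function(pca, k = selectComponents(pca)) {
  if (k > ncol(pca$scores)) stop("k exceeds available components")
  drop(pca$scores[, seq_len(k), drop = FALSE] %*%
         pca$rates[seq_len(k)])
}

#' Index weights from retained components
#'
#' Weight of index i is \eqn{\sum_{j \le k} \lambda_j |loading_{ij}|},
#' normalized to sum to 1 (absolute loading coefficients weighted by
#' contribution rates).
#'
#' @inheritParams necsScores
#' @return named numeric vector of 12 index weights summing to 1.
#' @export
indexWeights <- function(pca, k = selectComponents(pca)) {
  w <- abs(pca$loadings[, seq_len(k), drop = FALSE]) %*%
    pca$rates[seq_len(k)]
  drop(w / sum(w))
}

#' Classify varieties into the four N-responsiveness quadrants
#'
#' Places each variety in a two-axis quadrant model: the yield axis is
#' the mean z-score of the six yield-production indices and the
#' N-utilization axis the mean z-score of the six N-utilization indices
#' (z-scores within the requested treatment). "High" means at or above
#' the cohort mean of the axis (which is 0 for mean z-scores), "Low"
#' below it; ties go to High. The four labels are HYHN (high yield, high
#' N utilization; Class I), LYHN (Class II), LYLN (Class III) and HYLN
#' (Class IV).
#'
#' @param table Y&N index table.
#' @param treatment N level to subset (NULL uses the whole table).
#' @return data.frame with columns variety, yield_axis, n_axis, group.
#' @export
classifyQuadrants <- function(table, treatment = NULL) {
  if (!is.null(treatment)) table <- table[table$treatment == treatment, ]
  yIdx <- yieldIndexNames(); nIdx <- nIndexNames()
  miss <- setdiff(c(yIdx, nIdx), names(table))
  if (length(miss))
    stop("table lacks index columns: ", paste(miss, collapse = ", "))
  zmean <- function(cols) {
    X <- as.matrix(table[cols])
    sds <- apply(X, 2, stats::sd)
    if (all(sds < .Machine$double.eps^0.5))
      stop("degenerate axis: all index columns constant")
    Z <- scale(X[, sds > 0, drop = FALSE])
    rowMeans(Z)
  }
  yAxis <- zmean(yIdx)
  nAxis <- zmean(nIdx)
  group <- paste0(ifelse(yAxis >= mean(yAxis), "H", "L"), "Y",
                  ifelse(nAxis >= mean(nAxis), "H", "L"), "N")
  data.frame(variety = table$variety, yield_axis = yAxis,
             n_axis = nAxis, group = group,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Varieties consistently in a group across all treatments
#'
#' Intersects a group's membership across per-treatment quadrant
#' classifications (or any per-treatment named label sets), giving the
#' "overlapped" consistent performers.
#'
#' @param labels either a list of data.frames with columns variety and
#'   group (one per treatment, as from [classifyQuadrants()]) or a list
#'   of character vectors of variety names already subset to the group.
#' @param group group label to intersect (ignored when \code{labels}
#'   holds plain character vectors).
#' @return sorted character vector of variety names.
#' @export
consistentPerformers <- function(labels, group = "HYHN") {
  if (!length(labels)) stop("labels must cover at least one treatment")
  sets <- lapply(labels, function(l) {
    if (is.character(l)) l
    else l$variety[l$group == group]
  })
  sort(Reduce(intersect, sets))
}

#' Published HYHN / LYLN variety lists per N treatment
#'
#' Group-membership lists of the HYHN (Class I) and LYLN (Class III)
#' N-responsiveness classes under the N0, N180 and N270 treatments from
#' a multi-season field evaluation of 54 Chinese winter wheat varieties,
#' shipped as a plain-text table. Useful as a worked example for
#' [consistentPerformers()].
#'
#' @return data.frame with columns treatment, group, variety.
#' @export
nresGroupLists <- function() {
  path <- system.file("extdata", "nres_group_lists.tsv",
                      package = "wheatNRES", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
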