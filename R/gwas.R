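# Single-marker GLM association with population-structure covariates:
# marker QC, genotype-PCA structure, per-marker least-squares tests,
# cross-season significance filtering and candidate-gene windows.

#' Marker quality control
#'
#' Removes markers whose missing-call rate strictly exceeds
#' \code{maxMissing} or whose minor allele frequency (computed on
#' non-missing calls) is strictly below \code{minMaf}. Filtering is
#' idempotent.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @return list with \code{genotypes} (filtered
#'   \linkS4class{GenotypeData}) and \code{report} (data.frame: id,
#'   missing, maf, removed, reason).
#' @export
qcFilter <- function(genotypes, maxMissing = 0.10, minMaf = 0.05) {
  G <- genoMatrix(genotypes)
  if (!ncol(G)) stop("empty genotype matrix")
  missing <- colMeans(is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  badMiss <- missing > maxMissing
  badMaf <- maf < minMaf
  removed <- badMiss | badMaf
  reason <- rep("", ncol(G))
  reason[badMaf] <- "maf"
  reason[badMiss] <- "missing"
  reason[badMiss & badMaf] <- "missing+maf"
  report <- data.frame(id = colnames(G), missing = missing, maf = maf,
                       removed = removed, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(removed)) stop("QC removed every marker")
  keep <- which(!removed)
  gd <- methods::new("GenotypeData",
                     geno = G[, keep, drop = FALSE],
                     map = markerMap(genotypes)[keep, , drop = FALSE])
  list(genotypes = gd, report = report)
}

#' Population-structure covariates from genotype PCA
#'
#' Mean-imputes missing calls, centers the dosage matrix, and takes the
#' leading \code{k - 1} principal axes as the Q covariate matrix for the
#' association model; hard subgroup assignments come from k-means on
#' those axes. This is a deterministic, desk-scale stand-in for Bayesian
#' admixture estimation that is directly usable as GLM covariates.
#'
#' @param genotypes a \linkS4class{GenotypeData} (post-QC).
#' @param k number of subpopulations (default 3); \code{k = 1} yields an
#'   empty covariate set and a single cluster.
#' @param seed RNG seed for the k-means restarts.
#' @return list with \code{Q} (varieties x (k-1) covariate matrix),
#'   \code{cluster} (named integer assignments), \code{varExplained}.
#' @export
populationStructure <- function(genotypes, k = 3, seed = 1L) {
  G <- genoMatrix(genotypes)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(G)) stop("k exceeds the number of varieties")
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G))
  if (length(idx)) G[idx] <- mu[(idx - 1) %/% nrow(G) + 1]
  Gc <- sweep(G, 2, colMeans(G))
  if (k == 1)
    return(list(Q = matrix(numeric(0), nrow(G), 0,
                           dimnames = list(rownames(G), NULL)),
                cluster = stats::setNames(rep(1L, nrow(G)), rownames(G)),
                varExplained = numeric(0)))
  pc <- stats::prcomp(Gc, center = FALSE)
  nAx <- min(k - 1, ncol(pc$x))
  Q <- pc$x[, seq_len(nAx), drop = FALSE]
  colnames(Q) <- paste0("Q", seq_len(nAx))
  rownames(Q) <- rownames(G)
  cl <- withSeed(seed, stats::kmeans(Q, centers = k, nstart = 25))
  list(Q = Q,
       cluster = stats::setNames(cl$cluster, rownames(G)),
       varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nAx)])
}

#' Single-marker GLM association scan
#'
#' For each marker, fits the ordinary least-squares model
#' \code{phenotype ~ intercept + dosage + Q} and tests the additive
#' genotype term (t-test on the dosage coefficient, equivalent to the
#' partial F-test). Missing dosages are mean-imputed per marker; markers
#' with zero dosage variance after imputation are skipped with a log
#' entry (NA row).
#'
#' @param phenotype named numeric vector (names = varieties).
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param Q optional population-structure covariate matrix (varieties in
#'   rows).
#' @param meta optional named list (trait, window, treatment, season)
#'   attached to the result.
#' @return data.frame of class \code{GWASResult}: id, chrom, pos,
#'   effect, se, p, plus any metadata columns.
#' @export
glmAssociation <- function(phenotype, genotypes, Q = NULL, meta = list()) {
  G <- genoMatrix(genotypes)
  common <- intersect(names(phenotype), rownames(G))
  if (length(common) < (if (is.null(Q)) 0 else ncol(Q)) + 3)
    stop("too few varieties shared between phenotype and genotypes")
  y <- phenotype[common]
  G <- G[common, , drop = FALSE]
  covars <- cbind(`(Intercept)` = rep(1, length(y)),
                  if (!is.null(Q)) Q[common, , drop = FALSE])
  n <- length(y)
  nMark <- ncol(G)
  eff <- se <- pval <- rep(NA_real_, nMark)
  skipped <- character()
  for (m in seq_len(nMark)) {
    g <- G[, m]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::sd(g) < .Machine$double.eps^0.5) {
      skipped <- c(skipped, colnames(G)[m])
      next
    }
    Xm <- cbind(covars, g = g)
    fit <- stats::lm.fit(Xm, y)
    dfRes <- n - fit$rank
    if (dfRes < 1 || is.na(fit$coefficients[["g"]])) {
      skipped <- c(skipped, colnames(G)[m])
      next
    }
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / dfRes
    XtXinv <- tryCatch(
      chol2inv(chol(crossprod(Xm[, !is.na(fit$coefficients),
                                 drop = FALSE]))),
      error = function(e) NULL)
    if (is.null(XtXinv)) {
      skipped <- c(skipped, colnames(G)[m])
      next
    }
    gPos <- sum(!is.na(fit$coefficients))
    seG <- sqrt(sigma2 * XtXinv[gPos, gPos])
    tG <- fit$coefficients[["g"]] / seG
    eff[m] <- fit$coefficients[["g"]]
    se[m] <- seG
    pval[m] <- 2 * stats::pt(abs(tG), dfRes, lower.tail = FALSE)
  }
  if (length(skipped))
    message(length(skipped), " zero-variance marker(s) skipped")
  map <- markerMap(genotypes)
  res <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                    effect = eff, se = se, p = pval,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(meta)) res[[nm]] <- meta[[nm]]
  class(res) <- c("GWASResult", class(res))
  res
}

#' Markers significant in every required season
#'
#' @param results list of \code{GWASResult} data.frames, one per season.
#' @param alpha significance threshold on P (default 1e-5; markers with
#'   \code{p < alpha} count as significant).
#' @param requireAll require significance in every season (default TRUE;
#'   FALSE keeps markers significant in any season).
#' @return character vector of marker ids.
#' @export
significantHits <- function(results, alpha = 1e-5, requireAll = TRUE) {
  if (!length(results)) stop("need at least one season of results")
  if (inherits(results, "data.frame")) results <- list(results)
  sets <- lapply(results, function(r) r$id[!is.na(r$p) & r$p < alpha])
  if (requireAll) Reduce(intersect, sets) else Reduce(union, sets)
}

#' Candidate genes within a window around a significant marker
#'
#' Returns annotation records whose interval overlaps
#' \code{[pos - halfWidth, pos + halfWidth]} on the marker's chromosome
#' (interval overlap, not midpoint distance).
#'
#' @param hit one-row data.frame (or list) with \code{chrom} and
#'   \code{pos}, e.g. a row of a \code{GWASResult}.
#' @param annotation a \code{GRanges} of gene records (e.g. from
#'   [readAnnotation()]) or a data.frame with columns gene_id, chrom,
#'   start, end.
#' @param halfWidth window half-width in bp (default 500000).
#' @return data.frame of genes: gene_id, chrom, start, end, distance
#'   (0 when the gene spans the marker).
#' @export
candidateWindow <- function(hit, annotation, halfWidth = 500000) {
  if (is(annotation, "GRanges")) {
    ann <- data.frame(
      gene_id = if (!is.null(annotation$gene_id)) annotation$gene_id
                else if (!is.null(annotation$ID)) annotation$ID
                else if (!is.null(annotation$Name)) annotation$Name
                else as.character(seq_along(annotation)),
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      stringsAsFactors = FALSE)
  } else ann <- annotation
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns ", paste(need, collapse = ", "))
  lo <- hit$pos - halfWidth; hi <- hit$pos + halfWidth
  sel <- ann$chrom == hit$chrom & ann$end >= lo & ann$start <= hi
  out <- ann[sel, need, drop = FALSE]
  out$distance <- pmax(0, pmax(out$start - hit$pos, hit$pos - out$end))
  rownames(out) <- NULL
  out
}

#' Contrast static and dynamic phenotypes in association scans
#'
#' Runs [glmAssociation()] for every static phenotype (trait values at
#' fixed DAF time points, typically 5/10/15/20/25) and every dynamic
#' phenotype (five-day section CGRs) and tabulates significant hits per
#' family. Both phenotype families should derive from the same fitted
#' curves.
#'
#' @param staticPhenos named list of phenotype vectors, names like
#'   \code{"height@15"} (trait at DAF 15).
#' @param dynamicPhenos named list of phenotype vectors, names like
#'   \code{"height_11-15"} (trait CGR over a section).
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param Q optional covariate matrix.
#' @param alpha significance threshold (default 1e-5).
#' @return list with \code{hits} (long data.frame: family, phenotype,
#'   id, chrom, pos, p), \code{counts} (family, n_hits),
#'   \code{staticHits}/\code{dynamicHits} (marker-id vectors).
#' @export
compareStaticDynamic <- function(staticPhenos, dynamicPhenos, genotypes,
                                 Q = NULL, alpha = 1e-5) {
  runFamily <- function(phenos, family) {
    rows <- list()
    for (nm in names(phenos)) {
      res <- glmAssociation(phenos[[nm]], genotypes, Q)
      sig <- res[!is.na(res$p) & res$p < alpha, c("id", "chrom", "pos", "p")]
      if (nrow(sig)) {
        sig$family <- family; sig$phenotype <- nm
        rows[[nm]] <- sig
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(id = character(), chrom = character(),
                    pos = integer(), p = numeric(), family = character(),
                    phenotype = character(), stringsAsFactors = FALSE)
  }
  st <- runFamily(staticPhenos, "static")
  dy <- runFamily(dynamicPhenos, "dynamic")
  hits <- rbind(st, dy)
  rownames(hits) <- NULL
  list(hits = hits,
       counts = data.frame(family = c("static", "dynamic"),
                           n_hits = c(nrow(st), nrow(dy))),
       staticHits = unique(st$id),
       dynamicHits = unique(dy$id))
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages between marker pairs
#' (composite LD on 0/1/2 codes), pairwise-complete over missing calls.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param markers optional marker ids to subset.
#' @return symmetric matrix of r-squared values.
#' @export
ldR2 <- function(genotypes, markers = NULL) {
  G <- genoMatrix(genotypes)
  if (!is.null(markers)) G <- G[, markers, drop = FALSE]
  stats::cor(G, use = "pairwise.complete.obs")^2
}

#' Manhattan and QQ plot data from a GWAS result
#'
#' Returns plain tables ready for plotting: per-marker cumulative
#' genome coordinate and -log10 P (Manhattan), and expected vs observed
#' -log10 P quantiles (QQ).
#'
#' @param result a \code{GWASResult}.
#' @return list with \code{manhattan} and \code{qq} data.frames.
#' @export
gwasPlotData <- function(result) {
  r <- result[!is.na(result$p), , drop = FALSE]
  r <- r[order(r$chrom, r$pos), , drop = FALSE]
  offset <- 0; cumPos <- numeric(nrow(r))
  for (ch in unique(r$chrom)) {
    sel <- r$chrom == ch
    cumPos[sel] <- r$pos[sel] + offset
    offset <- offset + max(r$pos[sel])
  }
  man <- data.frame(id = r$id, chrom = r$chrom, pos = r$pos,
                    cum_pos = cumPos, neglog10p = -log10(r$p))
  o <- sort(r$p, decreasing = TRUE)
  qq <- data.frame(
    expected = rev(-log10(stats::ppoints(length(o)))),
    observed = -log10(o))
  list(manhattan = man, qq = qq)
}
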