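# Dissection of the 25-day post-fertilization response window into
# five-day compound growth rates (CGR) and key N-response phases.

#' Define the post-fertilization response window
#'
#' The response window spans days-after-fertilization (DAF) 1 to 25,
#' divided into five contiguous 5-day sections (1-5, 6-10, 11-15, 16-20,
#' 21-25 DAF). DAF d maps to DAS \code{fertilizationDas + (d - 1)}, so
#' with the default fertilization at 130 DAS, 1 DAF = 130 DAS and
#' 25 DAF = 154 DAS. Note that adjacent sections do not share endpoints
#' (section 1-5 ends at DAF 5, section 6-10 starts at DAF 6).
#'
#' @param fertilizationDas DAS of the jointing fertilization
#'   (default 130).
#' @return object of class \code{ResponseWindow}: list with
#'   \code{fertilizationDas}, \code{dafRange}, \code{sections}
#'   (data.frame: section, daf_start, daf_end, das_start, das_end).
#' @export
responseWindow <- function(fertilizationDas = 130) {
  starts <- c(1, 6, 11, 16, 21)
  sections <- data.frame(
    section = paste0(starts, "-", starts + 4),
    daf_start = starts, daf_end = starts + 4,
    stringsAsFactors = FALSE)
  sections$das_start <- dafToDas(sections$daf_start, fertilizationDas)
  sections$das_end <- dafToDas(sections$daf_end, fertilizationDas)
  structure(list(fertilizationDas = fertilizationDas,
                 dafRange = c(1, 25),
                 sections = sections),
            class = "ResponseWindow")
}

#' Convert between DAF and DAS
#'
#' DAF d corresponds to DAS \code{fertilizationDas + (d - 1)}: day 1
#' after fertilization is the fertilization day itself (130 DAS by
#' default), and 25 DAF is 154 DAS.
#'
#' @param daf,das numeric day indices.
#' @param fertilizationDas DAS of the fertilization (default 130).
#' @return numeric vector of converted days.
#' @export
dafToDas <- function(daf, fertilizationDas = 130)
  fertilizationDas + (daf - 1)

#' @rdname dafToDas
#' @export
dasToDaf <- function(das, fertilizationDas = 130)
  das - fertilizationDas + 1

#' Restrict a profile curve to the response window
#'
#' Returns the same fitted curve with its domain restricted to the
#' window's DAS range (130 to 154 DAS by default); evaluation delegates
#' to the parent parameters, so the restriction is an identity on values.
#'
#' @param curve a \linkS4class{ProfileCurve}.
#' @param window a [responseWindow()].
#' @return a \linkS4class{ProfileCurve} with restricted domain.
#' @export
extractSubcurve <- function(curve, window = responseWindow()) {
  stopifnot(is(curve, "ProfileCurve"), inherits(window, "ResponseWindow"))
  dasLo <- dafToDas(window$dafRange[1], window$fertilizationDas)
  dasHi <- dafToDas(window$dafRange[2], window$fertilizationDas)
  dom <- curveDomain(curve)
  if (dasLo < dom[1] - 1e-9 || dasHi > dom[2] + 1e-9)
    stop(sprintf("response window [%g, %g] DAS outside curve domain [%g, %g]",
                 dasLo, dasHi, dom[1], dom[2]))
  methods::initialize(curve, domain = c(dasLo, dasHi))
}

#' Five-day compound growth rate of a curve over one section
#'
#' CGR over a 5-day section starting at DAF i is
#' \eqn{(f(x_{i+4}) / f(x_i))^{1/5} - 1}, the compound daily rate that
#' carries the curve from its value on the section's first day to its
#' value on the last day (both in DAS coordinates). A constant curve
#' gives 0; a curve that doubles over the section gives
#' \eqn{2^{1/5} - 1 \approx 0.1487}. Non-positive curve values at either
#' endpoint are an error, not clipped: all six traits are non-negative
#' and a non-positive fitted value signals a bad fit.
#'
#' @param curve a \linkS4class{ProfileCurve} (typically a subcurve).
#' @param section section label (\code{"1-5"}, \code{"6-10"},
#'   \code{"11-15"}, \code{"16-20"} or \code{"21-25"}) or the starting
#'   DAF (1, 6, 11, 16, 21).
#' @param window a [responseWindow()].
#' @return numeric(1) compound daily growth rate.
#' @export
cgr <- function(curve, section, window = responseWindow()) {
  sec <- window$sections
  if (is.numeric(section)) {
    row <- match(section, sec$daf_start)
  } else row <- match(section, sec$section)
  if (is.na(row)) stop("unknown section: ", section)
  f0 <- evaluateCurve(curve, sec$das_start[row], warnExtrapolation = FALSE)
  f1 <- evaluateCurve(curve, sec$das_end[row], warnExtrapolation = FALSE)
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf("CGR undefined: curve value %.4g <= 0 at section start", f0))
  if (!is.finite(f1) || f1 <= 0)
    stop(sprintf("CGR undefined: curve value %.4g <= 0 at section end", f1))
  (f1 / f0)^(1 / 5) - 1
}

#' Build the CGR performance matrix for a trial
#'
#' Computes the five-day CGR of every fitted (variety, treatment, trait)
#' subcurve over the five response-window sections, yielding the tidy
#' form of the CGR performance matrix. Missing or failed curves are
#' recorded as NA with a warning, never silently dropped.
#'
#' @param curves data.frame with columns variety, treatment, trait and a
#'   \code{curve} list-column, as from [fitTrialCurves()] (a season
#'   column, if present, is carried through).
#' @param window a [responseWindow()].
#' @param groups optional named vector mapping variety to
#'   N-responsiveness group; carried into the output for [keyPhases()].
#' @return data.frame with columns variety, treatment, trait, section,
#'   cgr (and season/group when available).
#' @export
buildCGRMatrix <- function(curves, window = responseWindow(),
                           groups = NULL) {
  need <- c("variety", "treatment", "trait", "curve")
  miss <- setdiff(need, names(curves))
  if (length(miss))
    stop("curves lacks columns: ", paste(miss, collapse = ", "))
  sec <- window$sections$section
  nMissing <- 0L
  rows <- vector("list", nrow(curves))
  for (i in seq_len(nrow(curves))) {
    cv <- curves$curve[[i]]
    vals <- rep(NA_real_, length(sec))
    if (!is.null(cv)) {
      sub <- tryCatch(extractSubcurve(cv, window), error = function(e) NULL)
      if (!is.null(sub))
        vals <- vapply(sec, function(s)
          tryCatch(cgr(sub, s, window), error = function(e) NA_real_),
          numeric(1))
    }
    if (anyNA(vals)) nMissing <- nMissing + sum(is.na(vals))
    out <- data.frame(variety = curves$variety[i],
                      treatment = curves$treatment[i],
                      trait = curves$trait[i],
                      section = sec, cgr = vals,
                      stringsAsFactors = FALSE)
    if ("season" %in% names(curves)) out$season <- curves$season[i]
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (nMissing > 0)
    warning(nMissing, " CGR cell(s) missing (failed or out-of-window fits)")
  if (!is.null(groups))
    res$group <- unname(groups[res$variety])
  res
}

#' Bin CGR values for pseudo-color display
#'
#' Bins CGRs (as percentages) into the display scale used for CGR
#' heat maps, saturating below -15\% and above +15\%.
#'
#' @param cgrValues numeric CGRs (per-day rates, not percent).
#' @param breaks bin edges in percent (default every 5 from -15 to 15).
#' @return ordered factor of bins.
#' @export
binCGR <- function(cgrValues, breaks = seq(-15, 15, by = 5)) {
  pct <- 100 * cgrValues
  cut(pmin(pmax(pct, min(breaks) - 1e-9), max(breaks) + 1e-9),
      breaks = c(-Inf, breaks, Inf), ordered_result = TRUE)
}

#' Flag key N-response phases per group, treatment and trait
#'
#' A section is flagged active for a (group, treatment, trait) cell when
#' the absolute mean CGR over the group's varieties reaches
#' \code{threshold} (per-day rate, default 0.01 = 1\% per day);
#' contiguous flagged sections are merged into phases.
#'
#' @param cgrMatrix tidy CGR table from [buildCGRMatrix()] with a
#'   \code{group} column (or supply \code{groups}).
#' @param threshold absolute mean-CGR activity threshold (default 0.01).
#' @param groups optional named variety-to-group vector when the table
#'   has no group column.
#' @return data.frame with columns group, treatment, trait, phase (e.g.
#'   \code{"1-10"}), sections (comma-joined member sections).
#' @export
keyPhases <- function(cgrMatrix, threshold = 0.01, groups = NULL) {
  if (!"group" %in% names(cgrMatrix)) {
    if (is.null(groups)) stop("cgrMatrix needs a group column or groups=")
    cgrMatrix$group <- unname(groups[cgrMatrix$variety])
  }
  if (any(is.na(cgrMatrix$group))) stop("unassigned varieties in groups")
  secOrder <- responseWindow()$sections
  agg <- stats::aggregate(cgr ~ group + treatment + trait + section,
                          data = cgrMatrix, FUN = mean, na.rm = TRUE)
  agg$active <- abs(agg$cgr) >= threshold
  keys <- unique(agg[c("group", "treatment", "trait")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- agg$group == keys$group[i] &
      agg$treatment == keys$treatment[i] & agg$trait == keys$trait[i]
    a <- agg[sel, ]
    a <- a[match(secOrder$section, a$section), ]
    act <- which(!is.na(a$active) & a$active)
    if (!length(act)) next
    runs <- split(act, cumsum(c(1, diff(act) != 1)))
    for (rn in runs) {
      out[[length(out) + 1L]] <- data.frame(
        group = keys$group[i], treatment = keys$treatment[i],
        trait = keys$trait[i],
        phase = paste0(secOrder$daf_start[rn[1]], "-",
                       secOrder$daf_end[rn[length(rn)]]),
        sections = paste(secOrder$section[rn], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(), treatment = numeric(),
                      trait = character(), phase = character(),
                      sections = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
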