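# Interdependence statistics: per-analyte and network-level summaries, hub
# profiles and the hub report.

#' Per-analyte interdependence statistics
#'
#' For one analyte, sums |r| over all 16 partners regardless of significance
#' (sigma), divides by 16 (meanAbs), and counts significant (p <= alpha)
#' positive and negative correlations; trend-level correlations
#' (alpha < p <= trendAlpha) are counted separately, never added to the
#' significant counts. A coefficient of exactly 0 is classified as neither
#' positive nor negative.
#'
#' @param net A \linkS4class{CorrelationNetwork}.
#' @param analyte Analyte name.
#' @param alpha Significance threshold (default 0.05).
#' @param trendAlpha Trend threshold (default 0.1).
#' @return A one-row \code{data.frame} with columns \code{analyte},
#'   \code{sigma}, \code{meanAbs}, \code{nPos}, \code{nNeg},
#'   \code{nPosTrend}, \code{nNegTrend}.
#' @seealso \code{\link{networkSummary}}
#' @export
analyteSummary <- function(net, analyte, alpha = 0.05, trendAlpha = 0.1) {
  stopifnot(is(net, "CorrelationNetwork"))
  analyte <- .normalizeAnalytes(analyte)
  .checkAlphas(alpha, trendAlpha)
  r <- net@r[analyte, ]
  p <- net@p[analyte, ]
  keep <- names(r) != analyte
  r <- r[keep]; p <- p[keep]
  data.frame(
    analyte = analyte,
    sigma = sum(abs(r)),
    meanAbs = sum(abs(r)) / length(r),
    nPos = sum(p <= alpha & r > 0),
    nNeg = sum(p <= alpha & r < 0),
    nPosTrend = sum(p > alpha & p <= trendAlpha & r > 0),
    nNegTrend = sum(p > alpha & p <= trendAlpha & r < 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.checkAlphas <- function(alpha, trendAlpha) {
  if (!(alpha > 0 && alpha < trendAlpha && trendAlpha < 1)) {
    stop("need 0 < alpha < trendAlpha < 1", call. = FALSE)
  }
}

#' Network-level interdependence summary
#'
#' Aggregates the 17 per-analyte summaries of a correlation network into a
#' \linkS4class{NetworkSummary}: the total of the per-analyte sigma values,
#' the network mean (total / (17 * 16)) and the totals of the signed
#' significant-correlation counts (each significant pair contributes to both
#' of its endpoints, so totals are even).
#'
#' The \code{data.frame} method aggregates an existing per-analyte table
#' (columns as produced by \code{\link{analyteSummary}}), which allows
#' published per-analyte values to be run through the same totals.
#'
#' @param x A \linkS4class{CorrelationNetwork} or a per-analyte
#'   \code{data.frame}.
#' @param alpha,trendAlpha Thresholds, see \code{\link{analyteSummary}}.
#' @param group Group id recorded on the result (data.frame method).
#' @return A \linkS4class{NetworkSummary}.
#' @export
setGeneric("networkSummary",
           function(x, alpha = 0.05, trendAlpha = 0.1, group = "")
             standardGeneric("networkSummary"))

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "CorrelationNetwork",
  function(x, alpha = 0.05, trendAlpha = 0.1, group = "") {
    pa <- do.call(rbind, lapply(x@analytes, analyteSummary, net = x,
                                alpha = alpha, trendAlpha = trendAlpha))
    if (!nzchar(group)) group <- x@group
    networkSummary(pa, alpha = alpha, trendAlpha = trendAlpha, group = group)
  })

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "data.frame",
  function(x, alpha = 0.05, trendAlpha = 0.1, group = "") {
    need <- c("analyte", "sigma", "meanAbs", "nPos", "nNeg")
    if (!all(need %in% colnames(x))) {
      stop("per-analyte table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (is.null(x$nPosTrend)) x$nPosTrend <- 0L
    if (is.null(x$nNegTrend)) x$nNegTrend <- 0L
    A <- nrow(x)
    new("NetworkSummary",
        perAnalyte = x,
        totalSigma = sum(x$sigma),
        networkMean = sum(x$sigma) / (A * (A - 1)),
        totalPos = as.integer(sum(x$nPos)),
        totalNeg = as.integer(sum(x$nNeg)),
        totalPosTrend = as.integer(sum(x$nPosTrend)),
        totalNegTrend = as.integer(sum(x$nNegTrend)),
        alpha = alpha, trendAlpha = trendAlpha, group = group)
  })

#' NetworkSummary accessors
#'
#' @param x A \linkS4class{NetworkSummary}.
#' @return \code{perAnalyte} returns the 17-row per-analyte table;
#'   \code{summaryTotals} a one-row \code{data.frame} of the group-level
#'   totals.
#' @name summary-accessors
NULL

#' @rdname summary-accessors
#' @export
perAnalyte <- function(x) { stopifnot(is(x, "NetworkSummary")); x@perAnalyte }

#' @rdname summary-accessors
#' @export
summaryTotals <- function(x) {
  stopifnot(is(x, "NetworkSummary"))
  data.frame(group = x@group, totalSigma = x@totalSigma,
             networkMean = x@networkMean, totalPos = x@totalPos,
             totalNeg = x@totalNeg, totalPosTrend = x@totalPosTrend,
             totalNegTrend = x@totalNegTrend, stringsAsFactors = FALSE)
}

setMethod("show", "NetworkSummary", function(object) {
  cat("NetworkSummary",
      if (nzchar(object@group)) paste0("(", object@group, ")"), "\n")
  cat(sprintf("  total sigma %.2f, network mean %.2f\n",
              object@totalSigma, object@networkMean))
  cat(sprintf("  significant correlations: %d positive, %d negative (alpha = %g)\n",
              object@totalPos, object@totalNeg, object@alpha))
  cat(sprintf("  trends: %d positive, %d negative (%g < p <= %g)\n",
              object@totalPosTrend, object@totalNegTrend, object@alpha,
              object@trendAlpha))
})

#' Hub profile: algebraic sum of one analyte's signed correlations
#'
#' Preserves the sign of each of the 16 coefficients and reports their
#' algebraic sum. A shift of the sum toward negative values summarizes the
#' replacement of positive by negative correlations around the hub.
#'
#' @param signedR Numeric vector of length 16 with entries in [-1, 1];
#'   names (partner analytes) are kept if present.
#' @param hub Hub analyte name (default \code{"OGDHC"}).
#' @return A \linkS4class{HubProfile}.
#' @examples
#' hubProfile(rep(-0.5, 16))@signedSum  # -8
#' @export
hubProfile <- function(signedR, hub = "OGDHC") {
  .assertNumericVector(signedR, "signedR", 1L)
  if (length(signedR) != 16L) {
    stop("'signedR' must have length 16", call. = FALSE)
  }
  if (any(abs(signedR) > 1)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  new("HubProfile", hub = .normalizeAnalytes(hub),
      signedR = signedR, signedSum = sum(signedR))
}

#' @rdname hubProfile
#' @param x A \linkS4class{HubProfile}.
#' @export
signedSum <- function(x) { stopifnot(is(x, "HubProfile")); x@signedSum }

setMethod("show", "HubProfile", function(object) {
  cat("HubProfile:", object@hub, "\n")
  cat(sprintf("  algebraic sum of %d signed correlations: %.2f\n",
              length(object@signedR), object@signedSum))
})

# partner ordering used in hub reports: the companion hub(s) first, then the
# remaining amino acids in panel order
.hubPartners <- function(hub) {
  pref <- setdiff(c("TRP", "OGDHC"), hub)
  c(pref, setdiff(.PANEL, c(hub, pref)))
}

#' Hub report across groups
#'
#' For each requested hub and each available group network, extracts the 16
#' signed coefficients of the hub (companion hub first, then the amino acids
#' in panel order) and appends their algebraic sum as a final \code{"Sum"}
#' row. Full precision is retained; round for rendering with
#' \code{\link{formatHubReport}}.
#'
#' @param networks Named list of \linkS4class{CorrelationNetwork} objects;
#'   names are group ids.
#' @param hubs Character vector of hub analytes (default OGDHC and TRP).
#' @param groups Group ids to report (default: all networks). A requested
#'   group with no network is dropped with a warning.
#' @return A \code{data.frame}: first column \code{partner} (16 partners then
#'   \code{"Sum"}), then one column \code{"<hub>.<group>"} per hub x group.
#' @export
hubReport <- function(networks, hubs = c("OGDHC", "TRP"),
                      groups = names(networks)) {
  if (!length(hubs)) stop("'hubs' must be non-empty", call. = FALSE)
  hubs <- .normalizeAnalytes(hubs)
  missing <- setdiff(groups, names(networks))
  if (length(missing)) {
    warning("no network for group(s): ", paste(missing, collapse = ", "),
            "; column(s) omitted", call. = FALSE)
    groups <- intersect(groups, names(networks))
  }
  if (!length(groups)) stop("no groups to report", call. = FALSE)
  partnerList <- lapply(hubs, .hubPartners)
  labels <- partnerList[[1L]]
  if (length(hubs) > 1L) {
    tails <- unique(lapply(partnerList, `[`, -1L))
    if (length(tails) > 1L) {
      stop("hubs with incompatible partner orderings cannot share a report",
           call. = FALSE)
    }
    firsts <- unique(vapply(partnerList, `[`, character(1L), 1L))
    if (length(firsts) > 1L) {
      labels[1L] <- paste(firsts, collapse = " or ")
    }
  }
  cols <- list()
  for (i in seq_along(hubs)) {
    for (g in groups) {
      r <- networkR(networks[[g]])[hubs[i], partnerList[[i]]]
      cols[[paste(hubs[i], g, sep = ".")]] <- c(unname(r), sum(r))
    }
  }
  data.frame(partner = c(labels, "Sum"), cols,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Render a hub report at two decimals
#'
#' @param report A \code{data.frame} from \code{\link{hubReport}}.
#' @param digits Decimal places (default 2), rounded half away from zero.
#' @return The report with numeric columns rounded.
#' @export
formatHubReport <- function(report, digits = 2L) {
  num <- vapply(report, is.numeric, logical(1L))
  report[num] <- lapply(report[num], roundHalfAway, digits = digits)
  report
}
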