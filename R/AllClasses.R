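# S4 class definitions and validity methods.

#' CohortExperiment: one experimental group of animals
#'
#' A \code{SummarizedExperiment} whose single assay, \code{"concentration"},
#' holds the canonical 17-analyte panel (rows, fixed order: OGDHC activity
#' then 16 amino acids) measured in each animal (columns). Amino acids are in
#' micromol/g fresh tissue, OGDHC activity in micromol/min/g; units are
#' metadata only, since Pearson correlation is invariant to linear rescaling.
#' All animals in one object belong to the same experimental group, recorded
#' per animal in \code{colData} columns \code{stressor} and \code{state}.
#'
#' Validity requires: rows exactly the canonical panel in canonical order;
#' all values finite and non-negative; a single valid (stressor, state)
#' combination shared by all animals.
#'
#' @seealso \code{\link{cohortExperiment}}, \code{\link{readCohort}},
#'   \code{\link{buildNetwork}}
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  if (!identical(rownames(object), .PANEL)) {
    msg <- c(msg, "rows must be the canonical 17-analyte panel in order")
  }
  if (!"concentration" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'concentration' is required")
  } else {
    v <- SummarizedExperiment::assay(object, "concentration")
    if (!is.numeric(v) || any(!is.finite(v))) {
      msg <- c(msg, "all concentrations must be finite numbers")
    } else if (any(v < 0)) {
      msg <- c(msg, "concentrations must be non-negative")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stressor", "state") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'stressor' and 'state'")
  } else {
    st <- unique(as.character(cd$stressor))
    ph <- unique(as.character(cd$state))
    if (length(st) != 1L || !st %in% .STRESSORS) {
      msg <- c(msg, "all animals must share one valid stressor")
    }
    if (length(ph) != 1L || !ph %in% .STATES) {
      msg <- c(msg, "all animals must share one valid state")
    }
  }
  if (ncol(object) > 0L && anyDuplicated(colnames(object))) {
    msg <- c(msg, "animal ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationNetwork: per-group Pearson network over the analyte panel
#'
#' Symmetric matrices of pairwise Pearson correlation coefficients and their
#' two-sided p-values over the 17 analytes of one experimental group, with
#' the common per-pair sample size. Diagonals are \code{NA} (self-correlation
#' is excluded from all summaries).
#'
#' @slot analytes Character vector, the canonical panel.
#' @slot r,p Numeric 17 x 17 symmetric matrices; \code{|r| <= 1},
#'   \code{p} in (0, 1], diagonal \code{NA}.
#' @slot n Integer, number of animals behind every pair.
#' @slot group Character, \code{"<stressor>.<state>"} or \code{""}.
#' @seealso \code{\link{buildNetwork}}, \code{\link{correlationNetwork}}
#' @export
setClass("CorrelationNetwork",
  representation(analytes = "character", r = "matrix", p = "matrix",
                 n = "integer", group = "character"))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  a <- object@analytes
  A <- length(a)
  for (nm in c("r", "p")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(A, A))) {
      msg <- c(msg, sprintf("'%s' must be %d x %d", nm, A, A))
      next
    }
    if (!identical(rownames(m), a) || !identical(colnames(m), a)) {
      msg <- c(msg, sprintf("'%s' dimnames must match the analytes", nm))
    }
    if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE)) {
      msg <- c(msg, sprintf("'%s' must be symmetric within 1e-12", nm))
    }
    off <- m[row(m) != col(m)]
    if (anyNA(off)) {
      msg <- c(msg, sprintf("every off-diagonal cell of '%s' must be set", nm))
    }
  }
  if (!length(msg)) {
    off <- row(object@r) != col(object@r)
    if (any(abs(object@r[off]) > 1 + 1e-12)) {
      msg <- c(msg, "correlations must lie in [-1, 1]")
    }
    if (any(object@p[off] <= 0 | object@p[off] > 1)) {
      msg <- c(msg, "p-values must lie in (0, 1]")
    }
  }
  if (length(object@n) != 1L || object@n < 4L) {
    msg <- c(msg, "'n' must be a single integer >= 4")
  }
  if (length(msg)) msg else TRUE
})

#' NetworkSummary: interdependence statistics of one correlation network
#'
#' Per-analyte summed absolute correlations (sigma), their mean over the 16
#' partner analytes, and counts of significant (p <= alpha) positive and
#' negative correlations, with trend-level (alpha < p <= trendAlpha) counts
#' kept separate; plus the group-level totals. Each significant pair
#' contributes to both endpoints, so the totals are always even.
#'
#' @slot perAnalyte \code{data.frame} with one row per analyte: columns
#'   \code{analyte}, \code{sigma}, \code{meanAbs}, \code{nPos}, \code{nNeg},
#'   \code{nPosTrend}, \code{nNegTrend}.
#' @slot totalSigma,networkMean Numeric; \code{networkMean} is
#'   \code{totalSigma / (A * (A - 1))}.
#' @slot totalPos,totalNeg,totalPosTrend,totalNegTrend Integer totals.
#' @slot alpha,trendAlpha Significance and trend thresholds used.
#' @slot group Character group id (may be \code{""}).
#' @seealso \code{\link{networkSummary}}
#' @export
setClass("NetworkSummary",
  representation(perAnalyte = "data.frame", totalSigma = "numeric",
                 networkMean = "numeric", totalPos = "integer",
                 totalNeg = "integer", totalPosTrend = "integer",
                 totalNegTrend = "integer", alpha = "numeric",
                 trendAlpha = "numeric", group = "character"))

setValidity("NetworkSummary", function(object) {
  msg <- character()
  pa <- object@perAnalyte
  need <- c("analyte", "sigma", "meanAbs", "nPos", "nNeg",
            "nPosTrend", "nNegTrend")
  if (!all(need %in% colnames(pa))) {
    msg <- c(msg, "perAnalyte is missing required columns")
  } else {
    A <- nrow(pa)
    if (any(abs(pa$meanAbs * (A - 1) - pa$sigma) > 1e-9)) {
      msg <- c(msg, "meanAbs * (A - 1) must equal sigma within 1e-9")
    }
    if (any(pa$nPos + pa$nNeg > A - 1)) {
      msg <- c(msg, "significant counts cannot exceed A - 1 partners")
    }
    if (abs(object@networkMean * A * (A - 1) - object@totalSigma) > 1e-9) {
      msg <- c(msg, "networkMean * A * (A - 1) must equal totalSigma")
    }
    if (object@totalPos %% 2L || object@totalNeg %% 2L) {
      msg <- c(msg, "totalPos and totalNeg must be even")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HubProfile: signed correlations of one hub analyte with its 16 partners
#'
#' The hub's vector of signed Pearson coefficients against the other 16 panel
#' analytes and its algebraic (sign-preserving) sum. Increasingly negative
#' sums flag the stress-induced switch of the hub's correlations from
#' positive to negative.
#'
#' @slot hub Analyte name (OGDHC and TRP are the hubs of interest).
#' @slot signedR Named numeric vector of length 16, entries in [-1, 1].
#' @slot signedSum Numeric, \code{sum(signedR)}.
#' @seealso \code{\link{hubProfile}}, \code{\link{hubReport}}
#' @export
setClass("HubProfile",
  representation(hub = "character", signedR = "numeric",
                 signedSum = "numeric"))

setValidity("HubProfile", function(object) {
  msg <- character()
  if (length(object@hub) != 1L) msg <- c(msg, "'hub' must be a single name")
  if (any(abs(object@signedR) > 1)) {
    msg <- c(msg, "signed correlations must lie in [-1, 1]")
  }
  if (abs(object@signedSum - sum(object@signedR)) > 1e-9) {
    msg <- c(msg, "signedSum must equal sum(signedR) within 1e-9")
  }
  if (abs(object@signedSum) > length(object@signedR)) {
    msg <- c(msg, "|signedSum| cannot exceed the number of partners")
  }
  if (length(msg)) msg else TRUE
})

#' WilcoxonResult: paired signed-rank test result
#'
#' @slot statistic The smaller of the two one-sided rank sums (after zero
#'   differences are removed; midranks for ties).
#' @slot nEffective Number of pairs contributing after zero removal.
#' @slot p Two-sided p-value in (0, 1].
#' @slot method \code{"exact"} (full sign-assignment distribution) or
#'   \code{"normal_approx"} (tie-corrected normal with continuity correction).
#' @seealso \code{\link{wilcoxonSignedRank}}
#' @export
setClass("WilcoxonResult",
  representation(statistic = "numeric", nEffective = "integer",
                 p = "numeric", method = "character"))

setValidity("WilcoxonResult", function(object) {
  msg <- character()
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (!object@method %in% c("exact", "normal_approx")) {
    msg <- c(msg, "method must be 'exact' or 'normal_approx'")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: recipe for a simulated cohort
#'
#' Mean and SD vectors over the canonical panel, a target correlation matrix,
#' group size, seed, distribution family and group label. The target matrix
#' may be indefinite; it is repaired to positive semidefiniteness (eigenvalue
#' clipping, \code{\link{nearestPDCorrelation}}) at generation time.
#'
#' @slot analytes Character, the canonical panel.
#' @slot mean,sd Numeric vectors (length 17, \code{sd > 0}).
#' @slot targetCorr Symmetric 17 x 17 matrix, unit diagonal, entries in
#'   [-1, 1].
#' @slot nAnimals Integer >= 4.
#' @slot seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @slot family \code{"lognormal"} (default for concentrations, which are
#'   positive) or \code{"normal"}.
#' @slot stressor,state Group label for the generated cohort.
#' @seealso \code{\link{syntheticSpec}}, \code{\link{generateCohort}},
#'   \code{\link{specFromHubProfiles}}
#' @export
setClass("SyntheticSpec",
  representation(analytes = "character", mean = "numeric", sd = "numeric",
                 targetCorr = "matrix", nAnimals = "integer",
                 seed = "integer", family = "character",
                 stressor = "character", state = "character"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  A <- length(object@analytes)
  if (length(object@mean) != A || length(object@sd) != A) {
    msg <- c(msg, "'mean' and 'sd' must match the analyte panel length")
  }
  if (any(object@sd <= 0)) msg <- c(msg, "all sd must be > 0")
  tc <- object@targetCorr
  if (!all(dim(tc) == c(A, A))) {
    msg <- c(msg, "targetCorr must be square over the panel")
  } else {
    if (any(abs(tc - t(tc)) > 1e-8)) {
      msg <- c(msg, "targetCorr must be symmetric")
    }
    if (any(abs(diag(tc) - 1) > 1e-8)) {
      msg <- c(msg, "targetCorr must have unit diagonal")
    }
    if (any(abs(tc) > 1 + 1e-8)) {
      msg <- c(msg, "targetCorr entries must lie in [-1, 1]")
    }
  }
  if (length(object@nAnimals) != 1L || object@nAnimals < 4L) {
    msg <- c(msg, "nAnimals must be a single integer >= 4")
  }
  if (!object@family %in% c("normal", "lognormal")) {
    msg <- c(msg, "family must be 'normal' or 'lognormal'")
  }
  if (!object@stressor %in% .STRESSORS || !object@state %in% .STATES) {
    msg <- c(msg, "invalid group label")
  }
  if (length(msg)) msg else TRUE
})
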