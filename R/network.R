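# Pearson correlation networks.

#' Pearson correlation with analytic two-sided p-value
#'
#' Computes r as the centered dot product over the product of norms and its
#' two-sided p-value from \code{t = r * sqrt((n - 2) / (1 - r^2))} on
#' \code{n - 2} degrees of freedom. Degenerate inputs (constant vectors) are
#' an error, not r = 0; a perfect correlation returns the smallest positive
#' representable p rather than 0.
#'
#' @param x,y Numeric vectors of equal length \code{n >= 4}.
#' @return A list with elements \code{r}, \code{p} and \code{n}.
#' @examples
#' pearsonTest(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearsonTest <- function(x, y) {
  .assertNumericVector(x, "x", 4L)
  .assertNumericVector(y, "y", 4L)
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector has no defined correlation",
         call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  list(r = r, p = .pFromR(r, n), n = n)
}

# two-sided p for a Pearson r at sample size n (t distribution, n - 2 df)
.pFromR <- function(r, n) {
  r2 <- pmin(r * r, 1)
  p <- ifelse(r2 >= 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r2)),
                            df = n - 2, lower.tail = FALSE))
  .clampP(p)
}

#' Build the per-group correlation network of a cohort
#'
#' Computes all 136 unique Pearson correlations among the 17 analytes of one
#' experimental group, with analytic two-sided p-values.
#'
#' @param cohort A \linkS4class{CohortExperiment} with at least 4 animals.
#' @return A \linkS4class{CorrelationNetwork}.
#' @examples
#' sp <- syntheticSpec(nAnimals = 10, seed = 1)
#' net <- buildNetwork(generateCohort(sp))
#' networkR(net)["OGDHC", "TRP"]
#' @export
buildNetwork <- function(cohort) {
  stopifnot(is(cohort, "CohortExperiment"))
  v <- concentrations(cohort)
  n <- nrow(v)
  if (n < 4L) {
    stop("at least 4 animals are required for correlations", call. = FALSE)
  }
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant analyte column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(v)
  r <- (r + t(r)) / 2
  p <- .pFromR(r, n)
  diag(r) <- NA_real_
  diag(p) <- NA_real_
  correlationNetwork(r, p, n, group = cohortGroup(cohort))
}

#' Assemble a CorrelationNetwork from matrices
#'
#' Low-level constructor, used for fixture-based networks (e.g. carrying
#' published coefficient tables) as well as by \code{\link{buildNetwork}}.
#'
#' @param r,p Symmetric 17 x 17 matrices with analyte dimnames (any panel
#'   order; reordered canonically). Diagonals are set to \code{NA}.
#' @param n Per-pair sample size (integer >= 4).
#' @param group Optional \code{"<stressor>.<state>"} id.
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
correlationNetwork <- function(r, p, n, group = "") {
  stopifnot(is.matrix(r), is.matrix(p))
  ord <- .normalizeAnalytes(rownames(r))
  rownames(r) <- colnames(r) <- ord
  rownames(p) <- colnames(p) <- ord
  r <- r[.PANEL, .PANEL]
  p <- p[.PANEL, .PANEL]
  diag(r) <- NA_real_
  diag(p) <- NA_real_
  new("CorrelationNetwork", analytes = .PANEL, r = r, p = p,
      n = as.integer(n), group = as.character(group))
}

#' Fixture network carrying one hub's published coefficient column
#'
#' Builds a \linkS4class{CorrelationNetwork} whose hub row/column holds the
#' given signed coefficients while all other pairs are 0 with p = 1. Used to
#' replay published hub correlation vectors through the reporting code.
#'
#' @param hub Hub analyte name.
#' @param coefs Named numeric vector over the 16 partner analytes.
#' @param group Group id for the network.
#' @param n Nominal sample size recorded on the network.
#' @param p Two-sided p-values for the hub pairs (default 1: unknown).
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
networkFromHubColumn <- function(hub, coefs, group = "", n = 8L, p = 1) {
  hub <- .normalizeAnalytes(hub)
  partners <- .normalizeAnalytes(names(coefs))
  stopifnot(length(coefs) == 16L, !hub %in% partners)
  r <- matrix(0, 17L, 17L, dimnames = list(.PANEL, .PANEL))
  pm <- matrix(1, 17L, 17L, dimnames = list(.PANEL, .PANEL))
  r[hub, partners] <- coefs
  r[partners, hub] <- coefs
  pm[hub, partners] <- p
  pm[partners, hub] <- p
  correlationNetwork(r, pm, n, group = group)
}

#' Network accessors
#'
#' @param x A \linkS4class{CorrelationNetwork}.
#' @return \code{networkR}/\code{networkP} return the symmetric coefficient
#'   and p-value matrices (diagonal \code{NA}); \code{networkN} the per-pair
#'   sample size; \code{networkGroup} the group id.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
networkR <- function(x) { stopifnot(is(x, "CorrelationNetwork")); x@r }

#' @rdname network-accessors
#' @export
networkP <- function(x) { stopifnot(is(x, "CorrelationNetwork")); x@p }

#' @rdname network-accessors
#' @export
networkN <- function(x) { stopifnot(is(x, "CorrelationNetwork")); x@n }

#' @rdname network-accessors
#' @export
networkGroup <- function(x) { stopifnot(is(x, "CorrelationNetwork")); x@group }

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork",
      if (nzchar(object@group)) paste0("(", object@group, ")"), "\n")
  cat("  ", length(object@analytes), "analytes,",
      choose(length(object@analytes), 2L), "pairs, n =", object@n,
      "animals per pair\n")
  sig <- sum(object@p <= 0.05, na.rm = TRUE) / 2L
  cat("  significant pairs (p <= 0.05):", sig, "\n")
})
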