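# CohortExperiment construction and accessors.

#' Build a CohortExperiment from an animals-by-analytes matrix
#'
#' @param values Numeric matrix or data.frame, one row per animal, one column
#'   per analyte. Column names may be any case variant of the canonical panel
#'   names and in any order; they are normalized and reordered.
#' @param stressor,state Group label of the cohort (\code{control}, \code{SP}
#'   or \code{hypoxia}; \code{NP} or \code{P}).
#' @param animalIds Optional character vector of unique animal identifiers;
#'   defaults to the rownames of \code{values} or \code{animal_1 ...}.
#' @return A \linkS4class{CohortExperiment}.
#' @examples
#' m <- matrix(runif(4 * 17, 1, 5), nrow = 4,
#'             dimnames = list(NULL, panelNames()))
#' cohortExperiment(m, "control", "NP")
#' @export
cohortExperiment <- function(values, stressor, state, animalIds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("'values' must have analyte column names", call. = FALSE)
  }
  colnames(values) <- .normalizeAnalytes(colnames(values))
  if (length(unique(colnames(values))) != length(.PANEL)) {
    miss <- setdiff(.PANEL, colnames(values))
    stop("missing analyte column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  values <- values[, .PANEL, drop = FALSE]
  storage.mode(values) <- "double"
  stressor <- .matchToken(stressor, .STRESSORS, "stressor")
  state <- .matchToken(state, .STATES, "state")
  if (is.null(animalIds)) animalIds <- rownames(values)
  if (is.null(animalIds)) {
    animalIds <- sprintf("animal_%d", seq_len(nrow(values)))
  }
  rownames(values) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = t(values)),
    rowData = S4Vectors::DataFrame(kind = analytePanel()$kind,
                                   row.names = .PANEL),
    colData = S4Vectors::DataFrame(
      stressor = rep(stressor, nrow(values)),
      state = rep(state, nrow(values)),
      row.names = as.character(animalIds))
  )
  new("CohortExperiment", se)
}

#' Cohort accessors
#'
#' @param x A \linkS4class{CohortExperiment}.
#' @return \code{concentrations} returns the animals-by-analytes numeric
#'   matrix; \code{nAnimals} the number of animals; \code{animalIds} their
#'   identifiers; \code{groupStressor}/\code{groupState} the group label
#'   components and \code{cohortGroup} the \code{"<stressor>.<state>"} id.
#' @name cohort-accessors
#' @examples
#' m <- matrix(runif(4 * 17, 1, 5), nrow = 4,
#'             dimnames = list(NULL, panelNames()))
#' co <- cohortExperiment(m, "SP", "P")
#' dim(concentrations(co))
#' cohortGroup(co)
NULL

#' @rdname cohort-accessors
#' @export
concentrations <- function(x) {
  stopifnot(is(x, "CohortExperiment"))
  t(SummarizedExperiment::assay(x, "concentration"))
}

#' @rdname cohort-accessors
#' @export
nAnimals <- function(x) ncol(x)

#' @rdname cohort-accessors
#' @export
animalIds <- function(x) colnames(x)

#' @rdname cohort-accessors
#' @export
groupStressor <- function(x) {
  as.character(SummarizedExperiment::colData(x)$stressor[1L])
}

#' @rdname cohort-accessors
#' @export
groupState <- function(x) {
  as.character(SummarizedExperiment::colData(x)$state[1L])
}

#' @rdname cohort-accessors
#' @export
cohortGroup <- function(x) groupId(groupStressor(x), groupState(x))

setMethod("show", "CohortExperiment", function(object) {
  cat("CohortExperiment:", cohortGroup(object), "\n")
  cat("  ", ncol(object), "animals x", nrow(object), "analytes",
      "(OGDHC activity + 16 amino acids)\n")
  callNextMethod()
})
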