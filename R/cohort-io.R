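# Reading and writing the tidy cohort table format.
#
# Layout: one row per animal with header
#   animal_id,stressor,state,OGDHC,ALA,...,VAL
# Values are written at full double precision ("%.17g") so that a write/read
# round trip is bit-exact.

#' Read cohorts from a tidy CSV/TSV table
#'
#' The file must carry the header \code{animal_id, stressor, state} followed
#' by the 17 canonical analyte columns (any case, any order). Rows are
#' partitioned by \code{(stressor, state)} into one
#' \linkS4class{CohortExperiment} per experimental group.
#'
#' @param path File path.
#' @param dialect \code{"auto"} (by extension; default), \code{"csv"} or
#'   \code{"tsv"}.
#' @return Named list of \linkS4class{CohortExperiment} objects, names are
#'   the \code{"<stressor>.<state>"} group ids, ordered as
#'   \code{\link{validGroups}}.
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  meta <- c("animal_id", "stressor", "state")
  lowered <- tolower(colnames(df))
  metaIdx <- match(meta, lowered)
  if (anyNA(metaIdx)) {
    stop("missing required column(s): ",
         paste(meta[is.na(metaIdx)], collapse = ", "), call. = FALSE)
  }
  colnames(df)[metaIdx] <- meta
  analyteCols <- setdiff(colnames(df), meta)
  canon <- .normalizeAnalytes(analyteCols)   # errors on unknown columns
  colnames(df)[match(analyteCols, colnames(df))] <- canon
  if (length(unique(canon)) != length(.PANEL)) {
    stop("missing analyte column(s): ",
         paste(setdiff(.PANEL, canon), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[.PANEL], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, .PANEL))
  bad <- which(!stats::complete.cases(vals) |
                 apply(vals, 1L, function(r) any(!is.finite(r) | r < 0)))
  if (length(bad)) {
    stop("non-numeric or negative value(s) in row(s) with animal_id: ",
         paste(df$animal_id[bad], collapse = ", "), call. = FALSE)
  }
  groups <- mapply(groupId, df$stressor, df$state)   # validates tokens
  out <- lapply(split(seq_len(nrow(df)), factor(groups)), function(idx) {
    cohortExperiment(vals[idx, , drop = FALSE],
                     stressor = df$stressor[idx[1L]],
                     state = df$state[idx[1L]],
                     animalIds = df$animal_id[idx])
  })
  out[order(match(names(out), validGroups()))]
}

#' Write cohorts to a tidy CSV/TSV table
#'
#' Values are serialized at full double precision, so
#' \code{readCohort(writeCohort(x))} reproduces the concentration matrices
#' bit-exactly.
#'
#' @param groups A \linkS4class{CohortExperiment} or a non-empty list of them.
#' @param path Output file path.
#' @param dialect \code{"auto"} (by extension), \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readCohort}}
#' @export
writeCohort <- function(groups, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  if (is(groups, "CohortExperiment")) groups <- list(groups)
  if (!length(groups)) stop("'groups' must be non-empty", call. = FALSE)
  lines <- paste(c("animal_id", "stressor", "state", .PANEL), collapse = sep)
  for (g in groups) {
    stopifnot(is(g, "CohortExperiment"))
    v <- concentrations(g)
    body <- apply(v, 1L, function(r) {
      paste(sprintf("%.17g", r), collapse = sep)
    })
    lines <- c(lines, paste(animalIds(g), groupStressor(g), groupState(g),
                            body, sep = sep))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
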