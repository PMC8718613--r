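# Canonical analyte panel and experimental-group vocabulary.

.PANEL <- c("OGDHC", "ALA", "ARG", "ASP", "GABA", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "SER", "TRP", "TYR", "VAL")

.STRESSORS <- c("control", "SP", "hypoxia")
.STATES <- c("NP", "P")

#' Canonical analyte panel
#'
#' The fixed 17-analyte panel every cohort is measured on: the activity of the
#' 2-oxoglutarate dehydrogenase complex (OGDHC, micromol/min/g) followed by 16
#' free amino acids (micromol/g fresh tissue), in canonical order.
#'
#' @return A \code{data.frame} with columns \code{name} and \code{kind}
#'   (\code{"enzyme_activity"} or \code{"amino_acid"}).
#' @examples
#' analytePanel()
#' @export
analytePanel <- function() {
  data.frame(
    name = .PANEL,
    kind = c("enzyme_activity", rep("amino_acid", 16L)),
    stringsAsFactors = FALSE
  )
}

#' Names of the canonical analytes
#'
#' @return Character vector of the 17 analyte names, OGDHC first.
#' @export
panelNames <- function() .PANEL

#' Experimental group labels
#'
#' A group is the combination of a stressor (\code{control}, \code{SP} for
#' succinyl phosphonate, or \code{hypoxia}) and a physiological state
#' (\code{NP} non-pregnant, \code{P} pregnant); six combinations are valid.
#'
#' @param stressor,state Character scalars.
#' @return \code{groupId} returns the canonical \code{"<stressor>.<state>"}
#'   identifier; \code{validGroups} returns all six identifiers.
#' @examples
#' groupId("control", "NP")
#' validGroups()
#' @export
groupId <- function(stressor, state) {
  stressor <- .matchToken(stressor, .STRESSORS, "stressor")
  state <- .matchToken(state, .STATES, "state")
  paste(stressor, state, sep = ".")
}

#' @rdname groupId
#' @export
validGroups <- function() {
  as.vector(t(outer(.STRESSORS, .STATES, paste, sep = ".")))
}

# case-insensitive token matching with a helpful error
.matchToken <- function(x, choices, what) {
  if (length(x) != 1L || is.na(x)) {
    stop("'", what, "' must be a single non-missing value", call. = FALSE)
  }
  hit <- match(tolower(x), tolower(choices))
  if (is.na(hit)) {
    stop("unknown ", what, " '", x, "'; expected one of: ",
         paste(choices, collapse = ", "), call. = FALSE)
  }
  choices[hit]
}

# map possibly case-variant analyte names onto the canonical panel
.normalizeAnalytes <- function(nms) {
  hit <- match(toupper(nms), .PANEL)
  if (anyNA(hit)) {
    stop("unknown analyte column(s): ",
         paste(nms[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  .PANEL[hit]
}
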