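# Published reference tables shipped with the package.

#' Reference interdependence and hub-correlation tables
#'
#' Plain-text copies of the published per-analyte network statistics from
#' the six-group rat cerebellum study the package's statistics were
#' developed around. \code{referenceNetworkSummary} returns per-analyte
#' sigma (summed |r| over the 16 partners), the printed per-analyte mean
#' (\code{xbar}) and the counts of significant positive/negative
#' correlations, for the control and SP groups of non-pregnant (NP) and
#' pregnant (P) animals. \code{referenceHubCorrelations} returns the signed
#' correlation vectors of the OGDHC and TRP hubs with their 16 partner
#' analytes for the control, SP and hypoxia groups of both states. These
#' values serve as validation fixtures for the summary statistics and as
#' realistic inputs to \code{\link{specFromHubProfiles}}.
#'
#' @return A \code{data.frame}: for \code{referenceNetworkSummary} with
#'   columns \code{analyte}, \code{state}, \code{stressor}, \code{sigma},
#'   \code{xbar}, \code{n_pos}, \code{n_neg}; for
#'   \code{referenceHubCorrelations} with columns \code{hub}, \code{state},
#'   \code{stressor}, \code{partner}, \code{r}.
#' @examples
#' ref <- referenceHubCorrelations()
#' ogdhc <- subset(ref, hub == "OGDHC" & state == "NP" &
#'                   stressor == "hypoxia")
#' signedSum(hubProfile(ogdhc$r, "OGDHC"))  # -11.09
#' @export
referenceNetworkSummary <- function() {
  utils::read.csv(system.file("extdata", "reference_network_summary.csv",
                              package = "aminonet"),
                  stringsAsFactors = FALSE)
}

#' @rdname referenceNetworkSummary
#' @export
referenceHubCorrelations <- function() {
  utils::read.csv(system.file("extdata", "reference_hub_correlations.csv",
                              package = "aminonet"),
                  stringsAsFactors = FALSE)
}

#' One reference hub column as a named vector
#'
#' Convenience extractor: the 16 signed coefficients of one hub in one
#' group, named by partner analyte, in report order.
#'
#' @param hub \code{"OGDHC"} or \code{"TRP"}.
#' @param stressor \code{"control"}, \code{"SP"} or \code{"hypoxia"}.
#' @param state \code{"NP"} or \code{"P"}.
#' @return Named numeric vector of length 16.
#' @export
referenceHubColumn <- function(hub, stressor, state) {
  ref <- referenceHubCorrelations()
  sel <- ref$hub == .normalizeAnalytes(hub) &
    ref$stressor == .matchToken(stressor, .STRESSORS, "stressor") &
    ref$state == .matchToken(state, .STATES, "state")
  if (!any(sel)) stop("no reference column for that combination",
                      call. = FALSE)
  stats::setNames(ref$r[sel], ref$partner[sel])
}
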