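# End-to-end orchestration: ingest or simulate cohorts, build networks,
# write the report bundle.

#' Pipeline run configuration
#'
#' @param input Path to a tidy cohort CSV/TSV (see \code{\link{readCohort}}),
#'   or \code{NULL} to simulate from \code{specs}.
#' @param specs Named list of \linkS4class{SyntheticSpec} objects (one per
#'   group) used when \code{input} is \code{NULL}.
#' @param alpha,trendAlpha Significance and trend thresholds
#'   (defaults 0.05, 0.1; must satisfy 0 < alpha < trendAlpha < 1).
#' @param hubs Hub analytes for the hub report (default OGDHC, TRP).
#' @param comparisons List of length-2 character vectors of group ids to
#'   compare (Wilcoxon on per-analyte sigma and signed counts); \code{NULL}
#'   selects every within-state stressor pair plus control NP-vs-P.
#' @param outDir Output directory (created if absent).
#' @param seed Integer master seed; when simulating, spec seeds are derived
#'   from it so that one seed fixes the whole bundle.
#' @param format \code{"csv"} or \code{"tsv"} for the machine outputs.
#' @return A validated \code{RunConfig} object (a list).
#' @seealso \code{\link{runPipeline}}
#' @export
runConfig <- function(input = NULL, specs = NULL, alpha = 0.05,
                      trendAlpha = 0.1, hubs = c("OGDHC", "TRP"),
                      comparisons = NULL, outDir = tempfile("aminonet_run_"),
                      seed = 1L, format = c("csv", "tsv")) {
  .checkAlphas(alpha, trendAlpha)
  format <- match.arg(format)
  if (is.null(input) && is.null(specs)) {
    stop("either 'input' or 'specs' is required", call. = FALSE)
  }
  if (!is.null(specs)) {
    stopifnot(all(vapply(specs, is, logical(1L), "SyntheticSpec")))
  }
  structure(list(input = input, specs = specs, alpha = alpha,
                 trendAlpha = trendAlpha,
                 hubs = .normalizeAnalytes(hubs),
                 comparisons = comparisons, outDir = outDir,
                 seed = as.integer(seed), format = format),
            class = "RunConfig")
}

# default footer comparisons: stressor vs control within state, SP vs
# hypoxia, and control NP vs P, restricted to available groups
.defaultComparisons <- function(groupIds) {
  out <- list()
  for (st in .STATES) {
    g <- function(s) paste(s, st, sep = ".")
    for (pair in list(c(g("control"), g("SP")),
                      c(g("control"), g("hypoxia")),
                      c(g("SP"), g("hypoxia")))) {
      if (all(pair %in% groupIds)) out[[length(out) + 1L]] <- pair
    }
  }
  if (all(c("control.NP", "control.P") %in% groupIds)) {
    out[[length(out) + 1L]] <- c("control.NP", "control.P")
  }
  out
}

#' Run the full analysis pipeline
#'
#' Resolves cohorts (reading \code{input} or simulating from \code{specs}),
#' builds one correlation network per group, and writes a report bundle to
#' \code{outDir}: per-group r and p matrices, the per-analyte
#' interdependence summary with group totals, the hub report (full
#' precision plus a 2-decimal rendering), Wilcoxon comparisons of network
#' parameters between groups, per-analyte two-way ANOVA (when both factors
#' vary) and Tukey contrasts, a JSON manifest echoing the configuration,
#' and a plain-text log. Outputs are deterministic for a fixed
#' configuration and seed (no timestamps). On error, files created by the
#' failed run are removed and the error is re-signalled with the stage
#' name.
#'
#' @param config A \code{RunConfig} from \code{\link{runConfig}}.
#' @return Invisibly, a list with the cohorts, networks, summaries, hub
#'   report, comparison and ANOVA tables, and the paths written.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))
  sep <- if (config$format == "tsv") "\t" else ","
  ext <- config$format
  emit <- function(df, name) {
    path <- file.path(config$outDir, paste0(name, ".", ext))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- "ingest"
  result <- tryCatch({
    cohorts <- if (!is.null(config$input)) {
      note("reading cohorts from ", config$input)
      readCohort(config$input)
    } else {
      note("simulating ", length(config$specs), " cohort(s), master seed ",
           config$seed)
      specs <- config$specs
      for (i in seq_along(specs)) {
        specs[[i]]@seed <- as.integer(config$seed + 1000L * i)
      }
      cs <- lapply(specs, generateCohort)
      stats::setNames(cs, vapply(cs, cohortGroup, character(1L)))
    }

    stage <- "network"
    networks <- lapply(cohorts, buildNetwork)
    for (g in names(networks)) {
      r <- networkR(networks[[g]]); p <- networkP(networks[[g]])
      emit(data.frame(analyte = rownames(r), r, check.names = FALSE),
           paste0("r_matrix_", g))
      emit(data.frame(analyte = rownames(p), p, check.names = FALSE),
           paste0("p_matrix_", g))
    }
    note("built ", length(networks), " network(s): ",
         paste(names(networks), collapse = ", "))

    stage <- "summary"
    summaries <- lapply(networks, networkSummary, alpha = config$alpha,
                        trendAlpha = config$trendAlpha)
    perA <- do.call(rbind, lapply(names(summaries), function(g) {
      cbind(group = g, perAnalyte(summaries[[g]]))
    }))
    totals <- do.call(rbind, lapply(summaries, summaryTotals))
    emit(perA, "summary_per_analyte")
    emit(totals, "summary_totals")

    stage <- "hubs"
    hubs <- hubReport(networks, hubs = config$hubs)
    emit(hubs, "hub_report")
    emit(formatHubReport(hubs), "hub_report_rounded")

    stage <- "compare"
    cmp <- config$comparisons
    if (is.null(cmp)) cmp <- .defaultComparisons(names(networks))
    cmpRows <- list()
    for (pair in cmp) {
      if (!all(pair %in% names(summaries))) {
        warning("comparison ", paste(pair, collapse = " vs "),
                " skipped: group missing", call. = FALSE)
        next
      }
      pa <- lapply(pair, function(g) perAnalyte(summaries[[g]]))
      for (param in c("sigma", "nPos", "nNeg")) {
        va <- stats::setNames(pa[[1L]][[param]], pa[[1L]]$analyte)
        vb <- stats::setNames(pa[[2L]][[param]], pa[[2L]]$analyte)
        res <- suppressWarnings(compareNetworkParams(va, vb))
        cmpRows[[length(cmpRows) + 1L]] <- data.frame(
          parameter = param, groupA = pair[1L], groupB = pair[2L],
          statistic = res@statistic, nEffective = res@nEffective,
          p = res@p, method = res@method, stringsAsFactors = FALSE)
      }
    }
    comparisons <- if (length(cmpRows)) do.call(rbind, cmpRows) else NULL
    if (!is.null(comparisons)) emit(comparisons, "comparisons_wilcoxon")

    stage <- "anova"
    anovaTab <- tukeyTab <- NULL
    stressors <- vapply(cohorts, groupStressor, character(1L))
    states <- vapply(cohorts, groupState, character(1L))
    if (length(unique(stressors)) >= 2L && length(unique(states)) >= 2L) {
      long <- do.call(rbind, lapply(cohorts, function(co) {
        v <- concentrations(co)
        data.frame(group = cohortGroup(co), stressor = groupStressor(co),
                   state = groupState(co),
                   analyte = rep(colnames(v), each = nrow(v)),
                   value = as.vector(v), stringsAsFactors = FALSE)
      }))
      anovaTab <- do.call(rbind, lapply(split(long, long$analyte),
        function(d) {
          cbind(analyte = d$analyte[1L],
                twoWayAnova(d$value, d$stressor, d$state))
        }))
      tukeyTab <- do.call(rbind, lapply(split(long, long$analyte),
        function(d) {
          cbind(analyte = d$analyte[1L], tukeyHsd(d$value, d$group))
        }))
      rownames(anovaTab) <- rownames(tukeyTab) <- NULL
      emit(anovaTab, "anova_two_way")
      emit(tukeyTab, "tukey_contrasts")
    } else {
      note("ANOVA skipped: need both factors to vary across cohorts")
    }

    stage <- "manifest"
    manifest <- list(
      package = "aminonet",
      version = as.character(utils::packageVersion("aminonet")),
      seed = config$seed, alpha = config$alpha,
      trendAlpha = config$trendAlpha, hubs = config$hubs,
      format = config$format,
      input = if (is.null(config$input)) "synthetic" else config$input,
      groups = names(networks), outputs = basename(written))
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, manifestPath)
    logPath <- file.path(config$outDir, "run.log")
    writeLines(logLines, logPath)
    written <- c(written, logPath)

    list(cohorts = cohorts, networks = networks, summaries = summaries,
         hubReport = hubs, comparisons = comparisons, anova = anovaTab,
         tukey = tukeyTab, paths = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
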