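# Inferential machinery: exact Wilcoxon signed-rank, two-way Type II ANOVA,
# Tukey-Kramer post-hoc contrasts.

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences \code{a - b} are formed, zero differences removed (Wilcoxon's
#' original treatment; \code{zeroPolicy = "pratt"} ranks zeros first and then
#' discards their ranks), and absolute differences ranked with midranks for
#' ties. The reported statistic is the smaller of the two one-sided rank
#' sums. The p-value is two-sided and exact - computed from the full
#' distribution of the rank sum over all 2^n sign assignments (a convolution
#' over the realized midranks, so ties are handled exactly) - whenever the
#' effective sample size is at most \code{exactLimit}; beyond that a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @param exactLimit Largest effective n for the exact distribution
#'   (default 20).
#' @param zeroPolicy \code{"drop"} (default) or \code{"pratt"}.
#' @return A \linkS4class{WilcoxonResult}. When all differences are zero the
#'   result is degenerate (p = 1, statistic 0) with a warning.
#' @examples
#' res <- wilcoxonSignedRank(1:6, rep(0, 6))
#' res@p  # 2/64
#' @export
wilcoxonSignedRank <- function(a, b, exactLimit = 20L,
                               zeroPolicy = c("drop", "pratt")) {
  zeroPolicy <- match.arg(zeroPolicy)
  .assertNumericVector(a, "a", 3L)
  .assertNumericVector(b, "b", 3L)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have equal length", call. = FALSE)
  }
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate result",
            call. = FALSE)
    return(new("WilcoxonResult", statistic = 0, nEffective = 0L, p = 1,
               method = "exact"))
  }
  if (zeroPolicy == "drop") {
    d <- d[d != 0]
    rk <- rank(abs(d))
  } else {
    rkAll <- rank(abs(d))
    rk <- rkAll[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  wPlus <- sum(rk[d > 0])
  wMinus <- sum(rk[d < 0])
  stat <- min(wPlus, wMinus)
  if (n <= exactLimit) {
    p <- .wilcoxExactP(rk, wPlus)
    method <- "exact"
  } else {
    p <- .wilcoxNormalP(d, rk, wPlus)
    method <- "normal_approx"
  }
  new("WilcoxonResult", statistic = stat, nEffective = as.integer(n),
      p = .clampP(p), method = method)
}

# exact two-sided p over all 2^n sign assignments of the realized ranks;
# midranks are half-integers, so work on doubled integer rank values and
# convolve the count polynomial
.wilcoxExactP <- function(rk, wPlus) {
  vals <- as.integer(round(2 * rk))
  total <- sum(vals)
  cnt <- numeric(total + 1L)   # index s+1 holds count of assignments W+ = s/2
  cnt[1L] <- 1
  for (v in vals) {
    shifted <- c(rep(0, v), cnt[seq_len(total + 1L - v)])
    cnt <- cnt + shifted
  }
  nAssign <- 2^length(vals)
  obs <- as.integer(round(2 * wPlus))
  pLe <- sum(cnt[seq_len(obs + 1L)]) / nAssign
  pGe <- sum(cnt[seq.int(obs + 1L, total + 1L)]) / nAssign
  min(1, 2 * min(pLe, pGe))
}

# tie-corrected normal approximation with continuity correction
.wilcoxNormalP <- function(d, rk, wPlus) {
  n <- length(d)
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (wPlus - mu - 0.5 * sign(wPlus - mu)) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Compare paired network parameters between two groups
#'
#' Pairs two per-analyte parameter vectors (e.g. the per-analyte sigma, mean,
#' or signed-count columns of two group summaries, or two hub coefficient
#' columns) by analyte name and applies \code{\link{wilcoxonSignedRank}}.
#'
#' @param a,b Named numeric vectors over the same analytes.
#' @param ... Passed on to \code{\link{wilcoxonSignedRank}}.
#' @return A \linkS4class{WilcoxonResult}.
#' @export
compareNetworkParams <- function(a, b, ...) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || anyDuplicated(names(a))) {
    stop("'a' and 'b' must be named over the same analytes", call. = FALSE)
  }
  wilcoxonSignedRank(a, b[names(a)], ...)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits the full two-factor cell-means model
#' \code{values ~ stressor * pregnancy} and reports Type II sums of squares
#' (each main effect adjusted for the other; interaction last), suited to the
#' unbalanced group sizes of cohort designs. Every cell of the factor cross
#' must be occupied by at least two observations.
#'
#' @param values Numeric response vector.
#' @param stressor,pregnancy Factors (coerced) of the same length, each with
#'   at least two levels.
#' @return A \code{data.frame} with rows \code{stressor}, \code{pregnancy},
#'   \code{interaction}, \code{residual} and columns \code{effect},
#'   \code{ss}, \code{df}, \code{F}, \code{p}.
#' @export
twoWayAnova <- function(values, stressor, pregnancy) {
  .assertNumericVector(values, "values", 4L)
  stressor <- factor(stressor)
  pregnancy <- factor(pregnancy)
  if (length(stressor) != length(values) ||
      length(pregnancy) != length(values)) {
    stop("factor lengths must match 'values'", call. = FALSE)
  }
  if (nlevels(stressor) < 2L || nlevels(pregnancy) < 2L) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  cells <- table(stressor, pregnancy)
  if (any(cells == 0L)) {
    stop("empty factor cell(s); missing-cell designs are not supported",
         call. = FALSE)
  }
  if (any(cells == 1L)) {
    stop("every cell needs at least two observations", call. = FALSE)
  }
  fit <- stats::lm(values ~ stressor * pregnancy)
  if (stats::sd(values) == 0) {
    # degenerate: no variation at all; all F = 0, p = 1
    tab <- data.frame(
      effect = c("stressor", "pregnancy", "interaction", "residual"),
      ss = 0, df = c(nlevels(stressor) - 1L, nlevels(pregnancy) - 1L,
                     (nlevels(stressor) - 1L) * (nlevels(pregnancy) - 1L),
                     length(values) - nlevels(stressor) * nlevels(pregnancy)),
      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA), stringsAsFactors = FALSE)
    return(tab)
  }
  rssOf <- function(form) sum(stats::residuals(stats::lm(form))^2)
  rssFull <- rssOf(values ~ stressor * pregnancy)
  dfs <- c(nlevels(stressor) - 1L, nlevels(pregnancy) - 1L,
           (nlevels(stressor) - 1L) * (nlevels(pregnancy) - 1L),
           length(values) - nlevels(stressor) * nlevels(pregnancy))
  if (rssFull < .Machine$double.eps * sum(values^2)) {
    # perfect fit: Type II SS by model comparison; F degenerates to Inf
    rssBoth <- rssOf(values ~ stressor + pregnancy)
    ss <- c(rssOf(values ~ pregnancy) - rssBoth,
            rssOf(values ~ stressor) - rssBoth,
            rssBoth - rssFull, rssFull)
    return(data.frame(
      effect = c("stressor", "pregnancy", "interaction", "residual"),
      ss = ss, df = dfs,
      F = c(ifelse(ss[1:3] > 0, Inf, 0), NA),
      p = c(.clampP(ifelse(ss[1:3] > 0, 0, 1)), NA),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  a2 <- car::Anova(fit, type = "II")
  rows <- c("stressor", "pregnancy", "stressor:pregnancy", "Residuals")
  idx <- match(rows, rownames(a2))
  data.frame(
    effect = c("stressor", "pregnancy", "interaction", "residual"),
    ss = a2[idx, "Sum Sq"],
    df = a2[idx, "Df"],
    F = a2[idx, "F value"],
    p = a2[idx, "Pr(>F)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tukey-Kramer post-hoc contrasts for a one-way layout
#'
#' All pairwise group contrasts with studentized-range adjusted p-values,
#' using the Tukey-Kramer standard error for unequal group sizes and the
#' residual degrees of freedom of the one-way layout.
#'
#' @param values Numeric response vector.
#' @param group Factor (coerced) of group membership; every group needs at
#'   least two observations.
#' @return A \code{data.frame} with one row per pair: \code{group1},
#'   \code{group2}, \code{diff} (mean of group2 minus group1), \code{q}
#'   (studentized-range statistic) and \code{pAdj}.
#' @export
tukeyHsd <- function(values, group) {
  .assertNumericVector(values, "values", 4L)
  group <- factor(group)
  if (length(group) != length(values)) {
    stop("'group' must match 'values' in length", call. = FALSE)
  }
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2L)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  k <- nlevels(group)
  means <- tapply(values, group, mean)
  dfRes <- length(values) - k
  mse <- sum(tapply(values, group,
                    function(v) sum((v - mean(v))^2))) / dfRes
  pairs <- utils::combn(levels(group), 2L)
  diff <- means[pairs[2L, ]] - means[pairs[1L, ]]
  se <- sqrt(mse / 2 * (1 / sizes[pairs[1L, ]] + 1 / sizes[pairs[2L, ]]))
  q <- ifelse(se == 0, ifelse(diff == 0, 0, Inf), abs(diff) / se)
  pAdj <- ifelse(is.infinite(q), 0,
                 stats::ptukey(q, nmeans = k, df = dfRes,
                               lower.tail = FALSE))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             diff = as.numeric(diff), q = as.numeric(q),
             pAdj = .clampP(as.numeric(pAdj)),
             stringsAsFactors = FALSE, row.names = NULL)
}
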