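# Heart-rate-variability endpoints from R-R interval series.

.assertRR <- function(rr, minLength = 1L) {
  .assertNumericVector(rr, "rr", minLength)
  if (any(rr <= 0)) {
    stop("R-R intervals must be positive (milliseconds)", call. = FALSE)
  }
  invisible(rr)
}

#' Mean R-R interval
#'
#' @param rr Numeric vector of time-ordered R-R intervals in milliseconds.
#' @return Arithmetic mean, ms.
#' @export
meanRR <- function(rr) {
  .assertRR(rr, 1L)
  mean(rr)
}

#' RMSSD: root mean square of successive differences
#'
#' The parasympathetic (relaxation) index: the root of the mean squared
#' difference between adjacent R-R intervals.
#'
#' @param rr Numeric vector of R-R intervals, ms; length >= 2.
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(100, 110, 100))  # 10
#' @export
rmssd <- function(rr) {
  .assertRR(rr, 2L)
  sqrt(mean(diff(rr)^2))
}

#' Baevsky stress index
#'
#' The sympathetic (stress) index \code{SI = AMo / (2 * Mo * MxDMn)}, where
#' AMo is the relative frequency (percent) of the modal histogram bin, Mo the
#' midpoint of that bin in seconds, and MxDMn the full range of the intervals
#' in seconds. The histogram uses fixed bins of width \code{binMs} anchored
#' at 0; a tie between bins is broken toward the lowest bin.
#'
#' @param rr Numeric vector of R-R intervals, ms; length >= 20 with a
#'   positive range.
#' @param binMs Histogram bin width in ms (default 50, the conventional
#'   value).
#' @return The stress index (percent per second squared).
#' @export
baevskySI <- function(rr, binMs = 50) {
  .assertRR(rr, 20L)
  if (max(rr) == min(rr)) {
    stop("degenerate input: zero range, stress index undefined",
         call. = FALSE)
  }
  if (binMs <= 0) stop("'binMs' must be positive", call. = FALSE)
  idx <- floor(rr / binMs)        # bin k covers [k*binMs, (k+1)*binMs)
  counts <- table(idx)
  modal <- as.integer(names(counts)[which.max(counts)])  # lowest bin on tie
  aMo <- 100 * max(counts) / length(rr)
  mo <- (modal + 0.5) * binMs / 1000
  mxdmn <- (max(rr) - min(rr)) / 1000
  aMo / (2 * mo * mxdmn)
}

#' All HRV indices of one series
#'
#' @param rr Numeric vector of R-R intervals, ms.
#' @param binMs Bin width for the stress index, ms.
#' @return A one-row \code{data.frame}: \code{meanRR}, \code{rmssd},
#'   \code{si}, \code{histogramBin}.
#' @export
hrvIndices <- function(rr, binMs = 50) {
  data.frame(meanRR = meanRR(rr), rmssd = rmssd(rr),
             si = baevskySI(rr, binMs), histogramBin = binMs)
}

#' Simulate an R-R interval series
#'
#' First-order autoregressive Gaussian series around a mean interval, with
#' stationary standard deviation \code{sd} and lag-1 autocorrelation
#' \code{autocorr}, floored at 0.2 * mean so the series stays physiologic.
#' Deterministic per seed.
#'
#' @param mean Mean interval, ms.
#' @param sd Stationary SD, ms (>= 0).
#' @param n Series length.
#' @param autocorr Lag-1 autocorrelation, in [0, 1).
#' @param seed RNG seed.
#' @return Numeric vector of n intervals, ms.
#' @export
generateRR <- function(mean, sd, n, autocorr = 0, seed = 1L) {
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (autocorr < 0 || autocorr >= 1) {
    stop("'autocorr' must lie in [0, 1)", call. = FALSE)
  }
  if (mean <= 0 || n < 1L) {
    stop("'mean' must be positive and 'n' >= 1", call. = FALSE)
  }
  .withSeed(seed, {
    z <- stats::rnorm(n)
    e <- numeric(n)
    e[1L] <- sd * z[1L]
    if (n > 1L) {
      scale <- sd * sqrt(1 - autocorr^2)
      for (t in 2:n) e[t] <- autocorr * e[t - 1L] + scale * z[t]
    }
    pmax(mean + e, 0.2 * mean)
  })
}
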