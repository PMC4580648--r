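#' Normalized cross-correlation over signed lags
#'
#' Computes, for every integer lag tau in `[-max_lag, max_lag]`,
#' \deqn{R_{xy}(\tau) = \frac{1}{N_t - 1} \sum_{t}
#'   \frac{(x(t+\tau) - \bar x)(y(t) - \bar y)}{\sigma_x \sigma_y},}
#' with the sum running over the overlapping range `t = 1 .. N_t - |tau|`
#' (no zero padding) and means/SDs computed once on the full series with
#' the `N_t - 1` denominator.
#'
#' Sign convention of the stored lag grid: positive `tau` pairs `x(t+tau)`
#' with `y(t)`, so a peak at positive `tau` means y's fluctuations precede
#' x's. [detect_peak_lag()] reports, by default, the opposite
#' ("x-leads-positive") orientation used in all user-facing tables.
#'
#' @param x,y Numeric series of equal length >= 2, neither constant.
#' @param max_lag Maximum lag in samples, `< length(x)`.
#' @param fs Sampling rate in Hz (used to express lags in ms).
#' @return An object of class `crosscorr_result` with elements `tau`
#'   (lags in samples), `lag_ms` (`tau / fs * 1000`), `values`, `fs`,
#'   `n_points`.
#' @export
cross_correlation <- function(x, y, max_lag, fs = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  if (max_lag >= n || max_lag < 0) stop("max_lag must be in [0, length - 1]")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) stop("zero-variance input: cross-correlation undefined")
  xc <- x - mean(x)
  yc <- y - mean(y)
  taus <- seq.int(-max_lag, max_lag)
  vals <- vapply(taus, function(tau) {
    if (tau >= 0) {
      sum(xc[(1 + tau):n] * yc[1:(n - tau)])
    } else {
      sum(xc[1:(n + tau)] * yc[(1 - tau):n])
    }
  }, 0) / ((n - 1) * sx * sy)
  structure(
    list(tau = taus, lag_ms = taus / fs * 1000, values = vals,
         fs = fs, n_points = n),
    class = "crosscorr_result"
  )
}

#' Point-wise average of cross-correlation curves
#'
#' Averages correlation values across trials computed on identical lag
#' grids, propagating the shared metadata.
#'
#' @param results List of `crosscorr_result` objects with identical `tau`
#'   grids and sampling rates.
#' @return A `crosscorr_result` holding the mean curve.
#' @export
average_curves <- function(results) {
  if (length(results) == 0) stop("no curves to average")
  ref <- results[[1]]
  for (r in results) {
    if (!inherits(r, "crosscorr_result")) stop("inputs must be crosscorr_result")
    if (!identical(r$tau, ref$tau) || !identical(r$fs, ref$fs)) {
      stop("mismatched lag grids: all curves must share tau and fs")
    }
  }
  out <- ref
  out$values <- rowMeans(vapply(results, `[[`, ref$values, "values"))
  out
}

#' Detect the synchronization peak lag
#'
#' Finds the lag of the maximum correlation (maximum positive value by
#' default, maximum absolute value with `use_abs = TRUE`) within
#' `[-window_s, +window_s]`. Ties are broken deterministically toward the
#' smallest `|lag|`, then toward the more negative internal lag.
#'
#' Conventions: `"x_leads"` (default, used in all user-facing tables)
#' reports a positive lag when x's fluctuations precede y's;
#' `"y_leads"` reports the raw grid orientation of
#' [cross_correlation()] (positive = y precedes x), the orientation in
#' which a blindfolded-driver x yields negative lags.
#'
#' @param result A `crosscorr_result`.
#' @param window_s Half-width of the search window in seconds (default 1).
#' @param convention `"x_leads"` or `"y_leads"`.
#' @param use_abs Peak on `|R|` instead of `R` (default `FALSE`).
#' @return Signed peak lag in milliseconds.
#' @export
detect_peak_lag <- function(result, window_s = 1,
                            convention = c("x_leads", "y_leads"),
                            use_abs = FALSE) {
  stopifnot(inherits(result, "crosscorr_result"))
  convention <- match.arg(convention)
  if (window_s * result$fs > max(result$tau)) {
    stop("search window exceeds the computed lag range")
  }
  in_win <- abs(result$tau) <= window_s * result$fs
  if (!any(in_win)) stop("empty search window")
  tau <- result$tau[in_win]
  vals <- result$values[in_win]
  score <- if (use_abs) abs(vals) else vals
  best <- which(score == max(score))
  best <- best[order(abs(tau[best]), tau[best])][1]
  lag_ms <- tau[best] / result$fs * 1000
  if (convention == "x_leads") -lag_ms else lag_ms
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf(
    "<crosscorr_result> %d lags (+/- %g ms @ %g Hz), n = %d, max R = %.3f\n",
    length(x$tau), max(x$lag_ms), x$fs, x$n_points, max(x$values)
  ))
  invisible(x)
}
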