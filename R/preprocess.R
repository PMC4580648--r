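#' Remove the least-squares linear trend
#'
#' Fits a straight line (intercept + slope) to the series by ordinary least
#' squares and subtracts it, leaving a series with zero mean and zero
#' linear slope. Applying it twice equals applying it once.
#'
#' @param series Numeric vector, length >= 2.
#' @return Detrended numeric vector of the same length.
#' @export
detrend_linear <- function(series) {
  if (!is.numeric(series) || length(series) < 2) {
    stop("series must be numeric with length >= 2")
  }
  t <- seq_along(series)
  fit <- stats::.lm.fit(cbind(1, t), series)
  as.numeric(fit$residuals)
}

#' Taper a series with a full-length Hanning window
#'
#' Element-wise product with a Hanning window of the same length as the
#' series; the first and last samples become exactly zero.
#'
#' @param series Numeric vector, length >= 2.
#' @return Tapered numeric vector.
#' @export
apply_hanning <- function(series) {
  if (!is.numeric(series) || length(series) < 2) {
    stop("series must be numeric with length >= 2")
  }
  as.numeric(series * signal::hanning(length(series)))
}

#' Zero-phase FIR decimation
#'
#' Anti-alias low-pass filters with a 30th-order (by default) FIR whose
#' cutoff sits at the post-decimation Nyquist, applied zero-phase
#' (forward-backward, implemented as one pass of the squared-magnitude
#' kernel with reflection padding at the edges), then keeps every
#' `factor`-th sample starting at the first. The FIR is normalized to unit
#' DC gain, so constants pass unchanged. Note that a 30th-order FIR at
#' large decimation factors has a wide transition band: attenuation is
#' partial just above the new Nyquist and becomes strong (>40 dB) only
#' deeper into the stopband.
#'
#' @param series Numeric vector, longer than twice the filter order.
#' @param factor Integer decimation factor >= 1.
#' @param fir_order FIR filter order (default 30, i.e. 31 taps).
#' @return Numeric vector of length `ceiling(length(series) / factor)`.
#' @export
decimate_fir <- function(series, factor, fir_order = 30L) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("factor must be an integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(as.numeric(series))
  n <- length(series)
  # forward-backward FIR needs 2*fir_order samples of edge padding
  if (n <= 2L * fir_order + 1L) {
    stop(sprintf("series too short (%d samples) for a %dth-order zero-phase FIR",
                 n, fir_order))
  }
  h <- signal::fir1(fir_order, 1 / factor)
  h <- h / sum(h)                      # unit DC gain
  g <- signal::conv(h, rev(h))         # combined forward-backward kernel
  np <- length(g) - 1L
  padded <- c(2 * series[1] - series[(np + 1L):2L],
              series,
              2 * series[n] - series[(n - 1L):(n - np)])
  filtered <- stats::filter(padded, g, method = "convolution", sides = 2)
  filtered <- as.numeric(filtered[(np + 1L):(np + n)])
  filtered[seq(1L, n, by = factor)]
}

#' Condition a trial for cross-correlation
#'
#' Linear detrend followed by a full-length Hanning taper on both channels,
#' at the original sampling rate.
#'
#' @param trial A [sway_trial()].
#' @return A [sway_trial()] with conditioned channels.
#' @export
preprocess_xcorr <- function(trial) {
  stopifnot(inherits(trial, "sway_trial"))
  trial$x <- apply_hanning(detrend_linear(trial$x))
  trial$y <- apply_hanning(detrend_linear(trial$y))
  trial
}

#' Condition a trial for autoregressive modeling
#'
#' Zero-phase FIR decimation to the model rate followed by linear
#' detrending of both channels.
#'
#' @param trial A [sway_trial()].
#' @param factor Decimation factor (default 40: 200 Hz -> 5 Hz).
#' @param fir_order Anti-alias FIR order (default 30).
#' @return A [sway_trial()] at `fs / factor` Hz.
#' @export
preprocess_var <- function(trial, factor = 40L, fir_order = 30L) {
  stopifnot(inherits(trial, "sway_trial"))
  trial$x <- detrend_linear(decimate_fir(trial$x, factor, fir_order))
  trial$y <- detrend_linear(decimate_fir(trial$y, factor, fir_order))
  trial$fs <- trial$fs / factor
  trial
}
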