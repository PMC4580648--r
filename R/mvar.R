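#' Construct a bivariate autoregressive model object
#'
#' Container for a fitted (or known) bivariate AR model
#' \deqn{x(t) = \sum_i a_i x(t-i) + b_i y(t-i) + u_x(t), \quad
#'       y(t) = \sum_i c_i x(t-i) + d_i y(t-i) + u_y(t),}
#' with per-lag coefficient matrices `[[a_i, b_i], [c_i, d_i]]` and the
#' variances of the independent driving noises.
#'
#' @param coeffs List of 2x2 matrices, one per lag.
#' @param noise_var Length-2 positive vector `(var(u_x), var(u_y))`.
#' @param fs Sampling rate (Hz) of the modeled series.
#' @param residuals Optional 2-column matrix of residuals `u_x, u_y`.
#' @param aic Optional AIC value of the fit.
#' @param n_obs Optional number of observations the model was fit to.
#' @param meta Optional named list of provenance (pair, trial, axis, ...).
#' @return Object of class `ar_model`. The stationarity flag (companion
#'   spectral radius < 1) is stored, not assumed.
#' @export
ar_model <- function(coeffs, noise_var, fs = 5, residuals = NULL,
                     aic = NA_real_, n_obs = NA_integer_, meta = list()) {
  if (any(noise_var <= 0) || length(noise_var) != 2) {
    stop("noise_var must be two positive values")
  }
  rho <- spectral_radius(coeffs)
  structure(
    list(order = length(coeffs), coeffs = coeffs,
         noise_var = as.numeric(noise_var), residuals = residuals,
         fs = fs, aic = aic, n_obs = n_obs,
         spectral_radius = rho, stationary = rho < 1, meta = meta),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf(
    "<ar_model> order %d @ %g Hz | noise var (%.4g, %.4g) | radius %.3f (%s)\n",
    x$order, x$fs, x$noise_var[1], x$noise_var[2], x$spectral_radius,
    if (x$stationary) "stationary" else "NON-STATIONARY"
  ))
  invisible(x)
}

# Lagged regressor matrix for observations idx, lags 1..p of both channels.
# Column order: x(t-1), y(t-1), x(t-2), y(t-2), ...
var_regressors <- function(x, y, idx, p) {
  do.call(cbind, lapply(seq_len(p), function(i) cbind(x[idx - i], y[idx - i])))
}

#' Fit a bivariate AR model by ordinary least squares
#'
#' Estimates each channel's equation over `t = order+1 .. n` by OLS on the
#' joint lagged history of both channels, with no intercept (inputs are
#' expected detrended). Noise variances use the residual sum of squares
#' divided by `n_eff - 2*order`.
#'
#' @param x,y Numeric series of equal length `> 10 * order`, detrended.
#' @param order Number of lags (>= 1).
#' @param fs Sampling rate (Hz) recorded in the model.
#' @param meta Optional provenance list.
#' @return An [ar_model()] with residuals and AIC
#'   (`n_eff * log det(Sigma_mle) + 2 * 4 * order`).
#' @export
fit_var <- function(x, y, order = 3L, fs = 5, meta = list()) {
  order <- as.integer(order)
  if (order < 1) stop("order must be >= 1")
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= 10 * order) {
    stop(sprintf("series too short (%d) for order %d: need > %d samples",
                 n, order, 10 * order))
  }
  idx <- (order + 1L):n
  Z <- var_regressors(x, y, idx, order)
  Yr <- cbind(x[idx], y[idx])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("rank-deficient regressor matrix (collinear or degenerate inputs)")
  }
  B <- qr.coef(qz, Yr)               # (2*order) x 2; columns = equations
  resid <- Yr - Z %*% B
  n_eff <- length(idx)
  noise_var <- colSums(resid^2) / (n_eff - 2 * order)
  # row i of A_k holds equation i's coefficients on (x(t-k), y(t-k))
  coeffs <- lapply(seq_len(order), function(k) t(B[(2 * k - 1):(2 * k), ]))
  S <- crossprod(resid) / n_eff
  aic <- n_eff * log(det(S)) + 2 * 4 * order
  ar_model(coeffs, noise_var, fs = fs, residuals = resid,
           aic = aic, n_obs = n, meta = meta)
}

#' Select AR order by AIC
#'
#' Fits every order `1 .. max_order` on a common effective sample (the
#' first `max_order` observations are withheld from all candidates so the
#' criteria are comparable) and minimizes
#' `AIC(p) = n_eff * log det(Sigma_p) + 2 * 4p`, where `Sigma_p` is the
#' residual covariance and `4p` the number of estimated coefficients.
#'
#' @param x,y Numeric detrended series.
#' @param max_order Largest candidate order (default 20).
#' @return List with `order` (the argmin) and `aic` (data frame of the
#'   full criterion curve).
#' @export
select_order_aic <- function(x, y, max_order = 20L) {
  max_order <- as.integer(max_order)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= 10 * max_order) {
    stop("series too short for the requested maximum order")
  }
  idx <- (max_order + 1L):n
  Zfull <- var_regressors(x, y, idx, max_order)
  Yr <- cbind(x[idx], y[idx])
  n_eff <- length(idx)
  aic <- vapply(seq_len(max_order), function(p) {
    Z <- Zfull[, seq_len(2 * p), drop = FALSE]
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) stop("rank-deficient regressor matrix")
    resid <- Yr - Z %*% qr.coef(qz, Yr)
    S <- crossprod(resid) / n_eff
    n_eff * log(det(S)) + 2 * 4 * p
  }, 0)
  list(order = which.min(aic),
       aic = data.frame(order = seq_len(max_order), aic = aic))
}

#' Residual whiteness and independence diagnostics
#'
#' Ljung-Box portmanteau test per residual channel up to `max_lag`, plus
#' the lag-0 cross-correlation between the two residual channels with its
#' correlation test. The NCR decomposition assumes white, mutually
#' independent driving noises; these diagnostics gate that assumption.
#'
#' @param model An [ar_model()] carrying residuals.
#' @param max_lag Portmanteau lag span (default 10), `<` residual length.
#' @param alpha Significance level for the pass/fail flags (default 0.05).
#' @param fitdf Degrees of freedom already consumed by the fit, passed to
#'   [stats::Box.test()] (default 0).
#' @return List with per-channel statistics/p-values and pass flags
#'   (`pass_x`, `pass_y` for whiteness, `pass_independence` for the lag-0
#'   residual cross-correlation, `pass` for their conjunction).
#' @export
check_residual_whiteness <- function(model, max_lag = 10L, alpha = 0.05,
                                     fitdf = 0L) {
  stopifnot(inherits(model, "ar_model"))
  if (is.null(model$residuals)) stop("model carries no residuals")
  resid <- model$residuals
  if (max_lag >= nrow(resid)) stop("max_lag must be < residual length")
  bx <- Box.test(resid[, 1], lag = max_lag, type = "Ljung-Box", fitdf = fitdf)
  by <- Box.test(resid[, 2], lag = max_lag, type = "Ljung-Box", fitdf = fitdf)
  ct <- stats::cor.test(resid[, 1], resid[, 2])
  list(
    stat_x = unname(bx$statistic), p_x = bx$p.value,
    stat_y = unname(by$statistic), p_y = by$p.value,
    cross_corr0 = unname(ct$estimate), p_independence = ct$p.value,
    alpha = alpha,
    pass_x = bx$p.value > alpha,
    pass_y = by$p.value > alpha,
    pass_independence = ct$p.value > alpha,
    pass = bx$p.value > alpha && by$p.value > alpha && ct$p.value > alpha
  )
}
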