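#' Drive a fitted model with fresh white noise
#'
#' Runs the autoregressive recursion of an [ar_model()] forward from a
#' zero initial state with standard-normal driving noise (unit variance by
#' default, matching the in-silico replication procedure: the empirical
#' residuals are replaced by artificial noise), discarding a burn-in. The
#' same `(model, seed)` always yields an identical realization.
#'
#' @param model A stationary [ar_model()].
#' @param n_samples Output length after burn-in removal.
#' @param seed Integer seed.
#' @param noise_sd Length-2 driving-noise SDs (default `c(1, 1)`).
#' @param burn_in Samples discarded from the start (default 500).
#' @return Object of class `simulated_pair`: `x_sim`, `y_sim`, `noise`
#'   (the driving pair), `fs`, `seed`, `source_model`.
#' @export
simulate_from_model <- function(model, n_samples, seed, noise_sd = c(1, 1),
                                burn_in = 500L) {
  stopifnot(inherits(model, "ar_model"))
  if (!model$stationary) {
    stop(sprintf("refusing to simulate a non-stationary model (spectral radius %.4g)",
                 model$spectral_radius))
  }
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  sim <- simulate_var_series(model$coeffs, n_samples, noise_sd = noise_sd,
                             burn_in = burn_in)
  structure(
    list(x_sim = sim$series[, 1], y_sim = sim$series[, 2],
         noise = sim$noise, fs = model$fs, seed = seed,
         source_model = model),
    class = "simulated_pair"
  )
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf("<simulated_pair> %d samples @ %g Hz (seed %d)\n",
              length(x$x_sim), x$fs, x$seed))
  invisible(x)
}

#' In-silico replication of the lag analysis
#'
#' For each pair and visual-interaction condition, repeatedly drives the
#' fitted model(s) with fresh white noise, runs the cross-correlation lag
#' analysis on each simulated trial (linear detrend, Hanning taper, peak
#' detection within `+/- window_s`), and aggregates the mean lag per pair
#' and condition. When several models are supplied per cell (one per
#' behavioral trial), repetitions cycle over them.
#'
#' @param models List of records, each a list with elements `pair_id`,
#'   `condition`, and `models` (a list of one or more [ar_model()]s).
#' @param reps Repetitions per pair x condition (default 40).
#' @param trial_len Simulated trial length in model-rate samples
#'   (default 300, i.e. one 60-s trial at 5 Hz).
#' @param seed Root seed; per-repetition seeds derive deterministically.
#' @param window_s Peak search half-window in seconds (default 1).
#' @param convention Lag sign convention (see [detect_peak_lag()]).
#' @return List with `lags` (data frame: pair_id, condition, rep,
#'   peak_lag_ms) and `summary` (mean lag per pair x condition).
#' @export
run_simulation_study <- function(models, reps = 40L, trial_len = 300L,
                                 seed = 1L, window_s = 1,
                                 convention = "x_leads") {
  if (length(models) == 0) stop("no models supplied")
  rows <- vector("list", length(models) * reps)
  k <- 0L
  for (rec in models) {
    if (is.null(rec$pair_id) || is.null(rec$condition) ||
        !length(rec$models)) {
      stop("each record needs pair_id, condition and at least one model")
    }
    for (r in seq_len(reps)) {
      model <- rec$models[[(r - 1L) %% length(rec$models) + 1L]]
      k <- k + 1L
      sp <- simulate_from_model(model, trial_len,
                                seed = derive_seed(seed, k))
      x <- apply_hanning(detrend_linear(sp$x_sim))
      y <- apply_hanning(detrend_linear(sp$y_sim))
      cc <- cross_correlation(x, y, max_lag = round(window_s * model$fs),
                              fs = model$fs)
      rows[[k]] <- data.frame(
        pair_id = rec$pair_id, condition = rec$condition, rep = r,
        peak_lag_ms = detect_peak_lag(cc, window_s, convention = convention)
      )
    }
  }
  lags <- do.call(rbind, rows)
  summary <- aggregate(peak_lag_ms ~ pair_id + condition, lags, mean)
  names(summary)[names(summary) == "peak_lag_ms"] <- "mean_lag_ms"
  list(lags = lags, summary = summary)
}

#' Regress behavioral lags on simulated lags
#'
#' Ordinary least-squares regression of per-pair behavioral peak lags on
#' the corresponding simulated mean lags, with Bonferroni correction of
#' the p-values across the conditions compared (default 3: OO, BO, OB).
#'
#' @param sim_lags,behav_lags Paired numeric vectors (one value per pair).
#' @param n_comparisons Bonferroni multiplier (default 3).
#' @return A `regression_result` (see [single_regression()]) with
#'   `p_B0_corrected` and `p_B1_corrected` added.
#' @export
compare_sim_behavioral <- function(sim_lags, behav_lags, n_comparisons = 3L) {
  if (length(sim_lags) != length(behav_lags)) {
    stop("sim and behavioral lags must be paired (equal length)")
  }
  res <- single_regression(sim_lags, behav_lags)
  res$corrected <- n_comparisons
  res$p_B0_corrected <- min(1, n_comparisons * res$p_B0)
  res$p_B1_corrected <- min(1, n_comparisons * res$p_B1)
  res
}
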