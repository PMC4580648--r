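#' Specification for a synthetic dyadic sway study
#'
#' Defines the generative conditions for a full synthetic study: a stable
#' bivariate autoregression at the model rate (default 5 Hz) whose coupling
#' topology is set per visual-interaction condition, band-limited
#' upsampling to the recording rate (default 200 Hz), a random slow linear
#' trend, and additive white measurement noise. The defaults mirror a
#' 22-pair study with 4 trials per condition, 60-s trials, and visibility
#' of the partner encoded as presence of the corresponding cross-coupling
#' term.
#'
#' The `DISTANCE` factor is emulated as a multiplicative scale on the
#' coupling strength (`far_coupling_scale`, default 0.4), reflecting weaker
#' visual influence at larger separation. A blindfolded participant's
#' innovation noise is scaled by `blindfold_noise_scale` (default 1.3),
#' reflecting larger sway without vision.
#'
#' @param model_order Number of autoregressive lags (default 3).
#' @param self_strength Lag-1 self (within-person) coefficient (default 0.5).
#' @param coupling_strength Lag-1 cross (partner) coefficient for a sighted
#'   receiver at Near distance (default 0.3).
#' @param lag_profile Multiplier per lag applied to both self and cross
#'   coefficients; default geometric decay with alternating sign,
#'   `(-0.5)^(0:(model_order-1))`.
#' @param noise_sd Length-2 positive vector: innovation SD (mm) per channel
#'   at the model rate.
#' @param fs_model Model sampling rate in Hz (default 5).
#' @param upsample_factor Integer upsampling factor to the recording rate
#'   (default 40, i.e. 200 Hz).
#' @param trial_duration Trial length in seconds (default 60).
#' @param trend_slope_range Interval (mm/s) from which each channel's linear
#'   trend slope is drawn uniformly.
#' @param measurement_noise_sd SD (mm) of additive white measurement noise
#'   at the recording rate.
#' @param n_pairs Number of participant pairs (default 22).
#' @param n_trials_per_condition Trials per condition cell (default 4).
#' @param far_coupling_scale Coupling multiplier for the Far distance.
#' @param blindfold_noise_scale Innovation-SD multiplier for a blindfolded
#'   participant.
#' @param seed Root seed; all per-trial seeds derive deterministically.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(model_order = 3L,
                       self_strength = 0.5,
                       coupling_strength = 0.3,
                       lag_profile = (-0.5)^(0:(model_order - 1)),
                       noise_sd = c(1, 1),
                       fs_model = 5,
                       upsample_factor = 40L,
                       trial_duration = 60,
                       trend_slope_range = c(-0.02, 0.02),
                       measurement_noise_sd = 0.05,
                       n_pairs = 22L,
                       n_trials_per_condition = 4L,
                       far_coupling_scale = 0.4,
                       blindfold_noise_scale = 1.3,
                       seed = 1L) {
  stopifnot(model_order >= 1, length(lag_profile) == model_order)
  if (any(noise_sd <= 0) || length(noise_sd) != 2) {
    stop("noise_sd must be two positive values")
  }
  if (upsample_factor < 1 || upsample_factor != round(upsample_factor)) {
    stop("upsample_factor must be a positive integer")
  }
  if (trial_duration <= 0) stop("trial_duration must be positive")
  n_model <- trial_duration * fs_model
  if (abs(n_model - round(n_model)) > 1e-9) {
    stop("trial_duration x fs_model must give an integer sample count")
  }
  spec <- structure(
    list(
      model_order = as.integer(model_order),
      self_strength = self_strength,
      coupling_strength = coupling_strength,
      lag_profile = lag_profile,
      noise_sd = noise_sd,
      fs_model = fs_model,
      upsample_factor = as.integer(upsample_factor),
      trial_duration = trial_duration,
      trend_slope_range = trend_slope_range,
      measurement_noise_sd = measurement_noise_sd,
      n_pairs = as.integer(n_pairs),
      n_trials_per_condition = as.integer(n_trials_per_condition),
      far_coupling_scale = far_coupling_scale,
      blindfold_noise_scale = blindfold_noise_scale,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
  # every condition x distance coefficient set must be stationary up front
  for (cond in .CONDITIONS) {
    for (scale in c(1, far_coupling_scale)) {
      make_condition_coefficients(cond, self_strength,
                                  coupling_strength * scale,
                                  order = model_order,
                                  lag_profile = lag_profile)
    }
  }
  spec
}

#' Coupling topology for a visual-interaction condition
#'
#' Builds the per-lag 2x2 coefficient matrices of a bivariate
#' autoregression whose cross-coupling encodes who can see whom. A
#' participant's equation receives partner history only if that participant
#' is sighted: with both sighted (`OO`) the coupling is bidirectional and
#' symmetric; with one blindfolded (`BO`, `OB`) only the sighted partner's
#' equation keeps its cross term, so the blindfolded partner drives; with
#' both blindfolded (`BB`) the two channels are uncoupled.
#'
#' Condition letters follow the (x state, y state) order: `"BO"` means x is
#' blindfolded (and hence drives the sighted y).
#'
#' @param condition One of `"OO"`, `"BO"`, `"OB"`, `"BB"`.
#' @param self_strength,coupling_strength Lag-1 coefficient magnitudes.
#' @param order Number of lags.
#' @param lag_profile Per-lag multiplier (default geometric, alternating).
#' @return List of `order` 2x2 matrices `[[a, b], [c, d]]` where `b` couples
#'   y's history into x's equation and `c` couples x's history into y's.
#' @export
make_condition_coefficients <- function(condition, self_strength,
                                        coupling_strength, order = 3L,
                                        lag_profile = (-0.5)^(0:(order - 1))) {
  match_vocab(condition, .CONDITIONS, "condition")
  if (order < 1) stop("order must be >= 1")
  stopifnot(length(lag_profile) == order)
  coeffs <- lapply(lag_profile, function(w) {
    A <- diag(2) * self_strength * w
    g <- coupling_strength * w
    if (condition == "OO") {
      A[1, 2] <- g  # x sees y: y history enters x's equation
      A[2, 1] <- g
    } else if (condition == "BO") {
      A[2, 1] <- g  # only sighted y receives x's history
    } else if (condition == "OB") {
      A[1, 2] <- g  # only sighted x receives y's history
    }
    A
  })
  rho <- spectral_radius(coeffs)
  if (rho >= 1) {
    stop(sprintf(
      "unstable coefficient set: companion spectral radius %.4g >= 1", rho
    ))
  }
  coeffs
}

# Core recursion shared by the generator and the model simulator: drive a
# stable bivariate AR with Gaussian noise, discard the burn-in.
simulate_var_series <- function(coeffs, n, noise_sd = c(1, 1), burn_in = 500L) {
  p <- length(coeffs)
  total <- n + burn_in
  X <- matrix(0, total, 2)
  E <- cbind(rnorm(total, 0, noise_sd[1]), rnorm(total, 0, noise_sd[2]))
  for (t in (p + 1L):total) {
    acc <- E[t, ]
    for (i in seq_len(p)) acc <- acc + coeffs[[i]] %*% X[t - i, ]
    X[t, ] <- acc
  }
  list(series = X[(burn_in + 1L):total, , drop = FALSE],
       noise = E[(burn_in + 1L):total, , drop = FALSE])
}

#' Generate one synthetic sway trial
#'
#' Simulates the coupled autoregression at the model rate (with a 500-sample
#' burn-in discarded), upsamples each channel by band-limited FIR
#' interpolation to the recording rate, then adds a random linear trend and
#' white measurement noise per channel. The same `(spec, coeffs, seed)`
#' always yields a bit-identical trial.
#'
#' @param spec A [synth_spec()].
#' @param coeffs Coefficient matrices from [make_condition_coefficients()].
#' @param seed Integer seed for this trial.
#' @param noise_sd Innovation SDs, defaulting to `spec$noise_sd`.
#' @param ... Metadata passed to [sway_trial()] (`axis`, `distance`,
#'   `condition`, `pair_id`, `trial_id`).
#' @return A [sway_trial()] at `fs_model * upsample_factor` Hz.
#' @export
generate_trial <- function(spec, coeffs, seed, noise_sd = spec$noise_sd, ...) {
  stopifnot(inherits(spec, "synth_spec"))
  rho <- spectral_radius(coeffs)
  if (rho >= 1) {
    stop(sprintf("unstable coefficients (spectral radius %.4g)", rho))
  }
  n_model <- as.integer(round(spec$trial_duration * spec$fs_model))
  set.seed(seed)
  sim <- simulate_var_series(coeffs, n_model, noise_sd = noise_sd)
  up <- spec$upsample_factor
  if (up > 1) {
    x <- as.numeric(signal::interp(sim$series[, 1], up))
    y <- as.numeric(signal::interp(sim$series[, 2], up))
  } else {
    x <- sim$series[, 1]
    y <- sim$series[, 2]
  }
  fs <- spec$fs_model * up
  t_s <- (seq_along(x) - 1) / fs
  slopes <- runif(2, spec$trend_slope_range[1], spec$trend_slope_range[2])
  x <- x + slopes[1] * t_s + rnorm(length(x), 0, spec$measurement_noise_sd)
  y <- y + slopes[2] * t_s + rnorm(length(y), 0, spec$measurement_noise_sd)
  sway_trial(x, y, fs = fs, ...)
}

#' Generate a full factorial synthetic study
#'
#' Produces the complete pair x distance x condition x trial design (each
#' trial carrying one [sway_trial()] per requested axis), with per-trial
#' seeds derived deterministically from `spec$seed`. Far-distance trials use
#' coupling scaled by `spec$far_coupling_scale`; a blindfolded participant's
#' innovation SD is scaled by `spec$blindfold_noise_scale`.
#'
#' @param spec A [synth_spec()].
#' @param axes Axes to generate (default both `"AP"` and `"LR"`).
#' @return An object of class `sway_dataset`: a list with elements `trials`
#'   (list of [sway_trial()]), `spec`, and `ground_truth` (the coefficient
#'   matrices per condition x distance).
#' @export
generate_dataset <- function(spec, axes = c("AP", "LR")) {
  stopifnot(inherits(spec, "synth_spec"))
  axes <- vapply(axes, match_vocab, "", vocab = .AXES, what = "axis")
  gt <- list()
  for (dist in .DISTANCES) {
    scale <- if (dist == "Near") 1 else spec$far_coupling_scale
    for (cond in .CONDITIONS) {
      gt[[paste(dist, cond, sep = ".")]] <- make_condition_coefficients(
        cond, spec$self_strength, spec$coupling_strength * scale,
        order = spec$model_order, lag_profile = spec$lag_profile
      )
    }
  }
  trials <- list()
  idx <- 0L
  for (pair in seq_len(spec$n_pairs)) {
    for (dist in .DISTANCES) {
      for (cond in .CONDITIONS) {
        # blindfolded participant sways more: scale that channel's noise
        nsd <- spec$noise_sd
        states <- strsplit(cond, "")[[1]]
        nsd[states == "B"] <- nsd[states == "B"] * spec$blindfold_noise_scale
        for (tr in seq_len(spec$n_trials_per_condition)) {
          idx <- idx + 1L
          for (ax in axes) {
            seed <- derive_seed(spec$seed,
                                idx * length(.AXES) + match(ax, .AXES))
            trials[[length(trials) + 1L]] <- generate_trial(
              spec, gt[[paste(dist, cond, sep = ".")]], seed,
              noise_sd = nsd, axis = ax, distance = dist,
              condition = cond, pair_id = pair, trial_id = tr
            )
          }
        }
      }
    }
  }
  structure(list(trials = trials, spec = spec, ground_truth = gt),
            class = "sway_dataset")
}

#' Number of design trials in a dataset
#'
#' Counts unique pair x distance x condition x trial cells (axes within a
#' trial count once).
#'
#' @param dataset A `sway_dataset`.
#' @return Integer count.
#' @export
n_trials <- function(dataset) {
  stopifnot(inherits(dataset, "sway_dataset"))
  keys <- vapply(dataset$trials, function(tr) {
    paste(tr$pair_id, tr$distance, tr$condition, tr$trial_id, sep = "|")
  }, "")
  length(unique(keys))
}

#' @export
print.sway_dataset <- function(x, ...) {
  cat(sprintf("<sway_dataset> %d trials (%d series) from %d pairs\n",
              n_trials(x), length(x$trials), x$spec$n_pairs))
  invisible(x)
}
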