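# Shared fixtures, all generated in code.

# Independent white-noise dyad at a given length.
white_dyad <- function(n, seed) {
  set.seed(seed)
  list(x = rnorm(n), y = rnorm(n))
}

# Small synthetic study spec used by pipeline-level tests.
tiny_spec <- function(seed = 7, n_pairs = 3, n_trials = 2, ...) {
  synth_spec(n_pairs = n_pairs, n_trials_per_condition = n_trials,
             seed = seed, ...)
}

# Known stable bivariate AR(3) with bidirectional symmetric coupling,
# the default generator topology at Near distance.
oo_coeffs <- function(self = 0.5, coupling = 0.3, order = 3) {
  make_condition_coefficients("OO", self, coupling, order = order)
}

# Model-rate dyad simulated from given coefficients, unit noise.
model_dyad <- function(coeffs, n, seed, noise_sd = c(1, 1)) {
  m <- ar_model(coeffs, noise_var = noise_sd^2, fs = 5)
  sp <- simulate_from_model(m, n, seed = seed, noise_sd = noise_sd)
  list(x = sp$x_sim, y = sp$y_sim)
}

# Mean absolute error between fitted and true coefficient matrices.
coeff_mae <- function(fit, truth) {
  mean(abs(unlist(fit$coeffs) - unlist(truth)))
}

# Balanced participant-level integrated-NCR table for ANOVA tests.
null_ncr_table <- function(n_participants = 44, seed = 1, values = NULL) {
  grid <- expand.grid(sender = c("Open", "Blindfold"),
                      receiver = c("Open", "Blindfold"),
                      distance = c("Near", "Far"),
                      participant = seq_len(n_participants),
                      stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(seed)
    values <- rnorm(nrow(grid))
  }
  grid$sum_ncr <- values
  grid
}
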