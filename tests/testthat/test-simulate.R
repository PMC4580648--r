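test_that("a zero-coefficient model reproduces its driving noise", {
  m <- ar_model(list(matrix(0, 2, 2)), c(1, 1), fs = 5)
  sp <- simulate_from_model(m, 5000, seed = 41)
  expect_equal(sp$x_sim, sp$noise[, 1])
  expect_equal(var(sp$x_sim), 1, tolerance = 0.05)
  expect_equal(var(sp$y_sim), 1, tolerance = 0.05)
})

test_that("simulation is deterministic in (model, seed)", {
  m <- ar_model(oo_coeffs(), c(1, 1), fs = 5)
  a <- simulate_from_model(m, 500, seed = 42)
  b <- simulate_from_model(m, 500, seed = 42)
  expect_identical(a$x_sim, b$x_sim)
  expect_false(identical(a$x_sim, simulate_from_model(m, 500, seed = 43)$x_sim))
})

test_that("unstable models are refused with the computed radius", {
  A <- matrix(c(0.7, 0.4, 0.4, 0.7), 2, 2)  # radius 1.1
  m <- ar_model(list(A), c(1, 1), fs = 5)
  expect_error(simulate_from_model(m, 100, seed = 1), "1.1")
})

test_that("simulate-then-refit recovers the source model", {
  coeffs <- oo_coeffs()
  m <- ar_model(coeffs, c(1, 1), fs = 5)
  sp <- simulate_from_model(m, 10000, seed = 44)
  fit <- fit_var(sp$x_sim, sp$y_sim, order = 3)
  expect_lt(coeff_mae(fit, coeffs), 0.05)
})

test_that("the simulation study aggregates lags per pair and condition", {
  mk <- function(cond) ar_model(make_condition_coefficients(cond, 0.5, 0.4),
                                c(1, 1), fs = 5)
  recs <- list(
    list(pair_id = 1, condition = "OO", models = list(mk("OO"), mk("OO"))),
    list(pair_id = 1, condition = "BO", models = list(mk("BO"))),
    list(pair_id = 1, condition = "OB", models = list(mk("OB")))
  )
  study <- run_simulation_study(recs, reps = 6, trial_len = 300, seed = 45)
  expect_equal(nrow(study$lags), 18)
  expect_equal(nrow(study$summary), 3)
  expect_true(all(abs(study$lags$peak_lag_ms) <= 1000))
  # reruns with the same root seed are identical
  again <- run_simulation_study(recs, reps = 6, trial_len = 300, seed = 45)
  expect_identical(study$lags, again$lags)
})

test_that("simulated condition ordering matches the coupling direction", {
  # under the y-leads (driver-precedes-negative-for-x) orientation the
  # blindfolded-x condition BO lies below 0 and OB above, OO near 0
  mk <- function(cond) ar_model(make_condition_coefficients(cond, 0.5, 0.4),
                                c(1, 1), fs = 5)
  recs <- lapply(1:6, function(p) list(pair_id = p, condition = "BO",
                                       models = list(mk("BO"))))
  recs <- c(recs, lapply(1:6, function(p) list(pair_id = p, condition = "OB",
                                               models = list(mk("OB")))))
  recs <- c(recs, lapply(1:6, function(p) list(pair_id = p, condition = "OO",
                                               models = list(mk("OO")))))
  study <- run_simulation_study(recs, reps = 10, trial_len = 300, seed = 46,
                                convention = "y_leads")
  means <- tapply(study$summary$mean_lag_ms, study$summary$condition, mean)
  expect_lt(means[["BO"]], 0)
  expect_gt(means[["OB"]], 0)
  expect_lt(means[["BO"]], means[["OO"]])
  expect_gt(means[["OB"]], means[["OO"]])
  expect_lt(abs(means[["OO"]]), abs(means[["OB"]]))
})

test_that("behavioral-vs-simulated regression behaves at the extremes", {
  set.seed(47)
  sim <- rnorm(22, 0, 100)
  res <- compare_sim_behavioral(sim, sim)
  expect_equal(res$B1, 1, tolerance = 1e-12)
  expect_equal(res$B0, 0, tolerance = 1e-9)
  expect_equal(max(abs(res$residuals)), 0, tolerance = 1e-9)
  expect_equal(res$p_B1_corrected, min(1, 3 * res$p_B1))

  # shuffling destroys the association almost always
  behav <- sim * 1.2 + rnorm(22, 0, 20)
  rejections <- vapply(1:100, function(s) {
    set.seed(600 + s)
    compare_sim_behavioral(sim, sample(behav))$p_B1 < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.1)
  expect_error(compare_sim_behavioral(1:5, 1:4), "paired")
})
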