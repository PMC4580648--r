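test_that("condition topologies encode who sees whom", {
  # both blindfolded: no coupling at all
  bb <- make_condition_coefficients("BB", 0.5, 0.3, order = 1)
  expect_equal(bb[[1]], matrix(c(0.5, 0, 0, 0.5), 2, 2))

  # both sighted: symmetric bidirectional coupling
  oo <- make_condition_coefficients("OO", 0.5, 0.3, order = 1)
  expect_equal(oo[[1]], matrix(c(0.5, 0.3, 0.3, 0.5), 2, 2))
  # oracle: eigenvalues of the symmetric 2x2 are self +/- coupling
  expect_equal(spectral_radius(oo), 0.8)

  # one blindfolded: only the sighted partner's equation keeps cross terms
  bo <- make_condition_coefficients("BO", 0.5, 0.3, order = 3)
  ob <- make_condition_coefficients("OB", 0.5, 0.3, order = 3)
  for (k in 1:3) {
    expect_identical(bo[[k]][1, 2], 0)      # x blindfolded: no y history
    expect_true(bo[[k]][2, 1] != 0)          # sighted y driven by x
    expect_identical(ob[[k]][2, 1], 0)
    expect_true(ob[[k]][1, 2] != 0)
  }
})

test_that("unstable coefficient requests are rejected with the radius", {
  # oracle: eigenvalues 0.7 +/- 0.4, radius 1.1
  expect_error(make_condition_coefficients("OO", 0.7, 0.4, order = 1), "1.1")
  expect_error(synth_spec(self_strength = 0.9, coupling_strength = 0.4,
                          model_order = 1, lag_profile = 1),
               "radius")
})

test_that("trial generation is seed-deterministic with the documented length", {
  spec <- tiny_spec()
  coeffs <- oo_coeffs()
  a <- generate_trial(spec, coeffs, seed = 42)
  b <- generate_trial(spec, coeffs, seed = 42)
  c <- generate_trial(spec, coeffs, seed = 43)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_false(identical(a$x, c$x))
  # 60 s at 5 Hz model rate upsampled x40 -> 12000 samples at 200 Hz
  expect_length(a$x, 12000)
  expect_equal(a$fs, 200)
})

test_that("the factorial design is complete and reproducible", {
  spec <- tiny_spec(n_pairs = 2, n_trials = 2)
  ds1 <- generate_dataset(spec, axes = "AP")
  expect_equal(n_trials(ds1), 2 * 2 * 4 * 2)
  expect_length(ds1$trials, 2 * 2 * 4 * 2)
  # all emitted ground-truth sets are stationary
  for (gt in ds1$ground_truth) expect_lt(spectral_radius(gt), 1)
  # regeneration from the same spec is bit-identical
  ds2 <- generate_dataset(spec, axes = "AP")
  expect_identical(lapply(ds1$trials, `[[`, "x"),
                   lapply(ds2$trials, `[[`, "x"))
})

test_that("long trend-free simulations recover the generating coefficients", {
  coeffs <- oo_coeffs()
  d <- model_dyad(coeffs, 10000, seed = 5)
  fit <- fit_var(d$x, d$y, order = 3)
  expect_lt(coeff_mae(fit, coeffs), 0.05)
})

test_that("datasets round-trip through the CSV layout", {
  spec <- tiny_spec(n_pairs = 2, n_trials = 1, trial_duration = 10)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_sway_dataset(ds, dir)
  back <- read_sway_dataset(dir)
  expect_length(back$trials, length(ds$trials))
  key <- function(tr) paste(tr$pair_id, tr$axis, tr$distance, tr$condition,
                            tr$trial_id)
  ord <- match(vapply(ds$trials, key, ""), vapply(back$trials, key, ""))
  expect_false(anyNA(ord))
  for (i in seq_along(ds$trials)) {
    expect_equal(back$trials[[ord[i]]]$x, ds$trials[[i]]$x, tolerance = 1e-12)
    expect_equal(back$trials[[ord[i]]]$y, ds$trials[[i]]$y, tolerance = 1e-12)
  }
  # ground truth survives the manifest
  expect_equal(back$ground_truth[["Near.OO"]], ds$ground_truth[["Near.OO"]],
               tolerance = 1e-12)
})
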