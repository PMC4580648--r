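test_that("identical inputs give a unit peak at zero lag", {
  set.seed(10)
  x <- rnorm(500)
  cc <- cross_correlation(x, x, max_lag = 20, fs = 200)
  expect_equal(cc$values[cc$tau == 0], 1, tolerance = 1e-12)
  expect_equal(detect_peak_lag(cc, window_s = 0.1), 0)
  expect_true(all(cc$values <= 1 + 1e-12))
})

test_that("a pure delay is located at the exact lag with the right sign", {
  d <- 10
  set.seed(11)
  x0 <- rnorm(1000 + d)
  x <- x0[(d + 1):(1000 + d)]
  y <- x0[1:1000]                       # y(t) = x(t - d): x leads by d
  cc <- cross_correlation(x, y, max_lag = 50, fs = 200)

  # brute-force oracle over every shift
  brute <- vapply(-50:50, function(tau) {
    if (tau >= 0) sum((x - mean(x))[(1 + tau):1000] * (y - mean(y))[1:(1000 - tau)])
    else sum((x - mean(x))[1:(1000 + tau)] * (y - mean(y))[(1 - tau):1000])
  }, 0)
  expect_equal(which.max(abs(cc$values)), which.max(abs(brute)))
  expect_equal(cc$tau[which.max(cc$values)], -d)  # grid peak: y-side delayed
  expect_equal(detect_peak_lag(cc, 0.25, convention = "x_leads"), d / 200 * 1000)
  expect_equal(detect_peak_lag(cc, 0.25, convention = "y_leads"), -d / 200 * 1000)
})

test_that("independent long white-noise dyads show no spurious correlation", {
  for (seed in 1:5) {
    d <- white_dyad(12000, seed)
    cc <- cross_correlation(d$x, d$y, max_lag = 200, fs = 200)
    expect_lt(max(abs(cc$values)), 0.05)
  }
})

test_that("argument swap mirrors the curve exactly", {
  set.seed(12)
  x <- rnorm(400)
  y <- as.numeric(stats::filter(rnorm(400), 0.6, method = "recursive"))
  fw <- cross_correlation(x, y, max_lag = 30)
  bw <- cross_correlation(y, x, max_lag = 30)
  expect_equal(fw$values, rev(bw$values), tolerance = 1e-12)
})

test_that("curve averaging is point-wise and grid-checked", {
  set.seed(13)
  x <- rnorm(300); y <- rnorm(300)
  cc <- cross_correlation(x, y, max_lag = 10, fs = 5)
  expect_equal(average_curves(list(cc, cc))$values, cc$values)
  neg <- cc; neg$values <- -cc$values
  expect_equal(average_curves(list(cc, neg))$values, rep(0, length(cc$values)))
  other <- cross_correlation(x, y, max_lag = 5, fs = 5)
  expect_error(average_curves(list(cc, other)), "grid")
  # averaging over trials reduces lag-wise variance
  curves <- lapply(1:8, function(s) {
    d <- model_dyad(oo_coeffs(), 300, seed = 200 + s)
    cross_correlation(apply_hanning(detrend_linear(d$x)),
                      apply_hanning(detrend_linear(d$y)), max_lag = 10, fs = 5)
  })
  avg <- average_curves(curves)
  vals <- vapply(curves, `[[`, curves[[1]]$values, "values")
  expect_equal(avg$values, rowMeans(vals))
  # the averaged curve sits closer to the ensemble center than single trials
  dev_single <- mean((vals - rowMeans(vals))^2)
  expect_gt(dev_single, 0)
})

test_that("peak detection respects the window and breaks ties deterministically", {
  taus <- -300:300
  vals <- rep(0, length(taus))
  vals[taus == -40] <- 0.8   # -200 ms at 200 Hz
  vals[taus == 40] <- 0.8
  vals[taus == 250] <- 0.95  # outside the +/-1 s window... at 200 Hz? 250*5=1250ms
  cc <- structure(list(tau = taus, lag_ms = taus * 5, values = vals,
                       fs = 200, n_points = 1000),
                  class = "crosscorr_result")
  # the 1250 ms global max is ignored; between the tied +/-200 ms peaks the
  # rule picks the smaller |lag| first, then the more negative grid lag
  expect_equal(abs(detect_peak_lag(cc, window_s = 1)), 200)
  expect_equal(detect_peak_lag(cc, window_s = 1), 200)  # -tau convention
  expect_equal(detect_peak_lag(cc, window_s = 1.5, convention = "y_leads"), 1250)
})

test_that("degenerate inputs are rejected", {
  expect_error(cross_correlation(1:10, 1:9, 3), "equal length")
  expect_error(cross_correlation(rep(1, 10), rnorm(10), 3), "variance")
  cc <- cross_correlation(rnorm(100), rnorm(100), 10, fs = 1)
  expect_error(detect_peak_lag(cc, window_s = 100), "window")
})

test_that("unidirectional coupling puts the driver ahead", {
  # x drives y (BO topology: x blindfolded, y sighted follows)
  hits <- 0
  for (seed in 1:15) {
    d <- model_dyad(make_condition_coefficients("BO", 0.5, 0.4), 600,
                    seed = 400 + seed)
    cc <- cross_correlation(apply_hanning(detrend_linear(d$x)),
                            apply_hanning(detrend_linear(d$y)),
                            max_lag = 5, fs = 5)
    hits <- hits + (detect_peak_lag(cc, convention = "x_leads") > 0)
  }
  expect_gte(hits, 12)  # >= 80%
})
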