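test_that("simple regression recovers exact linear relations", {
  X <- c(1, 2, 3, 4, 5)
  res <- single_regression(X, 2 * X + 1)
  expect_equal(res$B1, 2, tolerance = 1e-12)
  expect_equal(res$B0, 1, tolerance = 1e-12)
  expect_equal(max(abs(res$residuals)), 0, tolerance = 1e-10)
  expect_error(single_regression(rep(2, 5), rnorm(5)), "constant")
  expect_error(single_regression(1:2, 1:2), "3 observations")
})

test_that("lag t-tests follow the OO-anchored comparison scheme", {
  # perfectly symmetric OO lags: t = 0, p = 1
  lags <- list(OO = c(-200, -100, 100, 200),
               BO = c(-150, -50, 150, 50),
               OB = c(250, 300, 350, 400))
  out <- lag_ttests(lags)
  oo <- out[out$condition == "OO", ]
  expect_equal(oo$t, 0, tolerance = 1e-12)
  expect_equal(oo$p_raw, 1, tolerance = 1e-12)
  expect_equal(oo$comparison, "vs 0")
  # Bonferroni doubling, capped at 1
  for (cond in c("BO", "OB")) {
    row <- out[out$condition == cond, ]
    expect_equal(row$p_corrected, min(1, 2 * row$p_raw))
    expect_gte(row$p_corrected, row$p_raw)
  }
  # long-format input with trial replicates averages per pair first
  df <- data.frame(
    pair_id = rep(1:4, times = 3 * 2),
    condition = rep(c("OO", "BO", "OB"), each = 4, times = 2),
    peak_lag_ms = c(unlist(lags), unlist(lags))
  )
  expect_equal(lag_ttests(df)$t, out$t)
  expect_error(lag_ttests(lags[c("OO", "BO")]), "OB")
  expect_error(lag_ttests(list(OO = 1:4, BO = 1:3, OB = 1:4)), "paired")
})

test_that("a flat NCR table yields all-zero F statistics", {
  tab <- null_ncr_table(n_participants = 10, values = rep(5, 80))
  out <- rm_anova_ncr(tab)
  expect_equal(nrow(out), 7)
  expect_true(all(out$F == 0))
  expect_true(all(out$p == 1))
  expect_true(all(out$eta_p_sq == 0))
})

test_that("an injected receiver effect dominates and is sized correctly", {
  set.seed(51)
  tab <- null_ncr_table(n_participants = 30, seed = 51)
  tab$sum_ncr <- tab$sum_ncr + ifelse(tab$receiver == "Open", 3, 0)
  out <- rm_anova_ncr(tab)
  expect_equal(out$effect[which.max(out$F)], "RECEIVER")
  rec <- out[out$effect == "RECEIVER", ]
  expect_lt(rec$p, 1e-6)
  expect_gt(rec$eta_p_sq, 0.5)
  expect_equal(rec$df1, 1)
  expect_equal(rec$df2, 29)
})

test_that("effect partitioning is invariant to factor-label permutation", {
  set.seed(52)
  tab <- null_ncr_table(n_participants = 12, seed = 52)
  out1 <- rm_anova_ncr(tab)
  # swap the roles of sender and distance wholesale: the set of F values
  # must be unchanged, with SENDER and DISTANCE rows exchanged
  tab2 <- tab
  tab2$sender <- c(Near = "Open", Far = "Blindfold")[tab$distance]
  tab2$distance <- c(Open = "Near", Blindfold = "Far")[tab$sender]
  out2 <- rm_anova_ncr(tab2)
  expect_equal(out2$F[out2$effect == "SENDER"],
               out1$F[out1$effect == "DISTANCE"], tolerance = 1e-12)
  expect_equal(out2$F[out2$effect == "DISTANCE"],
               out1$F[out1$effect == "SENDER"], tolerance = 1e-12)
  expect_equal(sort(out2$F), sort(out1$F), tolerance = 1e-12)
  expect_error(rm_anova_ncr(tab[-1, ]), "incomplete")
})

test_that("receiver-level follow-up ANOVAs mirror the subset design", {
  set.seed(53)
  tab <- null_ncr_table(n_participants = 15, seed = 53)
  fu <- rm_anova_followup(tab)
  expect_named(fu, c("Blindfold", "Open"))
  for (block in fu) {
    expect_equal(block$effect, c("SENDER", "DISTANCE", "SENDER:DISTANCE"))
    expect_true(all(block$df2 == 14))
  }
})

test_that("variance summaries stratify by both partners' visual states", {
  set.seed(54)
  trials <- list(
    sway_trial(rnorm(1000), rnorm(1000, sd = 2), fs = 200, condition = "OB"),
    sway_trial(seq(1, 2, length.out = 1000), seq(0, 5, length.out = 1000),
               fs = 200, condition = "BB", trial_id = 2)
  )
  out <- variance_summary(trials)
  # pure lines detrend to zero variance (the BB cell holds only lines)
  bb_row <- out[out$self_state == "B" & out$partner_state == "B", ]
  expect_equal(bb_row$mean_variance, 0, tolerance = 1e-18)
  # unit white noise keeps variance near 1; sd-2 noise near 4
  ob_self_o <- out[out$self_state == "O" & out$partner_state == "B", ]
  expect_equal(ob_self_o$mean_variance, 1, tolerance = 0.15)
  ob_self_b <- out[out$self_state == "B" & out$partner_state == "O", ]
  expect_equal(ob_self_b$mean_variance, 4, tolerance = 0.6)

  # generator-level check: blindfolded participants sway more
  ds <- generate_dataset(tiny_spec(n_pairs = 2, n_trials = 1), axes = "AP")
  vs <- variance_summary(ds$trials)
  vb <- mean(vs$mean_variance[vs$self_state == "B"])
  vo <- mean(vs$mean_variance[vs$self_state == "O"])
  expect_gt(vb, vo)
})
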