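#' Simple linear regression with coefficient t-tests
#'
#' Ordinary least squares of `Y` on `X` with intercept `B0` and slope `B1`,
#' and t-tests on both coefficients with `n - 2` degrees of freedom. Used
#' for the influence-difference vs. lag analysis and the simulated vs.
#' behavioral lag comparison.
#'
#' @param X,Y Numeric vectors of equal length >= 3; `X` must not be
#'   constant.
#' @return Object of class `regression_result`: `B0`, `B1`, `t_B0`,
#'   `t_B1`, `p_B0`, `p_B1`, `n`, `residuals`, `corrected` (Bonferroni
#'   multiplier, 1 if uncorrected).
#' @export
single_regression <- function(X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length")
  n <- length(X)
  if (n < 3) stop("need at least 3 observations")
  if (sd(X) == 0) stop("X is constant: slope undefined")
  fit <- lm(Y ~ X)
  # exact fits trigger a benign "perfect fit" note from summary.lm
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(
    list(B0 = cf[1, 1], B1 = cf[2, 1],
         t_B0 = cf[1, 3], t_B1 = cf[2, 3],
         p_B0 = cf[1, 4], p_B1 = cf[2, 4],
         n = n, residuals = unname(stats::residuals(fit)), corrected = 1L),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> n = %d | B1 = %.4g (t = %.3f, p = %.4g) | B0 = %.4g (t = %.3f, p = %.4g)\n",
    x$n, x$B1, x$t_B1, x$p_B1, x$B0, x$t_B0, x$p_B0
  ))
  invisible(x)
}

#' Synchronization-lag t-tests across visual-interaction conditions
#'
#' Tests the per-pair mean peak lags: the OO condition against 0 ms with a
#' one-sample t-test (uncorrected), and the BO and OB conditions against
#' OO with paired t-tests whose p-values are Bonferroni-doubled (two
#' comparisons, capped at 1).
#'
#' @param lags_by_condition Either a data frame with columns `pair_id`,
#'   `condition`, and a lag column (`mean_lag_ms` or `peak_lag_ms`), or a
#'   named list/data frame with components `OO`, `BO`, `OB` aligned by
#'   pair.
#' @return Data frame: condition, comparison, n, mean_lag_ms, sd_lag_ms,
#'   t, df, p_raw, p_corrected.
#' @export
lag_ttests <- function(lags_by_condition) {
  lc <- lags_by_condition
  if (is.data.frame(lc) && all(c("pair_id", "condition") %in% names(lc))) {
    lag_col <- intersect(c("mean_lag_ms", "peak_lag_ms"), names(lc))[1]
    if (is.na(lag_col)) stop("no lag column found")
    agg <- aggregate(lc[[lag_col]],
                     list(pair_id = lc$pair_id, condition = lc$condition),
                     mean)
    lc <- split(agg$x[order(agg$pair_id)],
                agg$condition[order(agg$pair_id)])
  }
  for (cond in c("OO", "BO", "OB")) {
    if (is.null(lc[[cond]])) stop(sprintf("missing condition %s", cond))
  }
  if (length(unique(vapply(lc[c("OO", "BO", "OB")], length, 0L))) != 1) {
    stop("conditions must be paired: equal pair counts required")
  }
  if (length(lc$OO) < 2) stop("need at least 2 pairs")
  one <- t.test(lc$OO, mu = 0)
  rows <- list(data.frame(
    condition = "OO", comparison = "vs 0", n = length(lc$OO),
    mean_lag_ms = mean(lc$OO), sd_lag_ms = sd(lc$OO),
    t = unname(one$statistic), df = unname(one$parameter),
    p_raw = one$p.value, p_corrected = one$p.value
  ))
  for (cond in c("BO", "OB")) {
    tt <- t.test(lc[[cond]], lc$OO, paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, comparison = "vs OO (paired)", n = length(lc[[cond]]),
      mean_lag_ms = mean(lc[[cond]]), sd_lag_ms = sd(lc[[cond]]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_corrected = min(1, 2 * tt$p.value)
    )
  }
  do.call(rbind, rows)
}

# One-sample t on a per-participant contrast; returns the classical
# repeated-measures F, p and partial eta squared for a 2-level effect.
contrast_effect <- function(L, effect) {
  n <- length(L)
  m <- mean(L)
  s <- sd(L)
  if (s == 0) {
    f <- if (abs(m) < .Machine$double.eps^0.5) 0 else Inf
    p <- if (f == 0) 1 else 0
  } else {
    tstat <- m / (s / sqrt(n))
    f <- tstat^2
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  data.frame(effect = effect, df1 = 1L, df2 = n - 1L, F = f, p = p,
             eta_p_sq = if (is.infinite(f)) 1 else f / (f + (n - 1)))
}

# Per-participant cell means as a named matrix participant x cell key.
ncr_cell_means <- function(table, factors) {
  needed <- c("participant", factors, "sum_ncr")
  if (!all(needed %in% names(table))) {
    stop(sprintf("table must have columns: %s", paste(needed, collapse = ", ")))
  }
  key <- do.call(paste, c(table[factors], sep = "."))
  agg <- aggregate(table$sum_ncr, list(participant = table$participant,
                                       key = key), mean)
  cells <- sort(unique(key))
  parts <- sort(unique(agg$participant))
  M <- matrix(NA_real_, length(parts), length(cells),
              dimnames = list(as.character(parts), cells))
  M[cbind(match(agg$participant, parts), match(agg$key, cells))] <- agg$x
  if (anyNA(M)) stop("incomplete within-participant design: missing cells")
  M
}

#' Repeated-measures ANOVA on integrated NCR
#'
#' Classical three-way fully-within ANOVA of per-participant integrated
#' noise contribution ratios with two-level factors SENDER, RECEIVER and
#' DISTANCE. With one observation per cell (trial replicates are averaged
#' first), each effect's F equals the squared one-sample t of the
#' corresponding per-participant contrast, with `1, n - 1` degrees of
#' freedom; partial eta squared is `F / (F + df2)`. No sphericity
#' correction is needed for two-level factors.
#'
#' @param table Long-format data frame with columns `participant`,
#'   `sender`, `receiver`, `distance` (each factor with exactly its two
#'   levels present for every participant) and `sum_ncr`.
#' @return Data frame of class `anova_result`: one row per effect (3 main
#'   effects, 3 two-way interactions, 1 three-way) with `df1`, `df2`,
#'   `F`, `p`, `eta_p_sq`.
#' @export
rm_anova_ncr <- function(table) {
  factors <- c("sender", "receiver", "distance")
  M <- ncr_cell_means(table, factors)
  cells <- strsplit(colnames(M), ".", fixed = TRUE)
  signs <- lapply(seq_along(factors), function(i) {
    lv <- sort(unique(vapply(cells, `[[`, "", i)))
    if (length(lv) != 2) stop(sprintf("factor %s must have 2 levels", factors[i]))
    ifelse(vapply(cells, `[[`, "", i) == lv[2], 1, -1)
  })
  effects <- list(
    SENDER = signs[[1]], RECEIVER = signs[[2]], DISTANCE = signs[[3]],
    `SENDER:RECEIVER` = signs[[1]] * signs[[2]],
    `SENDER:DISTANCE` = signs[[1]] * signs[[3]],
    `RECEIVER:DISTANCE` = signs[[2]] * signs[[3]],
    `SENDER:RECEIVER:DISTANCE` = signs[[1]] * signs[[2]] * signs[[3]]
  )
  out <- do.call(rbind, lapply(names(effects), function(nm) {
    w <- effects[[nm]]
    contrast_effect(as.numeric(M %*% (w / sum(w == 1))), nm)
  }))
  class(out) <- c("anova_result", class(out))
  out
}

#' Follow-up two-way ANOVAs per RECEIVER level
#'
#' For each level of RECEIVER, runs the two-way fully-within ANOVA with
#' factors SENDER and DISTANCE on the subset, mirroring the standard
#' follow-up to a SENDER x RECEIVER or RECEIVER x DISTANCE interaction.
#'
#' @inheritParams rm_anova_ncr
#' @return Named list of `anova_result` data frames, one per receiver
#'   level.
#' @export
rm_anova_followup <- function(table) {
  out <- lapply(sort(unique(table$receiver)), function(lv) {
    sub <- table[table$receiver == lv, ]
    M <- ncr_cell_means(sub, c("sender", "distance"))
    cells <- strsplit(colnames(M), ".", fixed = TRUE)
    signs <- lapply(1:2, function(i) {
      lvs <- sort(unique(vapply(cells, `[[`, "", i)))
      ifelse(vapply(cells, `[[`, "", i) == lvs[2], 1, -1)
    })
    effects <- list(SENDER = signs[[1]], DISTANCE = signs[[2]],
                    `SENDER:DISTANCE` = signs[[1]] * signs[[2]])
    res <- do.call(rbind, lapply(names(effects), function(nm) {
      w <- effects[[nm]]
      contrast_effect(as.numeric(M %*% (w / sum(w == 1))), nm)
    }))
    class(res) <- c("anova_result", class(res))
    res
  })
  names(out) <- as.character(sort(unique(table$receiver)))
  out
}

#' Per-condition signal variance summary
#'
#' Mean variance of the detrended series, stratified by axis, distance and
#' the participant's own visual state together with the partner's state
#' (so a sighted participant facing a blindfolded partner is summarized
#' separately from one facing a sighted partner).
#'
#' @param trials List of [sway_trial()] objects (e.g. from
#'   [generate_dataset()]`$trials`).
#' @return Data frame: axis, distance, self_state, partner_state, n,
#'   mean_variance (mm^2).
#' @export
variance_summary <- function(trials) {
  if (length(trials) == 0) stop("no trials supplied")
  rows <- lapply(trials, function(tr) {
    stopifnot(inherits(tr, "sway_trial"))
    states <- strsplit(tr$condition, "")[[1]]
    data.frame(
      axis = tr$axis, distance = tr$distance,
      self_state = states, partner_state = rev(states),
      variance = c(var(detrend_linear(tr$x)), var(detrend_linear(tr$y)))
    )
  })
  long <- do.call(rbind, rows)
  out <- aggregate(variance ~ axis + distance + self_state + partner_state,
                   long, mean)
  counts <- aggregate(variance ~ axis + distance + self_state + partner_state,
                      long, length)
  out$n <- counts$variance
  names(out)[names(out) == "variance"] <- "mean_variance"
  out[order(out$axis, out$distance, out$self_state, out$partner_state), ]
}
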