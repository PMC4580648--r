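#' Write a synthetic dataset to disk
#'
#' One CSV per pair (columns `distance`, `condition`, `trial`, `time_s`,
#' then `x_<axis>`, `y_<axis>` for each axis present) plus a
#' `manifest.json` recording the generator settings and the ground-truth
#' coefficient matrices.
#'
#' @param dataset A `sway_dataset` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sway_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sway_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  axes <- sort(unique(vapply(dataset$trials, `[[`, "", "axis")))
  fs <- dataset$trials[[1]]$fs
  by_pair <- split(dataset$trials,
                   vapply(dataset$trials, function(tr) as.character(tr$pair_id), ""))
  for (pid in names(by_pair)) {
    blocks <- list()
    trs <- by_pair[[pid]]
    keys <- vapply(trs, function(tr) paste(tr$distance, tr$condition, tr$trial_id,
                                           sep = "|"), "")
    for (key in unique(keys)) {
      sub <- trs[keys == key]
      first <- sub[[1]]
      n <- length(first$x)
      block <- data.frame(
        distance = first$distance, condition = first$condition,
        trial = first$trial_id, time_s = (seq_len(n) - 1) / first$fs
      )
      for (tr in sub) {
        block[[paste0("x_", tr$axis)]] <- tr$x
        block[[paste0("y_", tr$axis)]] <- tr$y
      }
      blocks[[length(blocks) + 1L]] <- block
    }
    write.csv(do.call(rbind, blocks),
              file.path(dir, sprintf("pair_%s.csv", pid)), row.names = FALSE)
  }
  manifest <- list(
    format = "dyadsync-csv-v1",
    fs = fs,
    axes = axes,
    pairs = names(by_pair),
    spec = unclass(dataset$spec),
    ground_truth = lapply(dataset$ground_truth,
                          function(gl) lapply(gl, function(m) unclass(m)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a sway dataset
#'
#' Reads the package's documented CSV-per-pair layout (written by
#' [write_sway_dataset()], identified by its `manifest.json`). MATLAB
#' `.mat` containers are not parsed directly; convert them to the CSV
#' layout first (any MAT reader can dump the per-pair series to the
#' documented columns), which also forces an explicit, auditable mapping
#' of variables to pairs/axes/conditions instead of a guessed one.
#'
#' @param path Directory containing `manifest.json` and pair CSVs.
#' @return A `sway_dataset`.
#' @export
read_sway_dataset <- function(path) {
  if (length(path) != 1 || !nzchar(path)) stop("path must be a single string")
  if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    stop(paste(
      "MAT containers are not read directly: convert the deposited file to",
      "the documented CSV layout (one pair_<id>.csv per pair with columns",
      "distance, condition, trial, time_s, x_<axis>, y_<axis>, plus a",
      "manifest.json with fields format/fs/axes/pairs) and point to that",
      "directory instead."
    ))
  }
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path))
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop(sprintf("missing manifest.json in %s: unrecognized dataset layout", path))
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(mf$format) || mf$format != "dyadsync-csv-v1") {
    stop("unrecognized dataset format in manifest.json")
  }
  trials <- list()
  for (pid in mf$pairs) {
    f <- file.path(path, sprintf("pair_%s.csv", pid))
    if (!file.exists(f)) stop(sprintf("missing data file for pair %s: %s", pid, f))
    df <- read.csv(f)
    need <- c("distance", "condition", "trial", "time_s")
    if (!all(need %in% names(df))) {
      stop(sprintf("truncated or malformed file %s: missing column(s) %s",
                   f, paste(setdiff(need, names(df)), collapse = ", ")))
    }
    key <- paste(df$distance, df$condition, df$trial, sep = "|")
    for (k in unique(key)) {
      block <- df[key == k, ]
      for (ax in mf$axes) {
        xc <- paste0("x_", ax)
        yc <- paste0("y_", ax)
        if (!all(c(xc, yc) %in% names(df))) {
          stop(sprintf("file %s lacks expected variable %s/%s", f, xc, yc))
        }
        trials[[length(trials) + 1L]] <- sway_trial(
          block[[xc]], block[[yc]], fs = mf$fs, axis = ax,
          distance = block$distance[1], condition = block$condition[1],
          pair_id = type.convert(pid, as.is = TRUE), trial_id = block$trial[1]
        )
      }
    }
  }
  gt <- NULL
  if (!is.null(mf$ground_truth)) {
    # matrices must be rebuilt from the unsimplified JSON (row-major lists)
    raw <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
    gt <- lapply(raw$ground_truth, function(gl) lapply(gl, function(m) {
      matrix(unlist(m), 2, 2, byrow = TRUE)
    }))
  }
  spec <- mf$spec
  if (!is.null(spec)) class(spec) <- "synth_spec"
  structure(list(trials = trials, spec = spec, ground_truth = gt),
            class = "sway_dataset")
}

#' Study configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' either a [synth_spec()] (synthetic study) or an input directory
#' (recorded study in the documented CSV layout); signal conditioning and
#' analysis parameters; and the simulation settings.
#'
#' @param spec A [synth_spec()], or `NULL` when reading from `input_dir`.
#' @param input_dir Dataset directory for [read_sway_dataset()].
#' @param axes Axes to analyze.
#' @param window_s Peak-lag search half-window in seconds (default 1).
#' @param ar_order Fixed AR order for production fits (default 3).
#' @param max_ar_order Order-scan upper bound for diagnostics (default 20).
#' @param n_freqs NCR frequency-grid size (default 512).
#' @param decimation_factor Recording-to-model-rate factor (default 40).
#' @param fir_order Anti-alias FIR order (default 30).
#' @param sim_reps Simulation repetitions per pair x condition (default 40).
#' @param sim_trial_len Simulated trial length in model samples (default 300).
#' @param sim_axis,sim_distance Slice replicated in silico (default
#'   `"AP"`, `"Near"`).
#' @param seed Root seed for the simulation stage.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return Object of class `study_config`.
#' @export
study_config <- function(spec = NULL, input_dir = NULL,
                         axes = c("AP", "LR"), window_s = 1,
                         ar_order = 3L, max_ar_order = 20L,
                         n_freqs = 512L, decimation_factor = 40L,
                         fir_order = 30L, sim_reps = 40L,
                         sim_trial_len = 300L, sim_axis = "AP",
                         sim_distance = "Near", seed = 1L,
                         output_dir = NULL) {
  if (is.null(spec) && is.null(input_dir)) {
    stop("supply either a synth_spec or an input_dir")
  }
  if (!is.null(spec)) stopifnot(inherits(spec, "synth_spec"))
  axes <- vapply(axes, match_vocab, "", vocab = .AXES, what = "axis")
  match_vocab(sim_axis, .AXES, "sim_axis")
  match_vocab(sim_distance, .DISTANCES, "sim_distance")
  for (nm in c("window_s", "ar_order", "n_freqs", "decimation_factor",
               "sim_reps", "sim_trial_len")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop(sprintf("%s must be positive", nm))
  }
  structure(
    list(spec = spec, input_dir = input_dir, axes = axes,
         window_s = window_s, ar_order = as.integer(ar_order),
         max_ar_order = as.integer(max_ar_order),
         n_freqs = as.integer(n_freqs),
         decimation_factor = as.integer(decimation_factor),
         fir_order = as.integer(fir_order),
         sim_reps = as.integer(sim_reps),
         sim_trial_len = as.integer(sim_trial_len),
         sim_axis = sim_axis, sim_distance = sim_distance,
         seed = as.integer(seed), output_dir = output_dir),
    class = "study_config"
  )
}

#' Write / read a study configuration as JSON
#'
#' @param config A [study_config()].
#' @param path JSON file path.
#' @return `read_study_config` returns the reconstructed [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- unclass(config)
  out$spec <- if (!is.null(config$spec)) unclass(config$spec) else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- NULL
  if (!is.null(raw$spec)) {
    spec <- do.call(synth_spec, raw$spec[names(raw$spec) %in%
                                           names(formals(synth_spec))])
  }
  do.call(study_config, c(list(spec = spec),
                          raw[setdiff(names(raw), "spec")]))
}

# Participant-level integrated-NCR rows from a per-trial NCR table.
# Participant x of pair k gets id 2k-1, participant y id 2k. A
# participant's "received influence" in a trial is the partner-to-self
# integrated NCR; SENDER is the partner's visual state, RECEIVER their own.
participant_ncr_table <- function(ncr_rows) {
  state_name <- c(O = "Open", B = "Blindfold")
  rows <- lapply(seq_len(nrow(ncr_rows)), function(i) {
    r <- ncr_rows[i, ]
    states <- strsplit(r$condition, "")[[1]]
    pid <- as.numeric(r$pair_id)
    data.frame(
      participant = c(2 * pid - 1, 2 * pid),
      axis = r$axis, distance = r$distance, condition = r$condition,
      trial_id = r$trial_id,
      sender = state_name[c(states[2], states[1])],
      receiver = state_name[states],
      sum_ncr = c(r$sum_ncr_y_to_x, r$sum_ncr_x_to_y),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes the complete study: (1) generate or read the dataset; (2)
#' cross-correlation peak lags per trial at the recording rate (linear
#' detrend + Hanning taper, x-leads-positive sign convention); (3)
#' decimation to the model rate, per-trial bivariate AR fits at the fixed
#' order, NCR spectra and integrated NCR; (4) inference: lag t-tests per
#' axis and distance, three-way repeated-measures ANOVA (with follow-ups)
#' on participant-level integrated NCR per axis, and the per-pair
#' regression of peak lag on the integrated-NCR difference (Near, OO); (5)
#' the in-silico replication (white-noise-driven simulation of the fitted
#' models for OO/BO/OB) with simulated-vs-behavioral regressions; (6)
#' signal variance summary. Re-running an identical configuration
#' reproduces identical outputs.
#'
#' The regression orientation is fixed so the two measures are
#' co-oriented: lags are positive when participant x leads, and the
#' influence difference is `sum NCR(x->y) - sum NCR(y->x)` (influence
#' exerted minus received by x).
#'
#' @param config A [study_config()].
#' @return A result bundle (list) with elements `dataset`, `lags`,
#'   `ncr`, `participant_ncr`, `lag_tests`, `anova`, `anova_followup`,
#'   `ncr_lag_regression`, `simulation`, `sim_vs_behavioral`,
#'   `variance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dataset <- if (!is.null(config$spec)) {
    generate_dataset(config$spec, axes = config$axes)
  } else {
    read_sway_dataset(config$input_dir)
  }
  trials <- Filter(function(tr) tr$axis %in% config$axes, dataset$trials)
  if (length(trials) == 0) stop("no trials on the requested axes")

  # --- stage: cross-correlation lags (recording rate) -------------------
  lag_rows <- lapply(trials, function(tr) {
    pp <- preprocess_xcorr(tr)
    cc <- cross_correlation(pp$x, pp$y,
                            max_lag = round(config$window_s * pp$fs),
                            fs = pp$fs)
    lag <- detect_peak_lag(cc, config$window_s, convention = "x_leads")
    data.frame(pair_id = tr$pair_id, axis = tr$axis, distance = tr$distance,
               condition = tr$condition, trial_id = tr$trial_id,
               peak_lag_ms = lag, peak_value = max(cc$values))
  })
  lags <- do.call(rbind, lag_rows)

  # --- stage: AR fits and NCR (model rate) ------------------------------
  models <- lapply(trials, function(tr) {
    d <- preprocess_var(tr, config$decimation_factor, config$fir_order)
    fit_var(d$x, d$y, order = config$ar_order, fs = d$fs,
            meta = tr[c("pair_id", "axis", "distance", "condition", "trial_id")])
  })
  ncr_rows <- mapply(function(tr, m) {
    sp <- ncr_spectrum(m, n_freqs = config$n_freqs)
    data.frame(pair_id = tr$pair_id, axis = tr$axis, distance = tr$distance,
               condition = tr$condition, trial_id = tr$trial_id,
               sum_ncr_y_to_x = sp$sum_ncr_y_to_x,
               sum_ncr_x_to_y = sp$sum_ncr_x_to_y)
  }, trials, models, SIMPLIFY = FALSE)
  ncr <- do.call(rbind, ncr_rows)
  participant_ncr <- participant_ncr_table(ncr)

  # --- stage: inference -------------------------------------------------
  lag_tests <- list()
  anova <- list()
  followup <- list()
  regressions <- list()
  for (ax in config$axes) {
    for (dist in intersect(.DISTANCES, unique(lags$distance))) {
      sub <- lags[lags$axis == ax & lags$distance == dist, ]
      lag_tests[[paste(ax, dist, sep = ".")]] <- lag_ttests(sub)
    }
    ptab <- participant_ncr[participant_ncr$axis == ax, ]
    anova[[ax]] <- rm_anova_ncr(ptab)
    followup[[ax]] <- rm_anova_followup(ptab)

    # influence-difference vs lag, Near OO, co-oriented with x-leads lags
    nsub <- ncr[ncr$axis == ax & ncr$distance == "Near" & ncr$condition == "OO", ]
    lsub <- lags[lags$axis == ax & lags$distance == "Near" & lags$condition == "OO", ]
    if (nrow(nsub) > 0) {
      X <- aggregate(sum_ncr_x_to_y - sum_ncr_y_to_x ~ pair_id, nsub, mean)
      Y <- aggregate(peak_lag_ms ~ pair_id, lsub, mean)
      stopifnot(identical(X$pair_id, Y$pair_id))
      if (nrow(X) >= 3) {
        regressions[[ax]] <- single_regression(X[[2]], Y$peak_lag_ms)
      }
    }
  }

  # --- stage: in-silico replication -------------------------------------
  sim_sel <- vapply(models, function(m) {
    m$meta$axis == config$sim_axis && m$meta$distance == config$sim_distance &&
      m$meta$condition %in% c("OO", "BO", "OB")
  }, TRUE)
  sim_models <- models[sim_sel]
  simulation <- NULL
  sim_vs_behav <- list()
  if (length(sim_models) > 0) {
    key <- vapply(sim_models, function(m) paste(m$meta$pair_id, m$meta$condition,
                                                sep = "|"), "")
    recs <- lapply(unique(key), function(k) {
      grp <- sim_models[key == k]
      list(pair_id = grp[[1]]$meta$pair_id,
           condition = grp[[1]]$meta$condition, models = grp)
    })
    simulation <- run_simulation_study(
      recs, reps = config$sim_reps, trial_len = config$sim_trial_len,
      seed = config$seed, window_s = config$window_s
    )
    behav <- lags[lags$axis == config$sim_axis &
                    lags$distance == config$sim_distance, ]
    behav_mean <- aggregate(peak_lag_ms ~ pair_id + condition, behav, mean)
    for (cond in intersect(c("OO", "BO", "OB"),
                           unique(simulation$summary$condition))) {
      s <- simulation$summary[simulation$summary$condition == cond, ]
      b <- behav_mean[behav_mean$condition == cond, ]
      m <- merge(s, b, by = "pair_id")
      if (nrow(m) >= 3) {
        sim_vs_behav[[cond]] <- compare_sim_behavioral(m$mean_lag_ms,
                                                       m$peak_lag_ms)
      }
    }
  }

  variance <- variance_summary(trials)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    n_trials = n_trials(dataset), n_series = length(trials),
    axes = config$axes, seed = config$seed,
    ar_order = config$ar_order, n_freqs = config$n_freqs,
    decimation_factor = config$decimation_factor,
    sim = list(axis = config$sim_axis, distance = config$sim_distance,
               reps = config$sim_reps, trial_len = config$sim_trial_len)
  )
  bundle <- list(dataset = dataset, lags = lags, ncr = ncr,
                 participant_ncr = participant_ncr, lag_tests = lag_tests,
                 anova = anova, anova_followup = followup,
                 ncr_lag_regression = regressions, simulation = simulation,
                 sim_vs_behavioral = sim_vs_behav, variance = variance,
                 manifest = manifest)

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(lags, file.path(out, "peak_lags.csv"), row.names = FALSE)
    write.csv(ncr, file.path(out, "sum_ncr.csv"), row.names = FALSE)
    write.csv(participant_ncr, file.path(out, "participant_sum_ncr.csv"),
              row.names = FALSE)
    write.csv(variance, file.path(out, "signal_variance.csv"),
              row.names = FALSE)
    for (ax in names(anova)) {
      write.table(anova[[ax]], file.path(out, sprintf("anova_%s.tsv", ax)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(simulation)) {
      write.csv(simulation$lags, file.path(out, "simulated_lags.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
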