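#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end pipelines. The configuration is
#' validated up front and a YAML copy is written into every output directory
#' so any artifact can be reproduced from its directory alone.
#'
#' @param out_dir Output directory.
#' @param channel Target channel (`"mz"`, `"fx"`, `"fy"`).
#' @param gen A [gen_params()] for simulation.
#' @param threshold_frac,hysteresis,extend Segmentation settings, see
#'   [segment_cycles()].
#' @param rms_window RMS window, see [rms_normalize()].
#' @param pattern_length Generic-pattern length `L`.
#' @param max_poles Order-search cap per linear block.
#' @param keep Models retained by the grid search.
#' @param train_cycles Cycles used for identification training.
#' @param hw An [hw_control()].
#' @param seqreg A [seqreg_config()].
#' @param seed Master seed.
#' @return A list of class `wk_config`.
#' @export
wk_config <- function(out_dir = "wheelkin_out", channel = "mz",
                      gen = gen_params(), threshold_frac = 0.10,
                      hysteresis = 0.050, extend = 0.20,
                      rms_window = "push", pattern_length = 140L,
                      max_poles = 6L, keep = 111L, train_cycles = 15L,
                      hw = hw_control(), seqreg = seqreg_config(),
                      seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(channel %in% c("mz", "fx", "fy"),
            rms_window %in% c("push", "extended"),
            cfg$train_cycles >= 1L, cfg$keep >= 1L, cfg$max_poles >= 1L)
  structure(cfg, class = "wk_config")
}

write_config <- function(cfg, dir) {
  ser <- rapply(unclass(cfg), function(x) x, how = "replace")
  yaml::write_yaml(ser, file.path(dir, "config.yaml"))
}

#' Simulate a recording to disk
#'
#' Writes the synthetic recording (CSV pair + JSON sidecar), the ground
#' truth as JSON and the configuration as YAML into `cfg$out_dir`.
#'
#' @param cfg A [wk_config()].
#' @return Invisibly, the recording stem.
#' @export
pipeline_simulate <- function(cfg = wk_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_recording(cfg$gen)
  stem <- file.path(cfg$out_dir, "recording")
  write_recording(g$recording, stem)
  truth <- g$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(cfg$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_config(cfg, cfg$out_dir)
  message(sprintf("simulated %d cycles (seed %d) -> %s",
                  cfg$gen$n_cycles, cfg$gen$seed, stem))
  invisible(stem)
}

#' Preprocess a recording: align, segment, pattern
#'
#' Reads the recording at `stem`, detects the kick events in the force and
#' acceleration streams, aligns the kinetics to the IMU rate, segments push
#' cycles from Mz, and writes the cycle table (indices, durations, RMS
#' factors) and the generic pattern as CSV.
#'
#' @param cfg A [wk_config()].
#' @param stem Recording stem (defaults to the one [pipeline_simulate()]
#'   writes).
#' @return List with the aligned `recording`, `cycles` and `pattern`.
#' @export
pipeline_preprocess <- function(cfg = wk_config(),
                                stem = file.path(cfg$out_dir, "recording")) {
  rec <- read_recording(stem)
  if (!has_kinetics(rec)) {
    stop("pipeline_preprocess: recording has no kinetics; nothing to align",
         call. = FALSE)
  }
  force_norm <- time_series(sqrt(rec$fx$values^2 + rec$fy$values^2),
                            rec$fx$rate, "N")
  ev_kin <- detect_sync_events(force_norm)
  ev_imu <- detect_sync_events(rec$accel_norm)
  aligned <- align_streams(rec, rec, ev_kin, ev_imu)
  # drop the kick transients at the crop boundaries before segmenting
  margin <- round(aligned$mz$rate)
  n <- length(aligned$mz$values)
  cycles <- segment_cycles(ts_crop(aligned$mz, margin, n - margin),
                           cfg$threshold_frac, cfg$hysteresis, cfg$extend)
  for (col in c("start", "end", "ext_start", "ext_end")) {
    cycles[[col]] <- cycles[[col]] + margin - 1L
  }
  pattern <- compute_generic_pattern(cycles, aligned[[cfg$channel]],
                                     L = cfg$pattern_length,
                                     window = cfg$rms_window)
  tab <- cycle_rms_table(cycles, list(accel = aligned$accel_norm,
                                      gyro = aligned$gyro_norm,
                                      target = aligned[[cfg$channel]]),
                         window = cfg$rms_window)
  tab$duration <- tab$end - tab$start
  utils::write.csv(tab, file.path(cfg$out_dir, "cycles.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pattern = pattern$values),
                   file.path(cfg$out_dir, "pattern.csv"), row.names = FALSE)
  list(recording = aligned, cycles = cycles, pattern = pattern)
}

#' Identify HW models over the order grid
#'
#' Runs [hw_grid_search()] for the configured channel, caching each fitted
#' order spec as JSON under `out_dir/hw_cache` so an interrupted sweep
#' resumes without refitting, and writes the ranked results table plus the
#' best model.
#'
#' @param cfg A [wk_config()].
#' @param prep A [pipeline_preprocess()] result (recomputed when `NULL`).
#' @return The [hw_grid_search()] result.
#' @export
pipeline_fit_hw <- function(cfg = wk_config(), prep = NULL) {
  if (is.null(prep)) prep <- pipeline_preprocess(cfg)
  data <- hw_make_dataset(prep$recording, prep$cycles, prep$pattern,
                          cfg$channel, cfg$rms_window)
  n_train <- min(cfg$train_cycles, length(data) - 1L)
  train <- data[seq_len(n_train)]
  test <- data[seq(n_train + 1L, length(data))]
  orders <- enumerate_orders(cfg$max_poles)
  cache_dir <- file.path(cfg$out_dir, "hw_cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- vector("list", nrow(orders))
  res_rows <- vector("list", nrow(orders))
  for (i in seq_len(nrow(orders))) {
    key <- paste(unlist(orders[i, ]), collapse = "-")
    cache <- file.path(cache_dir, paste0(key, ".json"))
    if (file.exists(cache)) {
      cached <- jsonlite::read_json(cache, simplifyVector = TRUE)
      res_rows[[i]] <- cached$train_error
      fits[[i]] <- structure(
        list(model = hw_load(file.path(cache_dir, paste0(key, "_model.json"))),
             order = as.list(orders[i, ]), train_error = cached$train_error,
             test_error = NA_real_, trace = numeric(0), converged = TRUE),
        class = "hw_fit")
      next
    }
    fit <- tryCatch(hw_identify(train, orders[i, ], cfg$hw),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res_rows[[i]] <- NA_real_
      next
    }
    fits[[i]] <- fit
    res_rows[[i]] <- fit$train_error
    hw_save(fit$model, file.path(cache_dir, paste0(key, "_model.json")))
    jsonlite::write_json(list(train_error = fit$train_error), cache,
                         auto_unbox = TRUE, digits = NA)
  }
  res <- cbind(as.data.frame(orders),
               train_error = unlist(res_rows),
               n_par = vapply(seq_len(nrow(orders)),
                              function(i) count_parameters(orders[i, ])$linear,
                              integer(1)))
  ok <- which(is.finite(res$train_error))
  rank_ord <- ok[order(res$train_error[ok], res$n_par[ok], ok)]
  kept <- rank_ord[seq_len(min(cfg$keep, length(rank_ord)))]
  res$test_error <- NA_real_
  for (i in kept) {
    fits[[i]]$test_error <- hw_nrmse(fits[[i]]$model, test)
    res$test_error[i] <- fits[[i]]$test_error
  }
  utils::write.csv(res[rank_ord, ], file.path(cfg$out_dir, "hw_results.csv"),
                   row.names = FALSE)
  hw_save(fits[[kept[1]]]$model, file.path(cfg$out_dir, "hw_best.json"))
  write_config(cfg, cfg$out_dir)
  structure(list(results = res, models = fits[kept], keep = cfg$keep),
            class = "hw_grid")
}

#' Train the BiLSTM baseline on a preprocessed recording
#'
#' @param cfg A [wk_config()].
#' @param prep A [pipeline_preprocess()] result (recomputed when `NULL`).
#' @return The trained [seqreg_train()] model; training curves are written
#'   to `out_dir/seqreg_curves.json`.
#' @export
pipeline_train_seqreg <- function(cfg = wk_config(), prep = NULL) {
  if (is.null(prep)) prep <- pipeline_preprocess(cfg)
  data <- seqreg_make_dataset(prep$recording, prep$cycles, cfg$channel,
                              cfg$rms_window)
  split <- seqreg_split(data, cfg$seqreg$train_val_split, cfg$seqreg$seed)
  model <- seqreg_train(cfg$seqreg, split$train, split$val)
  jsonlite::write_json(model$curves,
                       file.path(cfg$out_dir, "seqreg_curves.json"),
                       digits = NA, dataframe = "columns")
  write_config(cfg, cfg$out_dir)
  model
}

#' Predict and evaluate a fitted model on a recording
#'
#' End-to-end evaluation: normalized per-cycle predictions from either an
#' [hw_model()] (three inputs including the generic pattern) or a
#' [seqreg_train()] model (two IMU inputs), de-normalization by the
#' measured cycle RMS, RMSE/MAE in physical units, per-cycle peak
#' extraction, Bland-Altman agreement and peak ANOVA. When the recording
#' has no kinetics, predictions are returned and evaluation is skipped with
#' a warning.
#'
#' @param cfg A [wk_config()].
#' @param model An [hw_model()] or `seqreg_model`.
#' @param prep A [pipeline_preprocess()] result.
#' @return List with `predictions` (per cycle, normalized), `metrics`
#'   (RMSE/MAE in physical units), `peaks`, `agreement`
#'   ([bland_altman()]) and `anova`.
#' @export
pipeline_evaluate <- function(cfg, model, prep) {
  is_hw <- inherits(model, "hw_model")
  if (!is_hw && !inherits(model, "seqreg_model")) {
    stop("pipeline_evaluate: model must be an hw_model or seqreg_model",
         call. = FALSE)
  }
  if (is_hw && model$channel != cfg$channel) {
    stop(sprintf("pipeline_evaluate: model predicts %s but config asks for %s",
                 model$channel, cfg$channel), call. = FALSE)
  }
  deploy <- is.null(prep$recording[[cfg$channel]])
  if (is_hw) {
    data <- hw_make_dataset(prep$recording, prep$cycles, prep$pattern,
                            cfg$channel, cfg$rms_window,
                            require_target = !deploy)
    preds <- lapply(data, function(cyc) hw_simulate(model, cyc$inputs))
    if (deploy) {
      warning("recording has no measured kinetics: evaluation skipped",
              call. = FALSE)
      return(list(predictions = preds, metrics = NULL, peaks = NULL,
                  agreement = NULL, anova = NULL))
    }
  } else {
    data <- seqreg_make_dataset(prep$recording, prep$cycles, cfg$channel,
                                cfg$rms_window)
    preds <- lapply(data, function(cyc) predict(model, cyc$x))
  }
  measured <- lapply(data, `[[`, "target")
  factors <- vapply(data, `[[`, numeric(1), "factor")
  per_cycle <- t(vapply(seq_along(data), function(i) {
    error_metrics(measured[[i]], preds[[i]], factors[i])
  }, numeric(2)))
  overall <- error_metrics(unlist(mapply(`*`, measured, factors, SIMPLIFY = FALSE)),
                           unlist(mapply(`*`, preds, factors, SIMPLIFY = FALSE)))
  peaks <- data.frame(
    measured = vapply(seq_along(data), function(i) {
      cyc <- data[[i]]$cycle
      span <- (cyc$start - cyc$ext_start + 1L):(cyc$end - cyc$ext_start)
      max(measured[[i]][span]) * factors[i]
    }, numeric(1)),
    predicted = vapply(seq_along(data), function(i) {
      cyc <- data[[i]]$cycle
      span <- (cyc$start - cyc$ext_start + 1L):(cyc$end - cyc$ext_start)
      max(preds[[i]][span]) * factors[i]
    }, numeric(1)))
  agreement <- bland_altman(peaks$measured, peaks$predicted)
  an <- anova_peaks(peaks$measured, peaks$predicted)
  list(predictions = preds, metrics = list(per_cycle = per_cycle,
                                           overall = overall),
       peaks = peaks, agreement = agreement, anova = an)
}
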