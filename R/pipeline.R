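#' Configuration of a full pipeline run
#'
#' Collects every stage parameter in one validated, serializable object.
#'
#' @param sim A [sim_config()] describing the synthetic study (or `NULL`
#'   when recordings/tables are supplied to [run_pipeline()] directly).
#' @param window_length,window_step,t_max Rolling-window grid, seconds.
#' @param band Alpha band for envelopes, Hz (robustness variant
#'   `c(8, 12)`).
#' @param isc_channels Channels averaged for ISC.
#' @param rank_order Use Spearman (rank-ordered) correlations in the
#'   forecasting stage.
#' @param n_boot Bootstrap iterations for the peak-window CI (0 skips).
#' @param channel_map Compute the per-channel ISC predictive map (the
#'   most expensive optional stage).
#' @param power_grid Effect sizes for the power stage (`NULL` skips).
#' @param low,high Band-pass edges, Hz.
#' @param seed Seed controlling generation and bootstrapping.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), window_length = 5,
                       window_step = 1, t_max = 63, band = c(8, 13),
                       isc_channels = c("Cz", "C3", "C4"),
                       rank_order = FALSE, n_boot = 0,
                       channel_map = FALSE, power_grid = NULL,
                       low = 0.3, high = 50, seed = NULL) {
  cfg <- list(sim = sim, window_length = window_length,
              window_step = window_step, t_max = t_max, band = band,
              isc_channels = isc_channels, rank_order = rank_order,
              n_boot = n_boot, channel_map = channel_map,
              power_grid = power_grid, low = low, high = high,
              seed = seed %||% (if (!is.null(sim)) sim$seed else 1L))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full neuroforecasting pipeline
#'
#' Executes, in fixed order: simulate (unless a study is supplied),
#' preprocess, spectral decomposition, FAA and ISC metrics, rolling-window
#' forecasting against population interest / deal outcomes / funding
#' amounts, the mixed-model and amount-regression stages, the optional
#' per-channel ISC map and power analysis. Identical config and seed give
#' identical bundles.
#'
#' @param config A [run_config()].
#' @param study Optional pre-generated [generate_study()] bundle (used
#'   instead of simulating).
#' @return List of class `pipeline_result`: `forecasts` (FAA vs
#'   population interest, ISC vs deal, ISC vs amount), `bootstrap`
#'   (peak-window CIs when requested), `isc_trajectories`
#'   (funded/unfunded mean ISC per window), `faa_windows` and
#'   `isc_windows` (windows x videos matrices), `video_table`, `lmm`
#'   (fits plus likelihood-ratio comparison), `amount_model`,
#'   `channel_map`, `power`, and a provenance `manifest`.
#' @export
run_pipeline <- function(config = run_config(), study = NULL) {
  stopifnot(inherits(config, "run_config"))
  method <- if (config$rank_order) "spearman" else "pearson"
  study <- study %||% generate_study(config$sim)
  tables <- study$tables

  freqs <- seq(config$band[1], config$band[2], by = 1)
  need_ch <- unique(c("F3", "F4", config$isc_channels))

  # Preprocess and decompose each subject once, grouping by video.
  env_by_video <- list()
  welch_rows <- list()
  for (rec in study$recordings) {
    epochs <- preprocess_recording(rec, low = config$low, high = config$high)
    for (ep in epochs) {
      env <- morlet_alpha_envelope(ep, freqs = freqs, channels = need_ch)
      env_by_video[[ep$video_id]] <- c(env_by_video[[ep$video_id]], list(env))
      bp <- welch_band_power(ep, band = config$band)
      welch_rows[[length(welch_rows) + 1]] <- data.frame(
        subject_id = ep$subject_id, video_id = ep$video_id,
        faa = as.numeric(faa(bp[["F3"]], bp[["F4"]])))
    }
  }
  env_by_video <- env_by_video[order(names(env_by_video))]
  video_ids <- names(env_by_video)
  whole_faa <- do.call(rbind, welch_rows)

  t_max <- min(config$t_max, min(study$truth$durations))
  windows <- make_windows(t_max, config$window_length, config$window_step,
                          t_max)

  faa_mat <- vapply(env_by_video, function(envs) {
    group_faa_series(envs, windows)
  }, numeric(nrow(windows)))
  isc_mat <- vapply(env_by_video, function(envs) {
    isc_series(envs, windows, channels = config$isc_channels)$mean_isc
  }, numeric(nrow(windows)))

  ord <- match(video_ids, tables$outcomes$video_id)
  pop <- tables$population$pop_interest[match(video_ids,
                                              tables$population$video_id)]
  deal <- tables$outcomes$deal[ord]
  amount <- tables$outcomes$amount[ord]

  forecasts <- list(
    faa_pop = momentwise_forecast(faa_mat, pop, windows, method, "FAA"),
    isc_deal = momentwise_forecast(isc_mat, deal, windows, method, "ISC"),
    isc_amount = momentwise_forecast(isc_mat, amount, windows, method, "ISC")
  )
  boot <- NULL
  if (config$n_boot > 0) {
    boot <- lapply(names(forecasts), function(nm) {
      fc <- forecasts[[nm]]
      if (all(is.na(fc$r))) return(NULL)
      k <- which.max(abs(fc$r))
      metric <- if (fc$metric[1] == "FAA") faa_mat[k, ] else isc_mat[k, ]
      outcome <- switch(nm, faa_pop = pop, isc_deal = deal,
                        isc_amount = amount)
      ci <- bootstrap_ci(metric, outcome, n_boot = config$n_boot,
                         seed = config$seed + k)
      data.frame(forecast = nm, window = k, start = fc$start[k],
                 r = attr(ci, "r"), lo = ci[1], hi = ci[2])
    })
    boot <- do.call(rbind, Filter(Negate(is.null), boot))
  }

  traj <- data.frame(
    window = seq_len(nrow(windows)), start = windows$start,
    end = windows$end,
    funded = if (any(deal == 1)) rowMeans(isc_mat[, deal == 1, drop = FALSE]) else NA_real_,
    unfunded = if (any(deal == 0)) rowMeans(isc_mat[, deal == 0, drop = FALSE]) else NA_real_
  )

  # Individual-level mixed models (Table-2-style ladder).
  lmm <- amount_model <- NULL
  long <- build_long_table(tables, whole_faa)
  if (length(unique(long$subject_id)) >= 2 && nrow(long) >= 10) {
    fits <- list(
      dc = fit_interest_lmm(long, "dc"),
      joy = fit_interest_lmm(long, "joy"),
      faa = fit_interest_lmm(long, "faa"),
      full = fit_interest_lmm(long, c("dc", "joy", "faa"))
    )
    lmm <- list(fits = fits, lrt_full_vs_dc = compare_lrt(fits$dc, fits$full))
  }
  vt <- build_video_table(tables, whole_faa, video_ids)
  if (nrow(vt) >= 5) {
    amount_model <- fit_amount_regression(vt, c("stated_prediction", "joy",
                                                "mean_faa"))
  }

  cmap <- NULL
  if (isTRUE(config$channel_map) && length(video_ids) >= 3 &&
      var(deal) > 0) {
    all_ch <- setdiff(study$recordings[[1]]$channels, "EOG")
    full_env <- lapply(study$recordings, function(rec) {
      eps <- preprocess_recording(rec, low = config$low, high = config$high)
      setNames(lapply(eps, morlet_alpha_envelope, freqs = freqs,
                      channels = all_ch),
               vapply(eps, `[[`, character(1), "video_id"))
    })
    env_all <- lapply(video_ids, function(v) {
      Filter(Negate(is.null), lapply(full_env, `[[`, v))
    })
    cmap <- isc_channel_map(env_all, tables$outcomes, all_ch)
  }

  power <- if (!is.null(config$power_grid)) {
    power_table(config$power_grid, seed = config$seed)
  }

  manifest <- list(
    package = "neuroforecast",
    version = as.character(utils::packageVersion("neuroforecast")),
    seed = config$seed,
    config = serializable_config(config)
  )
  structure(list(forecasts = forecasts, bootstrap = boot,
                 isc_trajectories = traj, faa_windows = faa_mat,
                 isc_windows = isc_mat, whole_faa = whole_faa,
                 video_table = vt, lmm = lmm, amount_model = amount_model,
                 channel_map = cmap, power = power, windows = windows,
                 manifest = manifest),
            class = "pipeline_result")
}

# Long subject x video table for the mixed-model stage.
build_long_table <- function(tables, whole_faa) {
  rat <- tables$ratings
  long <- data.frame(
    subject_id = rat$subject_id, video_id = rat$video_id,
    interest = composite_interest(rat[, paste0("q", 1:5)]),
    dc = composite_dc(rat[, paste0("dc", 1:14)])
  )
  long <- merge(long, whole_faa, by = c("subject_id", "video_id"))
  if (!is.null(tables$sentiment)) {
    long <- merge(long, tables$sentiment[, c("video_id", "joy")],
                  by = "video_id")
  }
  long[order(long$subject_id, long$video_id), ]
}

# Per-video table for the amount regression.
build_video_table <- function(tables, whole_faa, video_ids) {
  mean_faa <- aggregate(faa ~ video_id, whole_faa, mean)
  names(mean_faa)[2] <- "mean_faa"
  pred <- aggregate(deal_prediction ~ video_id, tables$ratings, mean)
  names(pred)[2] <- "stated_prediction"
  vt <- merge(tables$outcomes, mean_faa, by = "video_id")
  vt <- merge(vt, pred, by = "video_id")
  if (!is.null(tables$sentiment)) {
    vt <- merge(vt, tables$sentiment[, c("video_id", "joy")], by = "video_id")
  }
  vt[match(video_ids, vt$video_id), ]
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    sim$ramp_shape <- NULL                     # functions don't serialize
    cfg$sim <- sim
  }
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$forecasts)) {
    fc <- x$forecasts[[nm]]
    if (all(is.na(fc$r))) {
      cat(sprintf("  %-10s undefined (constant metric or outcome)\n", nm))
      next
    }
    k <- which.max(abs(fc$r))
    cat(sprintf("  %-10s peak r = %+.3f at [%g, %g) s, p = %.3g\n", nm,
                fc$r[k], fc$start[k], fc$end[k], fc$p[k]))
  }
  if (!is.null(x$amount_model)) {
    cat(sprintf("  amount OLS: adj R^2 %.3f (n = %d)\n",
                x$amount_model$adj_r_squared, x$amount_model$n))
  }
  invisible(x)
}

#' Save a pipeline result bundle to disk
#'
#' Writes per-window forecast tables, ISC trajectories, windowed
#' matrices, model coefficient tables, the channel map, and the JSON
#' manifest under `dir`.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
save_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$forecasts)) {
    write.csv(result$forecasts[[nm]],
              file.path(dir, paste0("forecast_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(result$isc_trajectories, file.path(dir, "isc_trajectories.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$faa_windows),
            file.path(dir, "faa_windows.csv"))
  if (!is.null(result$bootstrap)) {
    write.csv(result$bootstrap, file.path(dir, "bootstrap_ci.csv"),
              row.names = FALSE)
  }
  if (!is.null(result$lmm)) {
    tabs <- lapply(names(result$lmm$fits), function(nm) {
      cbind(model = nm, result$lmm$fits[[nm]]$coefficients,
            AIC = result$lmm$fits[[nm]]$AIC)
    })
    write.csv(do.call(rbind, tabs), file.path(dir, "lmm_models.csv"),
              row.names = FALSE)
  }
  if (!is.null(result$amount_model)) {
    write.csv(result$amount_model$coefficients,
              file.path(dir, "amount_model.csv"), row.names = FALSE)
  }
  if (!is.null(result$channel_map)) {
    write.csv(result$channel_map, file.path(dir, "channel_map.csv"),
              row.names = FALSE)
  }
  if (!is.null(result$power)) {
    write.csv(result$power, file.path(dir, "power.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
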