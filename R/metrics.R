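#' Frontal alpha asymmetry from two power values
#'
#' `FAA = ln(P_F4) - ln(P_F3)`: log alpha power at the right-frontal
#' electrode minus log power at the homologous left-frontal electrode.
#' Positive values indicate relatively greater left-hemisphere activity
#' (alpha power is inversely related to activity), interpreted as
#' approach motivation. Powers are floored at `floor` before the log;
#' a value with both inputs at the floor is flagged unreliable.
#'
#' @param p_f3,p_f4 Alpha power at F3 and F4 (same positive units).
#' @param floor Power floor (default 1e-12) guarding against `-Inf`.
#' @return Numeric FAA value; `attr(, "unreliable")` is `TRUE` when both
#'   powers sat at the floor.
#' @examples
#' faa(1, 2)        # log(2)
#' faa(2, 1)        # -log(2): swapping inputs flips the sign
#' @export
faa <- function(p_f3, p_f4, floor = 1e-12) {
  p3 <- pmax(p_f3, floor)
  p4 <- pmax(p_f4, floor)
  out <- log(p4) - log(p3)
  attr(out, "unreliable") <- (p_f3 <= floor & p_f4 <= floor)
  out
}

#' Windowed FAA series from an alpha-power envelope
#'
#' Window-averages the F3 and F4 alpha-power envelopes on the rolling
#' grid, then takes [faa()] per window.
#'
#' @param series A `band_power_series` containing F3 and F4
#'   (from [morlet_alpha_envelope()]).
#' @param windows A [make_windows()] grid.
#' @param floor Power floor passed to [faa()].
#' @return Data frame: `subject_id`, `video_id`, `window` (1-based
#'   index), `start`, `end`, `faa`.
#' @export
faa_series <- function(series, windows, floor = 1e-12) {
  if (!all(c("F3", "F4") %in% series$channels)) {
    stop("missing channel: need F3 and F4", call. = FALSE)
  }
  wa <- window_average(series, windows)
  vals <- faa(wa$power["F3", ], wa$power["F4", ], floor)
  data.frame(subject_id = series$subject_id, video_id = series$video_id,
             window = seq_len(nrow(windows)), start = windows$start,
             end = windows$end, faa = as.numeric(vals))
}

#' Group-level windowed FAA for one video
#'
#' Mean across subjects of the per-subject windowed FAA series.
#'
#' @param series_list List of `band_power_series` (one per subject, same
#'   video).
#' @param windows A [make_windows()] grid.
#' @param floor Power floor passed to [faa()].
#' @return Numeric vector, one group FAA per window.
#' @export
group_faa_series <- function(series_list, windows, floor = 1e-12) {
  mat <- vapply(series_list, function(s) faa_series(s, windows, floor)$faa,
                numeric(nrow(windows)))
  rowMeans(as.matrix(mat), na.rm = TRUE)
}

#' Number of subject pairs
#'
#' The half triangle of the full inter-subject matrix: `n (n - 1) / 2`.
#' 28 subjects yield 378 pairwise comparisons.
#'
#' @param n Number of subjects (>= 2).
#' @return Integer pair count.
#' @export
n_pairs <- function(n) {
  if (n < 2) stop("need n >= 2 subjects", call. = FALSE)
  as.integer(n * (n - 1) / 2)
}

# Per-subject channel-averaged (or per-channel) envelope matrix restricted
# to a window; rows = subjects.
subject_window_series <- function(envelopes, channels, window,
                                  average_channels = TRUE) {
  n_t <- min(vapply(envelopes, function(e) length(e$times), integer(1)))
  ref <- envelopes[[1]]
  idx <- seq_len(n_t)
  keep <- ref$times[idx] >= 0 & !ref$edge[idx]
  if (!is.null(window)) {
    keep <- keep & ref$times[idx] >= window[1] & ref$times[idx] < window[2]
  }
  sel <- which(keep)
  t(vapply(envelopes, function(e) {
    miss <- setdiff(channels, e$channels)
    if (length(miss)) stop("missing channel: ", paste(miss, collapse = ","),
                           call. = FALSE)
    x <- e$power[channels, sel, drop = FALSE]
    if (average_channels) colMeans(x) else as.numeric(t(x))
  }, numeric(if (average_channels) length(sel) else length(sel) * length(channels))))
}

#' Inter-subject correlation of alpha-power envelopes
#'
#' For every subject pair, the Pearson correlation of channel-averaged
#' alpha-power envelopes (mid-central channels Cz/C3/C4 by default) within
#' the window; `mean_isc` is the unweighted mean over all
#' `n (n - 1) / 2` pairs. Pairs containing a zero-variance series are
#' excluded and counted.
#'
#' @param envelopes List of `band_power_series`, one per subject, same
#'   video, on a common time grid (see [morlet_alpha_envelope()]'s 250-Hz
#'   standardization).
#' @param channels Channels averaged into each subject's series.
#' @param window Length-2 seconds `[t0, t1)` restricting the correlation,
#'   or `NULL` for the whole video.
#' @param average_channels If `FALSE`, channels are concatenated instead
#'   of averaged before correlation (sensitivity variant).
#' @return List of class `isc_value`: `video_id`, `window`,
#'   `pair_correlations` (length `n_pairs(n)`, `NA` for excluded pairs),
#'   `mean_isc`, `n_excluded`, `channels`.
#' @export
isc <- function(envelopes, channels = c("Cz", "C3", "C4"), window = NULL,
                average_channels = TRUE) {
  n <- length(envelopes)
  if (n < 2) stop("need >= 2 subjects", call. = FALSE)
  series <- subject_window_series(envelopes, channels, window, average_channels)
  pairs <- utils::combn(n, 2)
  sds <- apply(series, 1, sd)
  r <- rep(NA_real_, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (sds[i] > 0 && sds[j] > 0) r[k] <- cor(series[i, ], series[j, ])
  }
  structure(list(video_id = envelopes[[1]]$video_id,
                 window = window %||% "whole-video",
                 pair_correlations = r,
                 mean_isc = mean(r, na.rm = TRUE),
                 n_excluded = sum(is.na(r)),
                 channels = channels),
            class = "isc_value")
}

#' @export
print.isc_value <- function(x, ...) {
  cat(sprintf("<isc_value> video %s, window %s: mean ISC %.4f over %d pairs (%d excluded)\n",
              x$video_id, paste(format(x$window), collapse = "-"),
              x$mean_isc, length(x$pair_correlations) - x$n_excluded,
              x$n_excluded))
  invisible(x)
}

#' Windowed ISC trajectory for one video
#'
#' [isc()] evaluated on every rolling window.
#'
#' @inheritParams isc
#' @param windows A [make_windows()] grid.
#' @return Data frame `window`, `start`, `end`, `mean_isc`, `n_excluded`;
#'   the pairs x windows correlation matrix is in `attr(, "pairs")`.
#' @export
isc_series <- function(envelopes, windows, channels = c("Cz", "C3", "C4"),
                       average_channels = TRUE) {
  vals <- lapply(seq_len(nrow(windows)), function(k) {
    isc(envelopes, channels, c(windows$start[k], windows$end[k]),
        average_channels)
  })
  out <- data.frame(window = seq_len(nrow(windows)), start = windows$start,
                    end = windows$end,
                    mean_isc = vapply(vals, `[[`, numeric(1), "mean_isc"),
                    n_excluded = vapply(vals, `[[`, numeric(1), "n_excluded"))
  attr(out, "pairs") <- vapply(vals, `[[`,
                               numeric(length(vals[[1]]$pair_correlations)),
                               "pair_correlations")
  out
}

#' Per-channel map of ISC predictive power
#'
#' For each EEG channel, the whole-video single-channel mean ISC is
#' computed per video and correlated across videos with the binary deal
#' outcome (point-biserial) and with the funding amount.
#'
#' @param envelopes_by_video List over videos; each element a list of
#'   per-subject `band_power_series` covering the channels of interest.
#' @param outcomes Data frame with `video_id`, `deal`, `amount`.
#' @param channels Channels to map (default: all EEG channels present in
#'   the first envelope).
#' @return Data frame `channel`, `r_deal`, `r_amount`.
#' @export
isc_channel_map <- function(envelopes_by_video, outcomes, channels = NULL) {
  if (length(envelopes_by_video) < 3) stop("need >= 3 videos", call. = FALSE)
  channels <- channels %||% setdiff(envelopes_by_video[[1]][[1]]$channels, "EOG")
  video_ids <- vapply(envelopes_by_video,
                      function(e) e[[1]]$video_id, character(1))
  outcomes <- outcomes[match(video_ids, outcomes$video_id), ]
  if (var(outcomes$deal) == 0) stop("constant outcome vector", call. = FALSE)
  per_channel <- lapply(channels, function(ch) {
    vapply(envelopes_by_video, function(env) {
      isc(env, channels = ch)$mean_isc
    }, numeric(1))
  })
  data.frame(
    channel = channels,
    r_deal = vapply(per_channel, function(v) cor(v, outcomes$deal), numeric(1)),
    r_amount = vapply(per_channel, function(v) cor(v, outcomes$amount), numeric(1))
  )
}
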