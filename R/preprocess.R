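#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed FIR band-pass applied with zero phase (the kernel is
#' convolved with its own reverse, giving a symmetric zero-delay kernel),
#' so window timestamps stay aligned to video onsets. The per-channel mean
#' (DC) is removed before filtering. All channels, including EOG, receive
#' the same filter.
#'
#' @param recording An [eeg_recording()] (or a [video_epoch()]).
#' @param low,high Band edges in Hz; defaults 0.3 and 50.
#' @param n_taps Filter length (odd); default targets a transition width
#'   of about the lower edge (`3.3 * fs / low`), capped at a quarter of
#'   the signal length.
#' @return The input object with filtered data.
#' @export
bandpass <- function(recording, low = 0.3, high = 50, n_taps = NULL) {
  fs <- recording$fs
  if (low >= high) stop("low must be < high", call. = FALSE)
  if (high >= fs / 2) stop("high must be below the Nyquist frequency", call. = FALSE)
  n <- ncol(recording$data)
  taps <- n_taps %||% min(round(3.3 * fs / low), floor(n / 4))
  taps <- max(31L, as.integer(taps))
  if (taps %% 2 == 0) taps <- taps + 1L
  h <- signal::fir1(taps - 1L, c(low, high) / (fs / 2), type = "pass")
  # Forward-backward response = |H|^2: convolve kernel with its reverse
  # (h is symmetric, so h * rev(h) = h * h, centered and zero-phase).
  h2 <- fft_convolve(h, rev(h))
  half <- (length(h2) - 1L) / 2L
  for (i in seq_len(nrow(recording$data))) {
    x <- recording$data[i, ]
    x <- x - mean(x)
    # Reflection padding keeps edge transients bounded.
    pad <- min(half, n - 1L)
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
    y <- fft_convolve(xp, h2)
    recording$data[i, ] <- y[(half + pad + 1L):(half + pad + n)]
  }
  recording
}

# Linear convolution via FFT; returns full length(x)+length(h)-1 result.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Cut a recording into per-video epochs
#'
#' One [video_epoch()] per onset event, spanning `[-baseline, duration)`
#' seconds around the onset in half-open sample convention: the onset
#' sample is the first sample of the epoch body, and the epoch holds
#' `round(baseline * fs) + round(duration * fs)` samples.
#'
#' @param recording An [eeg_recording()] with events.
#' @param baseline Pre-stimulus span in seconds (default 0.2).
#' @return List of `video_epoch` objects, one per event.
#' @export
epoch_by_events <- function(recording, baseline = 0.2) {
  fs <- recording$fs
  n <- ncol(recording$data)
  n_base <- round(baseline * fs)
  lapply(seq_len(nrow(recording$events)), function(k) {
    ev <- recording$events[k, ]
    start <- ev$onset_sample - n_base          # 0-based
    len <- n_base + round(ev$duration * fs)
    if (start < 0 || start + len > n) {
      stop("event out of bounds for video ", ev$video_id, call. = FALSE)
    }
    video_epoch(recording$subject_id, ev$video_id, fs,
                recording$data[, (start + 1):(start + len), drop = FALSE],
                recording$channels, baseline = baseline)
  })
}

#' Detect bad EEG channels
#'
#' Simplified bad-channel detector: a channel is flagged when its
#' log-variance z-score across channels exceeds `var_z`, or when its
#' maximum absolute correlation with every other EEG channel falls below
#' `neighbor_r`. The EOG channel is never flagged.
#'
#' @param epoch A [video_epoch()] with at least 4 EEG channels.
#' @param var_z Log-variance z-score threshold (default 4).
#' @param neighbor_r Minimum best-neighbor correlation (default 0.4).
#' @return Character vector of flagged labels (possibly empty).
#' @export
detect_bad_channels <- function(epoch, var_z = 4.0, neighbor_r = 0.4) {
  eeg <- setdiff(epoch$channels, "EOG")
  if (length(eeg) < 4) stop("need at least 4 EEG channels", call. = FALSE)
  x <- epoch$data[eeg, , drop = FALSE]
  v <- apply(x, 1, var)
  lv <- log(pmax(v, .Machine$double.xmin))
  z <- if (sd(lv) > 0) (lv - mean(lv)) / sd(lv) else rep(0, length(lv))
  flat <- v <= .Machine$double.eps
  ok_var <- !flat & abs(z) <= var_z
  # Best-neighbor correlation among non-flat channels.
  low_corr <- rep(FALSE, length(eeg))
  good <- which(!flat)
  if (length(good) >= 2) {
    cm <- abs(cor(t(x[good, , drop = FALSE])))
    diag(cm) <- NA
    best <- apply(cm, 1, max, na.rm = TRUE)
    low_corr[good] <- best < neighbor_r
  }
  eeg[!ok_var | low_corr]
}

#' Montage adjacency of the 19-channel 10-20 layout
#'
#' Fixed nearest-neighbor table shipped with the package
#' (`extdata/montage_adjacency_1020.csv`), used by
#' [interpolate_bad_channels()].
#'
#' @return Named list: for each channel, its neighbor labels.
#' @export
montage_adjacency <- function() {
  path <- system.file("extdata", "montage_adjacency_1020.csv",
                      package = "neuroforecast", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  split(tab$neighbor, tab$channel)
}

#' Interpolate bad channels from montage neighbors
#'
#' Each bad channel is replaced by the unweighted mean of its good montage
#' neighbors (falling back to the mean of all good EEG channels when fewer
#' than one good neighbor remains).
#'
#' @param epoch A [video_epoch()].
#' @param bads Labels to interpolate (default: the epoch's recorded bads).
#' @param adjacency Neighbor table; default [montage_adjacency()].
#' @return The epoch with bad channels replaced and recorded in
#'   `bad_channels`.
#' @export
interpolate_bad_channels <- function(epoch, bads = epoch$bad_channels,
                                     adjacency = montage_adjacency()) {
  if (!length(bads)) return(epoch)
  eeg <- setdiff(epoch$channels, "EOG")
  good <- setdiff(eeg, bads)
  if (!length(good)) stop("unrecoverable epoch: all channels bad", call. = FALSE)
  for (ch in bads) {
    nb <- intersect(adjacency[[ch]] %||% character(), good)
    src <- if (length(nb) >= 1) nb else good
    epoch$data[ch, ] <- colMeans(epoch$data[src, , drop = FALSE])
  }
  epoch$bad_channels <- union(epoch$bad_channels, bads)
  epoch
}

#' Remove ocular artifacts by EOG regression
#'
#' For each EEG channel whose correlation with the EOG channel is
#' significant at the `z_thresh` level (Fisher z of the Pearson r times
#' `sqrt(n - 3)`), the least-squares EOG projection is subtracted.
#' Channels below threshold are left untouched. The EOG channel itself is
#' dropped from the returned epoch.
#'
#' @param epoch A [video_epoch()] containing an "EOG" channel.
#' @param z_thresh Correlation z-score gate (default 1.96).
#' @return The cleaned epoch without the EOG row (`cleaned = TRUE`).
#' @export
remove_eog <- function(epoch, z_thresh = 1.96) {
  if (!"EOG" %in% epoch$channels) stop("missing EOG channel", call. = FALSE)
  eog <- epoch$data["EOG", ]
  n <- length(eog)
  v_eog <- var(eog)
  if (v_eog > 0) {
    for (ch in setdiff(epoch$channels, "EOG")) {
      r <- cor(epoch$data[ch, ], eog)
      z <- atanh(clamp(r, -1 + 1e-12, 1 - 1e-12)) * sqrt(n - 3)
      if (is.finite(z) && abs(z) > z_thresh) {
        beta <- cov(epoch$data[ch, ], eog) / v_eog
        epoch$data[ch, ] <- epoch$data[ch, ] - beta * eog
      }
    }
  }
  keep <- setdiff(epoch$channels, "EOG")
  epoch$data <- epoch$data[keep, , drop = FALSE]
  epoch$channels <- keep
  epoch$cleaned <- TRUE
  epoch
}

#' Baseline-correct an epoch
#'
#' Subtracts each channel's mean over the pre-stimulus window (default
#' `[-0.2, 0)` seconds) from the whole epoch. Idempotent.
#'
#' @param epoch A [video_epoch()].
#' @param window Length-2 seconds relative to onset; must lie inside the
#'   epoch span and be non-empty.
#' @return The baseline-corrected epoch.
#' @export
baseline_correct <- function(epoch, window = c(-0.2, 0)) {
  times <- epoch_times(epoch)
  idx <- times >= window[1] & times < window[2]
  if (!any(idx)) stop("empty baseline window", call. = FALSE)
  mu <- rowMeans(epoch$data[, idx, drop = FALSE])
  epoch$data <- epoch$data - mu
  epoch
}

#' Run the full preprocessing pipeline on one recording
#'
#' Fixed stage order: band-pass filter the continuous recording, epoch by
#' video onsets, detect and interpolate bad channels, regress out the EOG
#' channel, baseline-correct. Stage parameters and per-epoch bad channels
#' are recorded in each epoch's `provenance` attribute.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band-pass edges, Hz.
#' @param baseline Pre-stimulus span, seconds.
#' @param var_z,neighbor_r Bad-channel thresholds
#'   (see [detect_bad_channels()]).
#' @param z_thresh EOG regression gate (see [remove_eog()]).
#' @return List of cleaned `video_epoch` objects.
#' @export
preprocess_recording <- function(recording, low = 0.3, high = 50,
                                 baseline = 0.2, var_z = 4.0,
                                 neighbor_r = 0.4, z_thresh = 1.96) {
  rec <- bandpass(recording, low, high)
  epochs <- epoch_by_events(rec, baseline)
  lapply(epochs, function(ep) {
    bads <- detect_bad_channels(ep, var_z, neighbor_r)
    if (length(bads)) ep <- interpolate_bad_channels(ep, bads)
    ep$bad_channels <- bads
    ep <- remove_eog(ep, z_thresh)
    ep <- baseline_correct(ep, c(-baseline, 0))
    attr(ep, "provenance") <- list(low = low, high = high,
                                   baseline = baseline, var_z = var_z,
                                   neighbor_r = neighbor_r,
                                   z_thresh = z_thresh, bads = bads)
    ep
  })
}
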