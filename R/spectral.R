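#' Welch power spectral density
#'
#' Hamming-windowed overlapping-segment averaged periodogram, scaled as a
#' one-sided density (microvolts^2 / Hz), so that summing `psd * df` over
#' all frequencies recovers the signal variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = 2, overlap = 0.5) {
  nseg <- round(seg_len * fs)
  if (length(x) < nseg) stop("signal shorter than one Welch segment", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- signal::hamming(nseg)
  u <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  pxx <- acc / (length(starts) * fs * u)
  n_keep <- floor(nseg / 2) + 1L
  pxx <- pxx[seq_len(n_keep)]
  # One-sided: double everything except DC (and Nyquist when present).
  dbl <- seq(2L, n_keep - (1L - nseg %% 2L))
  pxx[dbl] <- 2 * pxx[dbl]
  list(freq = seq(0, fs / 2, length.out = n_keep), psd = pxx)
}

#' Welch band power of an epoch
#'
#' Mean Welch PSD over the frequency bins inside `band` (edges inclusive),
#' per channel, computed on the post-onset part of the epoch.
#'
#' @param epoch A [video_epoch()] (or a plain channels x samples matrix
#'   with an `fs` argument supplied via `fs`).
#' @param band Length-2 Hz band; default `c(8, 13)`.
#' @param seg_len,overlap Welch parameters (seconds, fraction).
#' @param fs Sampling rate; taken from the epoch when omitted.
#' @return Named numeric vector: band power (density units) per channel.
#' @export
welch_band_power <- function(epoch, band = c(8, 13), seg_len = 2,
                             overlap = 0.5, fs = NULL) {
  if (inherits(epoch, "video_epoch")) {
    keep <- epoch_times(epoch) >= 0
    x <- epoch$data[, keep, drop = FALSE]
    fs <- epoch$fs
  } else {
    x <- as.matrix(epoch)
    if (is.null(fs)) stop("fs required for matrix input", call. = FALSE)
  }
  if (band[2] >= fs / 2 || band[1] <= 0) {
    stop("band outside resolvable range", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(x)), function(i) {
    p <- welch_psd(x[i, ], fs, seg_len, overlap)
    sel <- p$freq >= band[1] & p$freq <= band[2]
    mean(p$psd[sel])
  }, numeric(1))
  setNames(out, rownames(x))
}

# Complex Morlet wavelet at frequency f, n_cycles wide, support +/- 5 sd.
# Normalized so a unit-amplitude sinusoid at f yields |conv| = 1.
morlet_wavelet <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma_t * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * f * t)
  w / (sum(g) / 2)
}

#' Morlet alpha-power envelope of an epoch
#'
#' Time-frequency decomposition with complex Morlet wavelets (fixed
#' `n_cycles`) on a 1-Hz grid across the alpha band; squared magnitudes
#' are averaged across frequencies, giving a per-channel alpha-power
#' envelope at every sample. Samples within half a wavelet of either epoch
#' edge are flagged so window averaging can exclude them. When the epoch's
#' sampling rate exceeds `env_fs`, the envelope is resampled (linear
#' interpolation) onto the `env_fs` grid to standardize sampling.
#'
#' @param epoch A [video_epoch()].
#' @param freqs Wavelet center frequencies in Hz (default `8:13`).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param channels Channels to decompose (default all).
#' @param env_fs Target envelope sampling rate, Hz (default 250); ignored
#'   when the epoch is already at or below it.
#' @param keep_freqs If `TRUE`, also return the per-frequency envelopes.
#' @return Object of class `band_power_series`: `power` (channels x
#'   times), `times` (s, onset-relative), `edge` (logical mask of edge
#'   samples), `fs`, plus identifiers.
#' @export
morlet_alpha_envelope <- function(epoch, freqs = 8:13, n_cycles = 7,
                                  channels = epoch$channels, env_fs = 250,
                                  keep_freqs = FALSE) {
  fs <- epoch$fs
  n <- ncol(epoch$data)
  widest <- 2 * ceiling(5 * n_cycles / (2 * pi * min(freqs)) * fs) + 1
  if (n <= widest) stop("epoch too short for the lowest frequency", call. = FALSE)
  channels <- intersect(channels, epoch$channels)
  if (!length(channels)) stop("missing channel", call. = FALSE)

  wavelets <- lapply(freqs, morlet_wavelet, fs = fs, n_cycles = n_cycles)
  halfs <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, integer(1))
  edge_n <- max(halfs)

  # One FFT per channel, cached wavelet FFTs shared across epochs of the
  # same length: the transform is the workhorse of every multi-seed run.
  nfft <- stats::nextn(n + max(lengths(wavelets)) - 1L, 2)
  w_ffts <- lapply(seq_along(freqs), function(fi) {
    key <- paste(nfft, fs, freqs[fi], n_cycles, sep = "_")
    if (is.null(.morlet_cache[[key]])) {
      w <- wavelets[[fi]]
      .morlet_cache[[key]] <- fft(c(w, numeric(nfft - length(w))))
    }
    .morlet_cache[[key]]
  })

  per_freq <- if (keep_freqs) {
    array(NA_real_, c(length(channels), n, length(freqs)),
          dimnames = list(channels, NULL, freqs))
  } else NULL
  power <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    x <- epoch$data[channels[ci], ]
    fx <- fft(c(x, numeric(nfft - n)))
    for (fi in seq_along(freqs)) {
      conv <- fft(fx * w_ffts[[fi]], inverse = TRUE) / nfft
      p <- Mod(conv[(halfs[fi] + 1L):(halfs[fi] + n)])^2
      power[ci, ] <- power[ci, ] + p
      if (keep_freqs) per_freq[ci, , fi] <- p
    }
  }
  power <- power / length(freqs)
  times <- epoch_times(epoch)
  edge <- seq_len(n) <= edge_n | seq_len(n) > n - edge_n

  out <- list(subject_id = epoch$subject_id, video_id = epoch$video_id,
              channels = channels, times = times, power = power,
              edge = edge, fs = fs, unit = "uV^2 (Morlet, band mean)",
              freqs = freqs, per_freq = per_freq)
  class(out) <- "band_power_series"
  if (fs > env_fs) out <- resample_envelope(out, env_fs)
  out
}

.morlet_cache <- new.env(parent = emptyenv())

# Complex-capable linear FFT convolution (full output).
fft_convolve_complex <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- fft(fft(c(x, numeric(nfft - length(x)))) *
             fft(c(h, numeric(nfft - length(h)))), inverse = TRUE) / nfft
  y[seq_len(n)]
}

#' Resample a power envelope onto a coarser grid
#'
#' Linear interpolation of the envelope (and edge mask) onto a regular
#' `env_fs` grid spanning the same time range; used to standardize
#' envelopes to 250 Hz before windowing and ISC.
#'
#' @param series A `band_power_series`.
#' @param env_fs Target rate, Hz.
#' @return The resampled series.
#' @export
resample_envelope <- function(series, env_fs = 250) {
  if (series$fs <= env_fs) return(series)
  new_t <- seq(series$times[1], series$times[length(series$times)],
               by = 1 / env_fs)
  pw <- t(vapply(seq_len(nrow(series$power)), function(i) {
    approx(series$times, series$power[i, ], xout = new_t)$y
  }, numeric(length(new_t))))
  rownames(pw) <- series$channels
  edge <- approx(series$times, as.numeric(series$edge), xout = new_t)$y > 0
  series$power <- pw
  series$times <- new_t
  series$edge <- edge
  series$fs <- env_fs
  series$per_freq <- NULL
  series
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> subject %s, video %s: %d ch x %d samples at %g Hz\n",
              x$subject_id, x$video_id, nrow(x$power), ncol(x$power), x$fs))
  invisible(x)
}

#' Rolling-window grid
#'
#' The moment-to-moment analysis grid: half-open windows
#' `[0, length), [step, step + length), ...` truncated at
#' `min(duration, t_max)`. The default 5-s length and 1-s step with
#' `t_max = 63` gives the 59-window grid `[0,5) ... [58,63)`; the 3-s
#' robustness variant gives 61 windows.
#'
#' @param duration Available duration in seconds (must be >= `length`).
#' @param length Window length, seconds (default 5).
#' @param step Window step, seconds (default 1).
#' @param t_max Truncation point for aggregate analyses (default 63).
#' @return Object of class `rolling_windows`: data frame with `start`,
#'   `end` columns and the spec as attributes.
#' @export
make_windows <- function(duration, length = 5, step = 1, t_max = 63) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  end <- min(duration, t_max)
  if (length > end) stop("window length exceeds available duration", call. = FALSE)
  starts <- seq(0, end - length, by = step)
  out <- data.frame(start = starts, end = starts + length)
  structure(out, class = c("rolling_windows", "data.frame"),
            length = length, step = step, t_max = t_max)
}

#' Average an envelope inside each rolling window
#'
#' Per-window mean of the in-window envelope samples (half-open window,
#' post-onset times only); samples flagged as wavelet edge artifacts are
#' excluded. Errors if a window contains no valid samples.
#'
#' @param series A `band_power_series`.
#' @param windows A [make_windows()] grid.
#' @return `band_power_series` with one column per window (`times` are
#'   window starts; `windows` kept as an attribute).
#' @export
window_average <- function(series, windows) {
  if (max(windows$end) > max(series$times) + 1 / series$fs + 1e-9) {
    stop("series does not cover all windows", call. = FALSE)
  }
  pw <- matrix(NA_real_, nrow(series$power), nrow(windows),
               dimnames = list(series$channels, NULL))
  for (k in seq_len(nrow(windows))) {
    idx <- series$times >= windows$start[k] & series$times < windows$end[k] &
      !series$edge
    if (!any(idx)) stop("window with no valid samples: [", windows$start[k],
                        ", ", windows$end[k], ")", call. = FALSE)
    pw[, k] <- rowMeans(series$power[, idx, drop = FALSE])
  }
  out <- series
  out$power <- pw
  out$times <- windows$start
  out$edge <- rep(FALSE, nrow(windows))
  out$per_freq <- NULL
  attr(out, "windows") <- windows
  out
}
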