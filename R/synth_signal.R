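#' Pink (1/f^slope) noise
#'
#' Spectral-shaping generator: white Gaussian noise is transformed to the
#' frequency domain, amplitudes scaled by `f^(-slope/2)` (DC kept at the
#' first positive frequency's level), transformed back, and rescaled to
#' the requested standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param slope Spectral slope (power ~ 1/f^slope); 0 gives white noise.
#' @param sd Target standard deviation of the output.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, slope = 1, sd = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sd == 0) return(numeric(n))
  white <- rnorm(n)
  if (slope == 0) return(white * sd)
  spec <- fft(white)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  half <- freqs > fs / 2
  freqs[half] <- fs - freqs[half]            # fold to physical frequency
  f0 <- fs / n                                # lowest resolvable frequency
  gain <- pmax(freqs, f0)^(-slope / 2)
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Synthesize one channel of alpha-band EEG
#'
#' Signal model used by the study generator:
#' `x(t) = pink(t) + alpha_amp(t) * (1 + coupling * shared(t)) * carrier(t)`
#' where the carrier is a fixed-frequency alpha sinusoid with random phase.
#' The alpha-band power of the noiseless signal increases monotonically
#' with `alpha_amp`.
#'
#' @param duration Seconds (> 0).
#' @param fs Sampling rate, Hz (> 0).
#' @param alpha_amp Envelope of the alpha amplitude in microvolts: a scalar
#'   or a vector of `round(duration * fs)` samples.
#' @param shared Shared stimulus-locked envelope (same length convention as
#'   `alpha_amp`); 0 disables the common component.
#' @param coupling Coupling strength `kappa` applied to `shared`.
#' @param pink_slope,noise_sd Background-noise spectral slope and SD.
#' @param carrier_freq Alpha carrier frequency, Hz; default 10.
#' @param carrier_phase Carrier phase, radians; drawn uniformly if `NULL`.
#' @param seed Optional seed for a self-contained draw.
#' @return Numeric voltage series (microvolts) of `round(duration * fs)`
#'   samples.
#' @export
synthesize_channel_signal <- function(duration, fs, alpha_amp = 10,
                                      shared = 0, coupling = 0,
                                      pink_slope = 1, noise_sd = 10,
                                      carrier_freq = 10,
                                      carrier_phase = NULL, seed = NULL) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    amp <- rep_len(alpha_amp, n)
    sh <- rep_len(shared, n)
    phase <- carrier_phase %||% runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * carrier_freq * t + phase)
    noise <- if (noise_sd > 0) pink_noise(n, fs, pink_slope, noise_sd) else numeric(n)
    noise + amp * (1 + coupling * sh) * carrier
  })
}

#' Canonical blink template
#'
#' A smooth positive deflection (raised-cosine bump) of the given width,
#' peak-normalized to 1.
#'
#' @param fs Sampling rate, Hz.
#' @param width Seconds from onset to offset (default 0.3 s).
#' @return Numeric vector (one blink, peak 1).
#' @export
blink_template <- function(fs, width = 0.3) {
  n <- max(3L, round(width * fs))
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Inject eye blinks into a recording
#'
#' Adds Poisson-timed blink deflections to the EOG channel and, with fixed
#' attenuation gains, to Fp1 and Fp2. Blink times are returned so recovery
#' tests can use them as ground truth.
#'
#' @param recording An [eeg_recording()]; must contain an "EOG" channel.
#' @param rate Blink events per minute (0 leaves the recording unchanged).
#' @param amplitude Peak EOG amplitude, microvolts.
#' @param template Blink waveform (peak-normalized); default
#'   [blink_template()].
#' @param gains Named per-channel gains applied to the template.
#' @param seed Optional seed.
#' @return The recording with blinks added; blink onset samples are in
#'   `attr(, "blink_onsets")`.
#' @export
inject_blinks <- function(recording, rate, amplitude = 120,
                          template = NULL,
                          gains = c(EOG = 1, Fp1 = 0.45, Fp2 = 0.45),
                          seed = NULL) {
  if (!"EOG" %in% recording$channels) {
    stop("recording has no EOG channel", call. = FALSE)
  }
  if (rate == 0) {
    attr(recording, "blink_onsets") <- integer()
    return(recording)
  }
  with_seed(seed, {
    tpl <- template %||% blink_template(recording$fs)
    n <- ncol(recording$data)
    n_blinks <- stats::rpois(1, rate * n / recording$fs / 60)
    onsets <- sort(sample.int(max(1L, n - length(tpl)), n_blinks, replace = TRUE))
    for (ch in intersect(names(gains), recording$channels)) {
      row <- match(ch, recording$channels)
      for (o in onsets) {
        idx <- o:(o + length(tpl) - 1)
        recording$data[row, idx] <- recording$data[row, idx] +
          gains[[ch]] * amplitude * tpl
      }
    }
    attr(recording, "blink_onsets") <- onsets
    recording
  })
}

# Smooth positive low-frequency (< cutoff Hz) envelope process, mean ~ 1.
# exp(z/2) of lowpassed unit-variance Gaussian noise.
smooth_positive_process <- function(n, fs, cutoff = 0.7) {
  z <- lowpass_fft(rnorm(n), fs, cutoff)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  exp(z / 2)
}

# Smooth zero-mean low-frequency process with the requested SD.
smooth_noise_process <- function(n, fs, cutoff = 0.7, sd = 1) {
  z <- lowpass_fft(rnorm(n), fs, cutoff)
  s <- stats::sd(z)
  if (s > 0) z <- z * (sd / s)
  z
}

# Brick-wall FFT lowpass (generator-internal; analysis filtering uses the
# FIR path in preprocess.R).
lowpass_fft <- function(x, fs, cutoff) {
  n <- length(x)
  spec <- fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  half <- freqs > fs / 2
  freqs[half] <- fs - freqs[half]
  spec[freqs > cutoff] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}
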