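#' Default 10-20 montage used by the synthetic study
#'
#' Nineteen EEG electrodes of the international 10-20 system plus one EOG
#' channel, in the order the generator lays them out.
#'
#' @return Character vector of 20 channel labels ("EOG" last).
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2", "EOG")
}

#' Configuration of a synthetic EEG study
#'
#' Bundles every tunable of the synthetic-study generator: design size,
#' signal model, behavioral-rating model, population raters, and outcome
#' model. Defaults emulate the target study design: 28 subjects watching
#' 14 videos of 63-112 s (mean about 85 s), 20-channel 10-20 EEG plus EOG
#' at 256 Hz, alpha band 8-13 Hz, 497 population raters per video.
#'
#' The signal model couples a latent per-video standardized interest level
#' `I_v` to (a) the F3/F4 alpha-amplitude ratio via `faa_gain` (boosted by
#' `faa_early_boost` in the first 10 s) and (b) a shared stimulus-locked
#' low-frequency envelope on mid-central channels whose coupling is
#' `isc_base + isc_deal_gain * deal * ramp(t)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_videos Number of videos.
#' @param video_durations Seconds per video; `NULL` draws them uniformly in
#'   63-108 s at generation time. All durations must be >= 63 s.
#' @param fs Sampling rate in Hz; must exceed twice the upper alpha edge.
#' @param channels Ordered channel labels; must contain "EOG", "F3", "F4".
#' @param alpha_band Length-2 Hz band inside (0.3, 50).
#' @param faa_gain Dimensionless FAA-interest coupling `a1` (0 = null).
#' @param faa_early_boost Multiplier on `faa_gain` for t < 10 s.
#' @param isc_base,isc_deal_gain Envelope coupling strengths `kappa0`,
#'   `kappa1` (both >= 0).
#' @param ramp_shape Monotone function mapping normalized time in `[0,1]`
#'   to `[0,1]`; default identity (linear ramp).
#' @param alpha_amp Base alpha oscillation amplitude, microvolts.
#' @param noise_sd Pink-noise standard deviation, microvolts.
#' @param pink_slope Spectral slope of the background noise (power ~ 1/f^slope).
#' @param noise_shared_frac Fraction of background-noise variance shared
#'   across a subject's EEG channels (volume conduction), in `[0, 1)`.
#' @param env_noise_sd SD of each channel's private low-frequency envelope
#'   modulation (dimensionless, relative to `alpha_amp`).
#' @param rating_noise_sd Occasion noise SD of the latent rating score.
#' @param subject_sd SD of per-subject rating offsets.
#' @param interest_slope Slope `b` of the latent rating score on `I_v`.
#' @param pop_n Population raters per video (>= 1).
#' @param deal_logit Length-2 `(gamma0, gamma1)` of the deal logit on `I_v`.
#' @param amount_scale USD scale of funded amounts
#'   (`amount = amount_scale * exp(0.5 I_v + eps)`).
#' @param blink_rate Blink events per minute on EOG/Fp1/Fp2.
#' @param truncate_subject Index of one subject to truncate to 10 videos
#'   (0 = none), mirroring a missing-data path.
#' @param seed Integer seed; the whole study is a pure function of the
#'   config including this seed.
#'
#' @return An object of class `sim_config` (validated list).
#' @seealso [generate_study()], [preset_strong()]
#' @export
sim_config <- function(n_subjects = 28,
                       n_videos = 14,
                       video_durations = NULL,
                       fs = 256,
                       channels = default_channels(),
                       alpha_band = c(8, 13),
                       faa_gain = 0.4,
                       faa_early_boost = 2.5,
                       isc_base = 0.15,
                       isc_deal_gain = 0.9,
                       ramp_shape = identity,
                       alpha_amp = 10,
                       noise_sd = 10,
                       pink_slope = 1,
                       noise_shared_frac = 0.7,
                       env_noise_sd = 0.3,
                       rating_noise_sd = 0.5,
                       subject_sd = 0.5,
                       interest_slope = 0.8,
                       pop_n = 497,
                       deal_logit = c(0.3, 1.0),
                       amount_scale = 312000,
                       blink_rate = 12,
                       truncate_subject = 0L,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_videos = as.integer(n_videos),
    video_durations = video_durations, fs = fs, channels = channels,
    alpha_band = alpha_band, faa_gain = faa_gain,
    faa_early_boost = faa_early_boost, isc_base = isc_base,
    isc_deal_gain = isc_deal_gain, ramp_shape = ramp_shape,
    alpha_amp = alpha_amp, noise_sd = noise_sd, pink_slope = pink_slope,
    noise_shared_frac = noise_shared_frac,
    env_noise_sd = env_noise_sd, rating_noise_sd = rating_noise_sd,
    subject_sd = subject_sd, interest_slope = interest_slope,
    pop_n = as.integer(pop_n), deal_logit = deal_logit,
    amount_scale = amount_scale, blink_rate = blink_rate,
    truncate_subject = as.integer(truncate_subject),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 2) stop_field("n_subjects", "need >= 2 subjects")
  if (cfg$n_videos < 1) stop_field("n_videos", "need >= 1 video")
  if (!is.null(cfg$video_durations)) {
    if (length(cfg$video_durations) != cfg$n_videos) {
      stop_field("video_durations", "length must equal n_videos")
    }
    if (any(cfg$video_durations < 63)) {
      stop_field("video_durations", "all durations must be >= 63 s")
    }
  }
  if (length(cfg$alpha_band) != 2 || cfg$alpha_band[1] >= cfg$alpha_band[2]) {
    stop_field("alpha_band", "must be an increasing pair")
  }
  if (cfg$alpha_band[1] <= 0.3 || cfg$alpha_band[2] >= 50) {
    stop_field("alpha_band", "must lie inside (0.3, 50) Hz")
  }
  if (cfg$fs <= 2 * cfg$alpha_band[2]) {
    stop_field("fs", "sampling rate must exceed twice the upper band edge")
  }
  if (anyDuplicated(cfg$channels)) stop_field("channels", "labels must be unique")
  for (need in c("EOG", "F3", "F4")) {
    if (!need %in% cfg$channels) {
      stop_field("channels", paste("must contain", need))
    }
  }
  if (cfg$pop_n < 1) stop_field("pop_n", "need >= 1 population rater")
  if (cfg$isc_base < 0 || cfg$isc_deal_gain < 0) {
    stop_field("isc_base", "coupling strengths must be >= 0")
  }
  if (!is.function(cfg$ramp_shape)) stop_field("ramp_shape", "must be a function")
  if (cfg$blink_rate < 0) stop_field("blink_rate", "must be >= 0")
  if (cfg$noise_shared_frac < 0 || cfg$noise_shared_frac >= 1) {
    stop_field("noise_shared_frac", "must lie in [0, 1)")
  }
  if (cfg$truncate_subject < 0 || cfg$truncate_subject > cfg$n_subjects) {
    stop_field("truncate_subject", "must index a subject or be 0")
  }
  cfg
}

#' Strong-effect preset of the synthetic study
#'
#' Convenience constructor: [sim_config()] with couplings at the documented
#' "strong" preset (`faa_gain = 0.4`, `faa_early_boost = 2.5`,
#' `isc_deal_gain = 0.9`), used throughout the recovery tests.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_strong <- function(...) {
  sim_config(faa_gain = 0.4, faa_early_boost = 2.5,
             isc_base = 0.15, isc_deal_gain = 0.9, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects x %d videos, fs = %g Hz, %d channels\n",
              x$n_subjects, x$n_videos, x$fs, length(x$channels)))
  cat(sprintf("  alpha %g-%g Hz | faa_gain %g (x%g < 10 s) | kappa0 %g, kappa1 %g | seed %d\n",
              x$alpha_band[1], x$alpha_band[2], x$faa_gain, x$faa_early_boost,
              x$isc_base, x$isc_deal_gain, x$seed))
  invisible(x)
}
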