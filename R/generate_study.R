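#' Generate a complete synthetic EEG study
#'
#' Produces, from a single seed, everything a real study would ship:
#' continuous per-subject EEG recordings with video-onset events, the
#' behavioral and outcome tables, and the latent ground truth that the
#' recovery tests check against.
#'
#' Generative model, per video `v` with latent standardized interest
#' `I_v ~ N(0, 1)`:
#' \itemize{
#'   \item Deal: `D_v ~ Bernoulli(plogis(gamma0 + gamma1 I_v))`; funded
#'     amount `amount_scale * exp(0.5 I_v + eps)`, 0 otherwise.
#'   \item Asymmetry: F3/F4 alpha amplitudes scaled by `(1 -/+ A_v(t)/2)`
#'     with `A_v(t) = faa_gain * I_v * (faa_early_boost if t < 10 s else 1)`
#'     (clamped to `[-1.6, 1.6]`), so positive interest lowers left (F3)
#'     alpha power and raises FAA = log P(F4) - log P(F3).
#'   \item Shared envelope: a smoothed positive (< 0.7 Hz) process common
#'     to all subjects for a video, injected on Cz/C3/C4 with coupling
#'     `kappa_v(t) = isc_base + isc_deal_gain * D_v * ramp(t / duration)`,
#'     reproducing a funded/unfunded ISC divergence that grows over time.
#'   \item Ratings: five 7-point items around a latent score
#'     `mu + b I_v + u_s + eps`, item noise calibrated so Cronbach's alpha
#'     is about 0.90; 14 DC items around a subject trait (alpha about
#'     0.88); a binary deal prediction; population interest as the mean of
#'     `pop_n` simulated raters per video.
#' }
#' Video order is randomized per subject; every channel rides on pink
#' noise and a private low-frequency envelope; blinks land on EOG/Fp1/Fp2.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `recordings`
#'   (list of [eeg_recording()]), `tables` (class `study_tables`: ratings,
#'   population, outcomes, sentiment data frames), and `truth` (class
#'   `ground_truth`: latent interest, deals, amounts, per-video asymmetry
#'   and coupling trajectories at 1 Hz, shared envelopes at 8 Hz, subject
#'   offsets, video orders, blink onsets).
#' @examples
#' study <- generate_study(sim_config(n_subjects = 2, n_videos = 2,
#'                                    video_durations = c(63, 63),
#'                                    fs = 128, pop_n = 25, seed = 7))
#' study$tables$outcomes
#' @export
generate_study <- function(config) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, {
    nv <- cfg$n_videos
    ns <- cfg$n_subjects
    fs <- cfg$fs
    durations <- cfg$video_durations %||% round(runif(nv, 63, 108))
    video_ids <- sprintf("v%02d", seq_len(nv))
    subject_ids <- sprintf("s%02d", seq_len(ns))

    interest <- rnorm(nv)
    if (nv > 1) interest <- as.numeric(scale(interest))  # standardized I_v
    deal <- rbinom(nv, 1, plogis(cfg$deal_logit[1] + cfg$deal_logit[2] * interest))
    amount <- ifelse(deal == 1,
                     cfg$amount_scale * exp(0.5 * interest + rnorm(nv, 0, 0.25)),
                     0)

    # Per-video shared envelope (common to all subjects) and trajectories.
    shared <- vector("list", nv)
    traj <- vector("list", nv)
    for (v in seq_len(nv)) {
      n_v <- round(durations[v] * fs)
      shared[[v]] <- smooth_positive_process(n_v, fs)
      tt <- seq(0, durations[v] - 1)
      A <- clamp(cfg$faa_gain * interest[v] *
                   ifelse(tt < 10, cfg$faa_early_boost, 1), -1.6, 1.6)
      kap <- cfg$isc_base +
        cfg$isc_deal_gain * deal[v] * cfg$ramp_shape(tt / durations[v])
      traj[[v]] <- data.frame(time = tt, asym = A, coupling = kap)
    }

    u_s <- rnorm(ns, 0, cfg$subject_sd)

    lead_in <- 5; gap <- 2
    central <- intersect(c("Cz", "C3", "C4"), cfg$channels)
    recordings <- vector("list", ns)
    orders <- vector("list", ns)
    blink_onsets <- vector("list", ns)
    for (s in seq_len(ns)) {
      order_v <- sample.int(nv)
      if (s == cfg$truncate_subject && nv > 10) order_v <- order_v[1:10]
      orders[[s]] <- order_v
      rec <- build_recording(cfg, subject_ids[s], order_v, video_ids,
                             durations, shared, interest, deal,
                             lead_in, gap, central)
      rec <- inject_blinks(rec, cfg$blink_rate)
      blink_onsets[[s]] <- attr(rec, "blink_onsets")
      recordings[[s]] <- rec
    }
    names(recordings) <- subject_ids

    tables <- build_tables(cfg, subject_ids, video_ids, orders, interest,
                           deal, amount, u_s)

    truth <- structure(list(
      video_id = video_ids, interest = interest, deal = deal,
      amount = amount, durations = durations, trajectories = traj,
      shared = lapply(shared, function(x) x[seq(1, length(x), by = max(1, round(fs / 8)))]),
      subject_offsets = setNames(u_s, subject_ids),
      video_order = setNames(orders, subject_ids),
      blink_onsets = setNames(blink_onsets, subject_ids)
    ), class = "ground_truth")

    structure(list(recordings = recordings, tables = tables, truth = truth,
                   config = cfg),
              class = "synthetic_study")
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# One subject's continuous recording: per-channel pink noise plus an alpha
# carrier whose envelope carries the asymmetry / shared-coupling structure
# inside video spans and rests at baseline in the gaps.
build_recording <- function(cfg, subject_id, order_v, video_ids, durations,
                            shared, interest, deal, lead_in, gap, central) {
  fs <- cfg$fs
  n_gap <- round(gap * fs)
  n_lead <- round(lead_in * fs)
  n_vid <- round(durations * fs)
  onsets <- integer(length(order_v))                # 0-based
  pos <- n_lead
  for (k in seq_along(order_v)) {
    onsets[k] <- pos
    pos <- pos + n_vid[order_v[k]] + n_gap
  }
  n_total <- pos
  t_all <- (seq_len(n_total) - 1) / fs

  # Shared envelope and coupling laid out on this subject's timeline
  # (identical across subjects up to video order).
  shared_t <- numeric(n_total)
  coupling_t <- numeric(n_total)
  asym_t <- numeric(n_total)
  for (k in seq_along(order_v)) {
    v <- order_v[k]
    idx <- onsets[k] + seq_len(n_vid[v])            # 1-based span
    shared_t[idx] <- shared[[v]]
    tv <- (seq_len(n_vid[v]) - 1) / fs
    coupling_t[idx] <- cfg$isc_base +
      cfg$isc_deal_gain * deal[v] * cfg$ramp_shape(tv / durations[v])
    asym_t[idx] <- clamp(cfg$faa_gain * interest[v] *
                           ifelse(tv < 10, cfg$faa_early_boost, 1), -1.6, 1.6)
  }

  data <- matrix(0, nrow = length(cfg$channels), ncol = n_total,
                 dimnames = list(cfg$channels, NULL))
  # Volume conduction: part of the broadband background is common to all
  # of a subject's EEG channels, so neighboring channels correlate as
  # they do in real recordings.
  common <- pink_noise(n_total, fs, cfg$pink_slope,
                       cfg$noise_sd * sqrt(cfg$noise_shared_frac))
  private_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_shared_frac)
  # One coherent alpha rhythm per subject (random frequency and phase),
  # seen by every channel with a small phase lag: nearby electrodes then
  # correlate as in real recordings while amplitude envelopes stay
  # channel-specific.
  f_alpha <- runif(1, 9, 11)
  phase0 <- runif(1, 0, 2 * pi)
  for (ch in cfg$channels) {
    if (ch == "EOG") {
      data[ch, ] <- pink_noise(n_total, fs, cfg$pink_slope, 5)
      next
    }
    eta <- smooth_noise_process(n_total, fs, sd = cfg$env_noise_sd)
    amp <- cfg$alpha_amp * pmax(0.05, 1 + eta)
    if (ch == "F3") amp <- amp * (1 - asym_t / 2)
    if (ch == "F4") amp <- amp * (1 + asym_t / 2)
    kap <- if (ch %in% central) coupling_t else 0
    carrier <- sin(2 * pi * f_alpha * t_all + phase0 + rnorm(1, 0, 0.3))
    noise <- common + pink_noise(n_total, fs, cfg$pink_slope, private_sd)
    data[ch, ] <- noise + amp * (1 + kap * shared_t) * carrier
  }

  events <- data.frame(video_id = video_ids[order_v],
                       onset_sample = onsets,
                       duration = durations[order_v])
  eeg_recording(subject_id, cfg$channels, fs, data, events)
}

# Behavioral, population, outcome, and sentiment tables.
build_tables <- function(cfg, subject_ids, video_ids, orders, interest,
                         deal, amount, u_s) {
  nv <- cfg$n_videos
  ns <- cfg$n_subjects
  b <- cfg$interest_slope
  mu <- 4

  # Item noise calibrated to a target Cronbach's alpha given the latent
  # score variance: alpha = k rho / (1 + (k-1) rho), rho the inter-item r.
  item_sd_for <- function(k, target_alpha, var_true) {
    rho <- target_alpha / (k - (k - 1) * target_alpha)
    sqrt(var_true * (1 - rho) / rho)
  }
  var_true <- b^2 + cfg$subject_sd^2 + cfg$rating_noise_sd^2
  sd_q <- item_sd_for(5, 0.90, var_true)
  sd_dc <- item_sd_for(14, 0.88, 0.8^2)

  rows <- list()
  for (s in seq_len(ns)) {
    dc_trait <- mu + rnorm(1, 0, 0.8)
    dc_items <- clamp(round(dc_trait + rnorm(14, 0, sd_dc)), 1, 7)
    age <- clamp(round(rnorm(1, 29.4, 10.9)), 18, 70)
    gender <- sample(c("F", "M"), 1)
    for (v in orders[[s]]) {
      latent <- mu + b * interest[v] + u_s[s] + rnorm(1, 0, cfg$rating_noise_sd)
      q <- clamp(round(latent + rnorm(5, 0, sd_q)), 1, 7)
      pred <- rbinom(1, 1, plogis(0.9 * interest[v]))
      row <- data.frame(subject_id = subject_ids[s], video_id = video_ids[v],
                        t(setNames(q, paste0("q", 1:5))),
                        deal_prediction = pred,
                        t(setNames(dc_items, paste0("dc", 1:14))),
                        age = age, gender = gender)
      rows[[length(rows) + 1]] <- row
    }
  }
  ratings <- do.call(rbind, rows)
  ratings <- ratings[order(ratings$subject_id, ratings$video_id), ]
  rownames(ratings) <- NULL

  pop <- vapply(seq_len(nv), function(v) {
    mean(clamp(mu + b * interest[v] + rnorm(cfg$pop_n, 0, 1), 1, 7))
  }, numeric(1))
  population <- data.frame(video_id = video_ids, pop_interest = pop)

  outcomes <- data.frame(video_id = video_ids, deal = deal, amount = amount)

  sentiment <- data.frame(
    video_id = video_ids,
    joy = pmax(0, 0.10 + 0.01 * interest + rnorm(nv, 0, 0.03)),
    trust = pmax(0, 0.12 + 0.01 * interest + rnorm(nv, 0, 0.03)),
    positive = pmax(0, 0.55 + 0.02 * interest + rnorm(nv, 0, 0.08)),
    negative = pmax(0, 0.12 + rnorm(nv, 0, 0.04)),
    word_count = pmax(40, round(170 + 10 * interest + rnorm(nv, 0, 15)))
  )

  structure(list(ratings = ratings, population = population,
                 outcomes = outcomes, sentiment = sentiment),
            class = "study_tables")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d recordings, %d videos (%d funded), seed %d\n",
              length(x$recordings), x$config$n_videos,
              sum(x$truth$deal), x$config$seed))
  invisible(x)
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> ratings %d rows, %d videos; mean amount $%.0f\n",
              nrow(x$ratings), nrow(x$outcomes),
              mean(x$outcomes$amount[x$outcomes$deal == 1])))
  invisible(x)
}
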