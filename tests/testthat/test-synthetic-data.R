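test_that("config validation errors name the offending field", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(video_durations = rep(50, 14)), "video_durations")
  expect_error(sim_config(alpha_band = c(13, 8)), "alpha_band")
  expect_error(sim_config(alpha_band = c(8, 60)), "alpha_band")
  expect_error(sim_config(fs = 20), "fs")
  expect_error(sim_config(pop_n = 0), "pop_n")
  expect_error(sim_config(channels = c("F3", "F4", "Cz")), "EOG")
  expect_error(sim_config(isc_base = -1), "isc_base")
  expect_error(sim_config(noise_shared_frac = 1), "noise_shared_frac")
})

test_that("identical config and seed give byte-identical studies", {
  cfg <- quick_cfg(7, n_subjects = 2, n_videos = 2)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$recordings[[2]]$events, b$recordings[[2]]$events)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$interest, b$truth$interest)
})

test_that("tables respect design invariants", {
  study <- generate_study(quick_cfg(11, n_subjects = 3, n_videos = 5))
  tab <- study$tables
  q <- as.matrix(tab$ratings[, paste0("q", 1:5)])
  expect_true(all(q >= 1 & q <= 7))
  expect_true(all(tab$ratings$deal_prediction %in% c(0, 1)))
  expect_identical(nrow(tab$population), 5L)
  expect_true(all(tab$population$pop_interest >= 1 &
                    tab$population$pop_interest <= 7))
  # funded <=> positive amount
  expect_identical(tab$outcomes$amount > 0, tab$outcomes$deal == 1)
  # one recording per subject, all videos present with onset events
  expect_length(study$recordings, 3)
  expect_setequal(study$recordings[[1]]$events$video_id,
                  sprintf("v%02d", 1:5))
})

test_that("a truncated subject watches only ten videos", {
  cfg <- quick_cfg(3, n_subjects = 2, n_videos = 12, truncate_subject = 1)
  study <- generate_study(cfg)
  expect_identical(nrow(study$recordings[[1]]$events), 10L)
  expect_identical(nrow(study$recordings[[2]]$events), 12L)
})

test_that("channel synthesis obeys its limit cases", {
  # silent channel
  expect_identical(synthesize_channel_signal(2, 128, alpha_amp = 0,
                                             noise_sd = 0, seed = 1),
                   numeric(256))
  # pure alpha oscillation concentrates Welch power in the alpha band
  x <- synthesize_channel_signal(8, 128, alpha_amp = 1, noise_sd = 0,
                                 carrier_freq = 10, carrier_phase = 0)
  p <- welch_psd(x, 128)
  bands <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30),
                gamma = c(31, 45))
  bp <- vapply(bands, function(b) {
    mean(p$psd[p$freq >= b[1] & p$freq <= b[2]])
  }, numeric(1))
  expect_gt(bp["alpha"], 50 * max(bp[c("theta", "beta", "gamma")]))
  # alpha-band power grows monotonically with the envelope amplitude
  pw <- vapply(c(1, 2, 4), function(a) {
    welch_band_power(matrix(synthesize_channel_signal(
      8, 128, alpha_amp = a, noise_sd = 0, carrier_freq = 10,
      carrier_phase = 0), 1), fs = 128)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(synthesize_channel_signal(0, 128), "duration")
  expect_error(synthesize_channel_signal(1, -5), "fs")
})

test_that("full coupling with a common envelope drives envelope correlation to 1", {
  fs <- 128
  set.seed(4)
  sh <- neuroforecast:::smooth_positive_process(63 * fs, fs)
  envs <- lapply(c(0.1, 0.9), function(phase) {
    x <- synthesize_channel_signal(63, fs, alpha_amp = 10, shared = sh,
                                   coupling = 1, noise_sd = 0,
                                   carrier_phase = phase)
    morlet_alpha_envelope(signal_epoch(x, fs))
  })
  r <- cor(envs[[1]]$power[1, !envs[[1]]$edge],
           envs[[2]]$power[1, !envs[[2]]$edge])
  expect_gt(r, 0.99)
})

test_that("blink injection matches its rate and is removable", {
  cfg <- quick_cfg(5, n_subjects = 2, n_videos = 1, blink_rate = 0,
                   channels = c("Fp1", "Fp2", "F3", "F4", "Cz", "EOG"))
  rec <- generate_study(cfg)$recordings[[1]]
  # rate 0: unchanged
  rec0 <- inject_blinks(rec, rate = 0)
  expect_identical(rec0$data, rec$data)
  # ~15 events/min expected on this ~73-s recording
  rec15 <- inject_blinks(rec, rate = 15, seed = 2)
  n_blinks <- length(attr(rec15, "blink_onsets"))
  expect_gt(n_blinks, 4)
  expect_lt(n_blinks, 40)
  # EOG regression reduces the frontal-EOG coupling the blinks create
  ep <- epoch_by_events(rec15)[[1]]
  eog <- ep$data["EOG", ]
  r_before <- abs(cor(ep$data["Fp1", ], eog))
  expect_gt(r_before, 0.3)
  clean <- remove_eog(ep)
  r_after <- abs(cor(clean$data["Fp1", ], eog))
  expect_lt(r_after, r_before)
  expect_lt(r_after, 0.05)
  # missing EOG channel is an error
  no_eog <- eeg_recording("s", "F3", 128, matrix(0, 1, 128),
                          data.frame(video_id = character(),
                                     onset_sample = integer(),
                                     duration = numeric()))
  expect_error(inject_blinks(no_eog, rate = 1), "EOG")
})

test_that("downstream FAA-interest coupling is monotone in the asymmetry gain", {
  gains <- c(0, 0.25, 0.6)
  seeds <- 1:20
  mean_cor <- vapply(gains, function(g) {
    mean(vapply(seeds, function(s) {
      study <- generate_study(quick_cfg(s, n_subjects = 3, n_videos = 6,
                                        faa_gain = g, blink_rate = 0))
      faa_sv <- vapply(study$recordings, function(rec) {
        eps <- epoch_by_events(rec)
        vids <- vapply(eps, `[[`, character(1), "video_id")
        vapply(eps[order(vids)], function(ep) {
          bp <- welch_band_power(ep)
          as.numeric(faa(bp[["F3"]], bp[["F4"]]))
        }, numeric(1))
      }, numeric(6))
      cor(rowMeans(faa_sv), study$truth$interest)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
  expect_lt(abs(mean_cor[1]), 0.35)   # null gain: correlation near zero
  expect_gt(mean_cor[3], 0.8)
})

test_that("late-video ISC gap between funded and unfunded grows with the deal gain", {
  gains <- c(0, 0.5, 1.2)
  seeds <- 1:20
  w <- make_windows(63)
  late <- w[w$start >= 48, ]
  mean_gap <- vapply(gains, function(g) {
    gaps <- vapply(seeds, function(s) {
      study <- generate_study(quick_cfg(s, n_subjects = 3, n_videos = 6,
                                        channels = isc_channels,
                                        isc_deal_gain = g, blink_rate = 0))
      deal <- study$truth$deal
      if (all(deal == 1) || all(deal == 0)) return(NA_real_)
      envs <- envelopes_by_video(study, isc_channels, c("Cz", "C3", "C4"),
                                 preprocess = FALSE)
      isc_late <- vapply(envs, function(e) mean(isc_series(e, late)$mean_isc),
                         numeric(1))
      mean(isc_late[deal == 1]) - mean(isc_late[deal == 0])
    }, numeric(1))
    mean(gaps, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_gap) > 0))
  expect_lt(abs(mean_gap[1]), 0.1)    # null gain: no funded/unfunded gap
  expect_gt(mean_gap[3], 0.2)
})
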