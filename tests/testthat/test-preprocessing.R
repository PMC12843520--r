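make_rec <- function(data, fs = 256, events = NULL, channels = NULL) {
  channels <- channels %||% paste0("ch", seq_len(nrow(data)))
  events <- events %||% data.frame(video_id = "v01",
                                   onset_sample = round(0.5 * fs),
                                   duration = floor(nrow(t(data)) / fs) - 1)
  eeg_recording("s01", channels, fs, data, events)
}

test_that("band-pass keeps alpha, rejects line noise and DC", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  trim <- seq(4 * fs, 16 * fs)            # steady-state region
  x60 <- sin(2 * pi * 60 * t)
  x10 <- sin(2 * pi * 10 * t)
  dc <- rep(3, length(t))
  rec <- make_rec(rbind(x60, x10, dc), fs,
                  events = data.frame(video_id = "v01", onset_sample = 256,
                                      duration = 10))
  out <- bandpass(rec)
  expect_lt(sd(out$data[1, trim]), 0.05 * sd(x60))        # 60 Hz crushed
  expect_lt(abs(sd(out$data[2, trim]) / sd(x10[trim]) - 1), 0.05)
  expect_lt(max(abs(out$data[3, trim])), 1e-6)            # DC removed
  expect_error(bandpass(rec, high = 130), "Nyquist")
  expect_error(bandpass(rec, low = 55, high = 50), "low")
})

test_that("band-pass filtering is zero-phase", {
  fs <- 128
  n <- 63 * fs
  x <- numeric(n)
  x[30 * fs] <- 1                          # impulse at t = 30 s
  rec <- make_rec(rbind(x, x, x), fs,
                  events = data.frame(video_id = "v01", onset_sample = 128,
                                      duration = 60))
  y <- bandpass(rec)$data[1, ]
  expect_equal(which.max(abs(y)), 30 * fs)
})

test_that("epoching is half-open, onset-anchored, and bounds-checked", {
  fs <- 250
  n <- 40 * fs
  data <- matrix(rep(seq_len(n), each = 2), nrow = 2)
  events <- data.frame(video_id = sprintf("v%02d", 1:14),
                       onset_sample = seq(100, by = 600, length.out = 14),
                       duration = rep(2, 14))
  rec <- make_rec(data, fs, events)
  eps <- epoch_by_events(rec)
  expect_length(eps, 14)                   # fourteen videos, fourteen epochs
  ep <- eps[[1]]
  expect_equal(ncol(ep$data), round(0.2 * fs) + round(2 * fs))
  # sample at time 0 is the onset sample (0-based onset 100 -> value 101)
  expect_equal(unname(ep$data[1, round(0.2 * fs) + 1]), 101)
  expect_equal(min(abs(epoch_times(ep))), 0)
  # no room for the baseline: error names the video
  bad <- make_rec(data, fs, data.frame(video_id = "vX", onset_sample = 0,
                                       duration = 2))
  expect_error(epoch_by_events(bad), "vX")
})

test_that("bad-channel detection flags noise and flat lines, never EOG", {
  fs <- 128
  set.seed(9)
  base <- sin(2 * pi * 10 * (0:(10 * fs - 1)) / fs) + rnorm(10 * fs, 0, 0.2)
  mk <- function(rows) video_epoch("s", "v", fs, do.call(rbind, rows),
                                   names(rows), baseline = 0)
  same <- mk(list(F3 = base, F4 = base, Cz = base, C4 = base, Pz = base))
  expect_identical(detect_bad_channels(same), character())
  noisy <- mk(list(F3 = base, F4 = base, Cz = base, C4 = base,
                   Pz = rnorm(10 * fs, 0, 10 * sd(base))))
  expect_identical(detect_bad_channels(noisy), "Pz")
  flat <- mk(list(F3 = base, F4 = base, Cz = base, C4 = base,
                  Pz = rep(0, 10 * fs)))
  expect_identical(detect_bad_channels(flat), "Pz")
  with_eog <- mk(list(F3 = base, F4 = base, Cz = base, C4 = base,
                      EOG = rnorm(10 * fs, 0, 50)))
  expect_false("EOG" %in% detect_bad_channels(with_eog))
  expect_error(detect_bad_channels(mk(list(F3 = base, F4 = base))), "4 EEG")
})

test_that("interpolation replaces a bad channel by its neighbor mean", {
  fs <- 100
  n <- 200
  ep <- video_epoch("s", "v", fs,
                    rbind(Fp1 = rep(1, n), Fz = rep(2, n), C3 = rep(3, n),
                          F7 = rep(4, n), F3 = rnorm(n, 0, 100)),
                    c("Fp1", "Fz", "C3", "F7", "F3"), baseline = 0)
  fixed <- interpolate_bad_channels(ep, "F3")
  expect_equal(unname(fixed$data["F3", ]), rep(2.5, n))    # mean(1,2,3,4)
  expect_identical(fixed$bad_channels, "F3")
  # no bads: unchanged
  expect_identical(interpolate_bad_channels(ep, character())$data, ep$data)
  # interpolated variance bounded by neighborhood variance
  set.seed(21)
  ep2 <- video_epoch("s", "v", fs,
                     rbind(Fp1 = rnorm(n), Fz = rnorm(n), C3 = rnorm(n),
                           F7 = rnorm(n), F3 = rnorm(n, 0, 50)),
                     c("Fp1", "Fz", "C3", "F7", "F3"), baseline = 0)
  fixed2 <- interpolate_bad_channels(ep2, "F3")
  expect_lte(var(fixed2$data["F3", ]),
             max(apply(ep2$data[c("Fp1", "Fz", "C3", "F7"), ], 1, var)))
  expect_error(interpolate_bad_channels(ep, ep$channels), "all channels bad")
})

test_that("EOG regression cleans contaminated channels and spares the rest", {
  fs <- 128
  n <- 30 * fs
  set.seed(12)
  eog <- rnorm(n)
  contaminated <- 0.8 * eog + rnorm(n)
  # construct a channel exactly orthogonal to EOG (z below any threshold)
  indep <- rnorm(n)
  indep <- indep - sum(indep * eog) / sum(eog^2) * eog
  ep <- video_epoch("s", "v", fs,
                    rbind(F3 = contaminated, F4 = indep, EOG = eog),
                    c("F3", "F4", "EOG"), baseline = 0)
  clean <- remove_eog(ep)
  expect_false("EOG" %in% clean$channels)
  expect_lt(abs(cor(clean$data["F3", ], eog)), 0.05)
  expect_identical(clean$data["F4", ], ep$data["F4", ])
  expect_true(clean$cleaned)
  # zero EOG: EEG unchanged
  ep0 <- video_epoch("s", "v", fs, rbind(F3 = contaminated, EOG = rep(0, n)),
                     c("F3", "EOG"), baseline = 0)
  expect_identical(remove_eog(ep0)$data["F3", ], contaminated)
  expect_error(remove_eog(clean), "EOG")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  fs <- 100
  ep <- video_epoch("s", "v", fs,
                    rbind(a = rep(5, 300), b = 1 + sin(2 * pi * 10 * (0:299) / fs)),
                    c("a", "b"), baseline = 0.2)
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data["a", ])), 0)
  idx <- epoch_times(bc) < 0
  expect_lt(max(abs(rowMeans(bc$data[, idx]))), 1e-12)
  expect_equal(baseline_correct(bc)$data, bc$data)
  expect_error(baseline_correct(ep, c(-0.5, -0.4)), "empty")
})

test_that("the full pipeline preserves structure and introduces no NaN", {
  study <- generate_study(quick_cfg(6, n_subjects = 2, n_videos = 2,
                                    channels = c("Fp1", "Fp2", "F3", "F4",
                                                 "Cz", "EOG"),
                                    blink_rate = 20))
  eps <- preprocess_recording(study$recordings[[1]])
  expect_length(eps, 2)
  for (ep in eps) {
    expect_true(all(is.finite(ep$data)))
    expect_identical(ep$channels, c("Fp1", "Fp2", "F3", "F4", "Cz"))
    expect_identical(ep$fs, 128)
    expect_true(ep$cleaned)
    expect_type(attr(ep, "provenance"), "list")
  }
})
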