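test_that("FAA closed forms: symmetry, log-ratio, antisymmetry, scale invariance", {
  expect_equal(as.numeric(faa(1, 1)), 0)
  expect_equal(as.numeric(faa(1, 2)), log(2))
  expect_equal(as.numeric(faa(2, 1)), -as.numeric(faa(1, 2)))
  expect_equal(as.numeric(faa(0.37, 1.91)), -as.numeric(faa(1.91, 0.37)))
  # common positive rescaling of both powers cancels
  expect_equal(as.numeric(faa(3 * 0.8, 3 * 1.7)), as.numeric(faa(0.8, 1.7)))
  # floor guards the log; double-floor flags unreliability
  expect_true(is.finite(faa(0, 1)))
  expect_true(attr(faa(0, 0), "unreliable"))
  expect_false(attr(faa(1, 2), "unreliable"))
})

test_that("windowed FAA series behaves on degenerate inputs", {
  fs <- 50
  n <- 63 * fs
  w <- make_windows(63)
  series <- envelope_series(rbind(F3 = rep(2, n), F4 = rep(4, n)), fs)
  fsr <- faa_series(series, w)
  expect_identical(nrow(fsr), 59L)
  expect_true(all(abs(fsr$faa - log(2)) < 1e-12))    # constant series
  one_ch <- envelope_series(matrix(1, 1, n, dimnames = list("F3")), fs)
  expect_error(faa_series(one_ch, w), "F3 and F4")
  # group series of identical subjects equals the single-subject series
  g <- group_faa_series(list(series, series), w)
  expect_equal(g, fsr$faa)
})

test_that("pair counting matches the half-triangle formula", {
  expect_identical(n_pairs(28), 378L)    # the full study's comparison count
  expect_identical(n_pairs(2), 1L)
  expect_identical(n_pairs(5), 10L)
  expect_error(n_pairs(1), "n >= 2")
})

test_that("mean ISC equals a brute-force loop over all pairs", {
  fs <- 250
  n <- 1500
  set.seed(14)
  envs <- lapply(1:6, function(i) {
    envelope_series(rbind(Cz = abs(rnorm(n)), C3 = abs(rnorm(n)),
                          C4 = abs(rnorm(n))), fs, subject = paste0("s", i))
  })
  got <- isc(envs)
  # oracle: explicit double loop over subject pairs
  avg <- t(vapply(envs, function(e) colMeans(e$power), numeric(n)))
  rs <- c()
  for (i in 1:5) for (j in (i + 1):6) rs <- c(rs, cor(avg[i, ], avg[j, ]))
  expect_identical(length(got$pair_correlations), n_pairs(6))
  expect_lt(max(abs(got$pair_correlations - rs)), 1e-10)
  expect_lt(abs(got$mean_isc - mean(rs)), 1e-10)
  # mean lies within the pair range
  expect_gte(got$mean_isc, min(rs))
  expect_lte(got$mean_isc, max(rs))
})

test_that("ISC is invariant to per-subject affine envelope rescaling", {
  fs <- 250
  set.seed(15)
  envs <- lapply(1:4, function(i) {
    envelope_series(rbind(Cz = abs(rnorm(1000)), C3 = abs(rnorm(1000)),
                          C4 = abs(rnorm(1000))), fs)
  })
  scaled <- lapply(seq_along(envs), function(i) {
    e <- envs[[i]]
    e$power <- e$power * (2 * i) + 5 * i
    e
  })
  expect_equal(isc(envs)$mean_isc, isc(scaled)$mean_isc, tolerance = 1e-12)
})

test_that("identical envelopes give mean ISC of exactly 1, independent noise near 0", {
  fs <- 250
  base <- abs(rnorm(2000))
  same <- lapply(1:5, function(i) {
    envelope_series(rbind(Cz = base, C3 = base, C4 = base), fs)
  })
  expect_equal(isc(same)$mean_isc, 1)
  set.seed(16)
  indep <- lapply(1:28, function(i) {
    envelope_series(rbind(Cz = abs(rnorm(1200)), C3 = abs(rnorm(1200)),
                          C4 = abs(rnorm(1200))), fs)
  })
  null_isc <- isc(indep)
  expect_identical(length(null_isc$pair_correlations), 378L)
  expect_lt(abs(null_isc$mean_isc), 0.02)
})

test_that("zero-variance series are excluded from the pair mean", {
  fs <- 250
  set.seed(17)
  envs <- c(
    lapply(1:3, function(i) {
      envelope_series(rbind(Cz = abs(rnorm(500)), C3 = abs(rnorm(500)),
                            C4 = abs(rnorm(500))), fs)
    }),
    list(envelope_series(rbind(Cz = rep(1, 500), C3 = rep(1, 500),
                               C4 = rep(1, 500)), fs))
  )
  got <- isc(envs)
  expect_identical(got$n_excluded, 3L)                 # all pairs with s4
  expect_identical(sum(is.na(got$pair_correlations)), 3L)
  expect_true(is.finite(got$mean_isc))
})

test_that("windowed ISC follows injected coupling within a window", {
  fs <- 250
  n <- 10 * fs
  set.seed(18)
  common <- abs(rnorm(n))
  # correlated in the second half only
  envs <- lapply(1:3, function(i) {
    x <- abs(rnorm(n))
    x[(n / 2 + 1):n] <- common[(n / 2 + 1):n] + 0.1 * abs(rnorm(n / 2))
    envelope_series(rbind(Cz = x, C3 = x, C4 = x), fs)
  })
  w <- data.frame(start = c(0, 5), end = c(5, 10))
  tr <- isc_series(envs, w)
  expect_lt(tr$mean_isc[1], 0.2)
  expect_gt(tr$mean_isc[2], 0.9)
  expect_identical(dim(attr(tr, "pairs")), c(3L, 2L))
})

test_that("the per-channel ISC map finds the coupled channels", {
  # coupling is injected on Cz/C3/C4 only: they must carry the deal signal
  cfg <- quick_cfg(19, n_subjects = 4, n_videos = 8,
                   channels = c("Fp1", "F3", "F4", "T3", "Cz", "C3", "C4",
                                "Pz", "O1", "EOG"),
                   isc_deal_gain = 1.2, blink_rate = 0)
  study <- generate_study(cfg)
  deal <- study$truth$deal
  if (all(deal == 1) || all(deal == 0)) skip("degenerate deal draw")
  eeg_ch <- setdiff(cfg$channels, "EOG")
  envs <- envelopes_by_video(study, cfg$channels, eeg_ch, preprocess = FALSE)
  cmap <- isc_channel_map(envs, study$tables$outcomes, eeg_ch)
  top3 <- cmap$channel[order(-cmap$r_deal)][1:3]
  expect_true(all(top3 %in% c("Cz", "C3", "C4")))
  # identical signals on every channel give identical channel correlations
  fs <- 250
  set.seed(20)
  same_env <- lapply(1:4, function(v) {
    lapply(1:3, function(s) {
      x <- abs(rnorm(600))                    # distinct per subject x video
      envelope_series(rbind(Cz = x, C3 = x, C4 = x), fs,
                      subject = paste0("s", s), video = paste0("v", v))
    })
  })
  outcomes <- data.frame(video_id = paste0("v", 1:4), deal = c(0, 1, 0, 1),
                         amount = c(0, 2, 0, 5))
  cm2 <- isc_channel_map(same_env, outcomes, c("Cz", "C3", "C4"))
  expect_lt(diff(range(cm2$r_deal)), 1e-12)
  expect_lt(diff(range(cm2$r_amount)), 1e-12)
  expect_error(isc_channel_map(same_env,
                               transform(outcomes, deal = 1), c("Cz")),
               "constant outcome")
})
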