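fs <- 600
t10 <- (0:5999) / fs

test_that("lock-in amplitude is calibrated, selective, and phase invariant", {
  fast <- las_setting("fast", log_transform = FALSE)
  a <- lock_in_amplitude(2 * sin(2 * pi * 35 * t10), 35, fs, fast)
  core <- t10 > 1 & t10 < 9
  expect_equal(mean(a[core]), 2, tolerance = 0.01)
  expect_lt(diff(range(a[core])), 0.02)
  # out-of-band rejection: 5 Hz away at 4 Hz bandwidth
  b <- lock_in_amplitude(sin(2 * pi * 40 * t10), 35, fs, fast)
  expect_lt(max(b[core]), 0.1)
  # invariance to the carrier phase of the input (8 phases, 1%)
  amps <- vapply(seq(0, 2 * pi, length.out = 9)[-9], function(ph) {
    mean(lock_in_amplitude(sin(2 * pi * 35 * t10 + ph), 35, fs, fast)[core])
  }, numeric(1))
  expect_lt(diff(range(amps)) / mean(amps), 0.01)
  expect_error(lock_in_amplitude(t10, 1, fs, las_setting("fast")),
               "images overlap")
})

test_that("fast setting resolves twitch transients, standard does not", {
  onsets <- c(1.2, 2.3, 3.5, 4.4, 5.6, 6.9, 8.1)
  x <- simulate_ideal_stim_signal(35, onsets, duration = 10)
  fast <- lock_in_amplitude(x, 35, fs, las_setting("fast",
                                                   log_transform = FALSE))
  std <- lock_in_amplitude(x, 35, fs, las_setting("standard",
                                                  log_transform = FALSE))
  steady <- stats::median(fast[t10 > 0.5 & t10 < 9.5])
  for (o in onsets) {
    win <- fast[t10 >= o & t10 < o + 0.1]
    expect_lt(min(win), steady * 0.95)       # a clear dip at every twitch
  }
  core <- t10 > 1.5 & t10 < 8.5
  steady_s <- stats::median(std[core])
  expect_lt(max(abs(std[core] - steady_s)) / steady_s, 0.1)
  # log transform preserves ordering
  flog <- lock_in_amplitude(x, 35, fs, las_setting("fast"))
  expect_equal(order(fast[core]), order(flog[core]))
})

test_that("fast setting settles faster than the standard setting", {
  step <- as.numeric(t10 >= 3) * sin(2 * pi * 27 * t10)
  settle <- function(setting) {
    a <- lock_in_amplitude(step, 27, fs, setting)
    final <- stats::median(a[t10 > 6 & t10 < 9])
    t10[t10 >= 3][which(a[t10 >= 3] >= 0.9 * final)[1]] - 3
  }
  expect_lt(settle(las_setting("fast", log_transform = FALSE)),
            settle(las_setting("standard", log_transform = FALSE)))
})

test_that("SSSEP features recover the attention effect", {
  tr <- small_trials(seed = 6, profile = quiet_profile(attention_gain = 1.3),
                     trials_per_class = 3)
  feats <- extract_sssep_features(tr)
  expect_equal(ncol(feats$x), 2 * length(tr$bipolar_labels))
  # left-frequency feature on the contralateral channel: left-cue > idle
  col <- match(sprintf("FC4-CP4@%gHz", tr$stim_freqs[["left"]]),
               colnames(feats$x))
  left_vals <- feats$x[feats$labels == "focus_left", col]
  idle_vals <- feats$x[feats$labels == "idle", col]
  expect_gt(min(left_vals), max(idle_vals))
  # feature dimension bookkeeping holds after rejection
  tr2 <- tr
  tr2$rejected_bipolar[1] <- TRUE
  expect_equal(nrow(extract_sssep_features(tr2)$x), nrow(tr$meta) - 1)
  # a trial too short for the averaging window errors
  tr3 <- tr
  tr3$meta$focus_duration[2] <- 5
  expect_error(extract_sssep_features(tr3), "8.5")
})

test_that("blocking features respond to the injected attenuation", {
  tr_block <- small_trials(seed = 8, profile = quiet_profile())
  tr_null <- small_trials(seed = 8,
                          profile = quiet_profile(blocking_depth_db = 0))
  fb <- extract_blocking_features(tr_block)
  f0 <- extract_blocking_features(tr_null)
  expect_equal(ncol(fb$x), 2 * length(tr_block$bipolar_labels))
  # blocked-condition features are lower on the contralateral channels
  for (col in c(sprintf("FC4-CP4@%gHz", tr_block$stim_freqs[["left"]]),
                sprintf("FC3-CP3@%gHz", tr_block$stim_freqs[["right"]]))) {
    expect_lt(mean(fb$x[, col]), mean(f0$x[, col]))
  }
  # time-resolved variant keeps a decimated time dimension
  ftr <- extract_blocking_features(tr_block, decimation = 16)
  expect_equal(ncol(ftr$x), 2 * length(tr_block$bipolar_labels) * 15)
  # missing twitches error
  tr_nt <- tr_block
  tr_nt$twitch_left <- rep(list(numeric(0)), nrow(tr_nt$meta))
  tr_nt$twitch_right <- rep(list(numeric(0)), nrow(tr_nt$meta))
  expect_error(extract_blocking_features(tr_nt), "twitch")
})

test_that("spectrograms localize energy in time and frequency", {
  # steady sinusoid: ridge at the FFT bin nearest 25 Hz
  tr <- small_trials(seed = 10, profile = quiet_profile(noise_amp = 0.05))
  spec3 <- spectrogram_spec(3, 2.95)
  out <- compute_spectrogram(tr, "FC4-CP4", spec3)
  expect_true(length(out) >= 1)
  s <- out[[1]]
  # the left hand's stimulation frequency dominates FC4-CP4 mid-trial
  mid <- s$psd_db[, round(ncol(s$psd_db) / 2)]
  band <- s$freq > 10 & s$freq < 40
  ridge <- s$freq[band][which.max(mid[band])]
  expect_lt(abs(ridge - tr$stim_freqs[["left"]]), 1)
  # time-frequency tradeoff on a step-onset tone
  fs_ <- 600
  tt <- (0:11999) / fs_
  x <- as.numeric(tt >= 10) * sin(2 * pi * 25 * tt)
  st3 <- twitchbci:::stft_gauss(x, fs_, spectrogram_spec(3, 2.95))
  st1 <- twitchbci:::stft_gauss(x, fs_, spectrogram_spec(1, 0.95))
  bin25 <- which.min(abs(st3$freq - 25))
  rise_time <- function(st) {
    p <- st$psd[which.min(abs(st$freq - 25)), ]
    p <- p / max(p)
    st$time[which(p >= 0.9)[1]] - st$time[which(p >= 0.1)[1]]
  }
  expect_lt(rise_time(st1), rise_time(st3))     # sharper onset, short window
  freq_width <- function(st) {
    col <- st$psd[, ncol(st$psd)]                # steady-state frame
    col <- col / max(col)
    sum(col >= 0.5) * (st$freq[2] - st$freq[1])
  }
  expect_lt(freq_width(st3), freq_width(st1))   # sharper ridge, long window
})
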