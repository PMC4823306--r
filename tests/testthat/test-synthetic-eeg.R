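test_that("background noise has the requested spectral shape", {
  prof_white <- subject_profile(alpha_amp = 0, noise_exponent = 0)
  bg <- simulate_background(1, prof_white, seed = 1,
                            channels = key_channels)
  expect_equal(ncol(bg), 600)
  expect_equal(rowMeans(bg), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # white noise: flat spectrum (compare band powers via the periodogram)
  bg2 <- simulate_background(30, prof_white, seed = 2,
                             channels = "Cz")
  pg <- Mod(stats::fft(bg2[1, ]))^2
  f <- 600 * (seq_along(pg) - 1) / length(pg)
  lo <- mean(pg[f > 5 & f < 50]); hi <- mean(pg[f > 150 & f < 280])
  expect_gt(lo / hi, 0.8); expect_lt(lo / hi, 1.25)
  # 1/f: low band carries much more power
  bg3 <- simulate_background(30, subject_profile(alpha_amp = 0,
                                                 noise_exponent = 1),
                             seed = 2, channels = "Cz")
  pg3 <- Mod(stats::fft(bg3[1, ]))^2
  expect_gt(mean(pg3[f > 1 & f < 10]) / mean(pg3[f > 100 & f < 280]), 5)
  # alpha component peaks in 8-12 Hz on all EEG channels
  bga <- simulate_background(30, subject_profile(alpha_amp = 10),
                             seed = 3, channels = key_channels)
  for (i in 1:4) {
    pga <- Mod(stats::fft(bga[i, ]))^2
    expect_gt(mean(pga[f >= 8 & f <= 12]), 5 * mean(pga[f > 20 & f < 40]))
  }
})

test_that("SSSEP fragment carries attention gain and contralateral layout", {
  prof <- quiet_profile(noise_amp = 0, attention_gain = 1.3,
                        blocking_depth_db = 0)
  pats <- generate_twitch_patterns(3, 7, 9.5, 0.25, 27, 23, seed = 2)
  sch <- generate_bci_schedule(1, 3, pats, seed = 4)
  frag <- simulate_sssep(sch, pats, prof, c(left = 27, right = 23),
                         seed = 6, channels = key_channels)
  fs <- 600
  t <- (seq_len(ncol(frag)) - 1) / fs
  # left-frequency amplitude on the contralateral derivation, mid-focus
  amp_at <- function(trial_row, freq) {
    idx <- t >= trial_row$t_cue_onset + 2 & t < trial_row$t_cue_onset + 7
    x <- frag["FC4", idx] - frag["CP4", idx]
    a <- lock_in_amplitude(x, freq, fs,
                           las_setting("fast", log_transform = FALSE))
    stats::median(a)
  }
  left_tr <- sch[sch$class_label == "focus_left", ][1, ]
  idle_tr <- sch[sch$class_label == "idle", ][1, ]
  a_left <- amp_at(left_tr, 27)
  a_idle <- amp_at(idle_tr, 27)
  expect_equal(a_left / a_idle, 1.3, tolerance = 0.03)
  # ipsilateral projection of the left-hand SSSEP is (essentially) absent:
  # FC3-CP3 carries only the right hand's 23 Hz component, so demodulating
  # it at the left frequency yields next to nothing
  idle_idx <- t >= idle_tr$t_cue_onset + 2 & t < idle_tr$t_cue_onset + 7
  a_ipsi <- stats::median(lock_in_amplitude(
    frag["FC3", idle_idx] - frag["CP3", idle_idx], 27, fs,
    las_setting("fast", log_transform = FALSE)))
  expect_lt(a_ipsi, 0.02 * a_idle)
})

test_that("blocking attenuates the SSSEP inside its window", {
  pats <- generate_twitch_patterns(1, 7, 9.5, 0.25, 27, 23, seed = 2)
  sch <- generate_bci_schedule(1, 1, pats, seed = 4)
  fs <- 600
  frag_of <- function(depth) {
    prof <- quiet_profile(noise_amp = 0, blocking_depth_db = depth)
    simulate_sssep(sch, pats, prof, c(left = 27, right = 23), seed = 6,
                   channels = key_channels)
  }
  f0 <- frag_of(0); f25 <- frag_of(2.5)
  t <- (seq_len(ncol(f0)) - 1) / fs
  las <- function(frag) {
    lock_in_amplitude(frag["FC4", ] - frag["CP4", ], 27, fs,
                      las_setting("fast", log_transform = FALSE))
  }
  a0 <- las(f0); a25 <- las(f25)
  cue <- sch$t_cue_onset[1]
  onsets <- cue + pats[[1]]$onsets_left
  mid_idx <- sapply(onsets, function(o) which.min(abs(t - (o + 0.125))))
  # no-blocking fragment is flat across the focus period
  focus <- t > cue + 0.5 & t < cue + 9
  expect_lt(diff(range(a0[focus])) / stats::median(a0[focus]), 0.02)
  # blocked windows dip; the smoothed dip reaches a substantial part of the
  # injected 2.5 dB (= factor 0.75) amplitude reduction
  ratio <- a25[mid_idx] / a0[mid_idx]
  expect_true(all(ratio < 0.9))
  expect_true(all(ratio > 0.7))
})

test_that("P300 fragment appears only after attended twitches", {
  prof <- quiet_profile(noise_amp = 0)
  pats <- generate_twitch_patterns(3, 7, 9.5, 0.25, 27, 23, seed = 12)
  sch <- generate_bci_schedule(1, 2, pats, seed = 14)
  frag <- simulate_p300(sch, pats, prof, seed = 1, channels = c("Cz", "Fz"))
  fs <- 600
  t <- (seq_len(ncol(frag)) - 1) / fs
  for (i in seq_len(nrow(sch))) {
    s <- sch[i, ]
    seg <- frag["Cz", t >= s$t_trial_start & t < s$t_trial_end]
    if (s$class_label == "idle") {
      expect_equal(max(abs(seg)), 0)
    } else {
      p <- pats[[s$pattern_id]]
      onsets <- if (s$class_label == "focus_left") p$onsets_left
                else p$onsets_right
      for (o in s$t_cue_onset + onsets) {
        win <- frag["Cz", t >= o + 0.3 & t < o + 0.4]
        expect_gt(mean(win), 0)
        # peak within 300-400 ms of the twitch (search window excludes
        # bumps of neighbouring twitches, which may sit 250 ms away)
        ep <- frag["Cz", t >= o + 0.15 & t < o + 0.55]
        pk <- 0.15 + (which.max(ep) - 1) / fs
        expect_true(pk >= 0.3 && pk <= 0.4)
      }
    }
  }
})

test_that("sessions are additive compositions and reproducible", {
  prof <- subject_profile(noise_amp = 1)
  rec <- simulate_session("bci", prof, seed = 31, n_runs = 1,
                          trials_per_class_per_run = 1,
                          channels = key_channels, return_fragments = TRUE)
  total <- Reduce(`+`, rec$fragments)
  expect_equal(rec$data, total, tolerance = 1e-12)
  # schedule counts: 7 twitches per hand per trial in the event table
  for (i in unique(rec$events$trial_id)) {
    ev <- rec$events[rec$events$trial_id == i, ]
    expect_equal(sum(ev$event_type == "twitch_left"), 7)
    expect_equal(sum(ev$event_type == "twitch_right"), 7)
  }
  # byte-identical event table on rerun with the same seed
  rec2 <- simulate_session("bci", prof, seed = 31, n_runs = 1,
                           trials_per_class_per_run = 1,
                           channels = key_channels)
  expect_identical(rec$events, rec2$events)
  expect_identical(rec$data, rec2$data[, seq_len(ncol(rec$data))])
})

test_that("ideal stimulation signal zeroes exactly one period per twitch", {
  x <- simulate_ideal_stim_signal(35, c(1, 2.5), duration = 4)
  t <- (seq_along(x) - 1) / 600
  per <- 1 / 35
  for (o in floor(c(1, 2.5) / per) * per) {
    expect_true(all(x[t >= o & t < o + per] == 0))
  }
  # without twitches the envelope is a 50% duty square wave
  y <- simulate_ideal_stim_signal(35, numeric(0), duration = 1)
  expect_equal(mean(y), 0.5, tolerance = 0.02)
})
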