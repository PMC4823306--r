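#' Synthetic subject profile
#'
#' Collects the physiological parameters of the synthetic EEG generator.
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: narrowband SSSEPs at the stimulation (envelope) frequencies with
#' contralateral topography and a subject-specific frequency tuning curve,
#' attention-dependent SSSEP gain, transient twitch-locked SSSEP attenuation
#' ("blocking"), a P300-like positive deflection after attended twitches,
#' and 1/f background noise with alpha-band activity.
#'
#' Amplitudes are free parameters (the underlying study reports none in
#' microvolts); the defaults were fixed once from a signal-to-noise
#' calculation for comfortable detectability and are documented in the
#' methods vignette.
#'
#' @param tuning_peak,tuning_width Gaussian tuning-curve peak location and
#'   width in Hz (SSSEP amplitude gain as a function of stimulation
#'   frequency; peak gain 1).
#' @param sssep_base_amp SSSEP source amplitude in microvolts at the tuning
#'   peak, before spatial weighting.
#' @param attention_gain multiplicative SSSEP gain on the attended finger
#'   during the focus period.
#' @param blocking_depth_db SSSEP attenuation after each twitch, in dB.
#' @param blocking_window c(onset_delay, offset_delay) of the rectangular
#'   blocking window in seconds after each twitch onset.
#' @param p300_amp,p300_latency,p300_width P300 bump amplitude (microvolts),
#'   peak latency and total duration (seconds) after attended twitches.
#' @param p300_nontarget_amp bump amplitude after non-target twitches
#'   (default 0; set > 0 to emulate the confound of P300s to non-target
#'   twitches).
#' @param alpha_amp amplitude of the 8-12 Hz background component
#'   (microvolts).
#' @param noise_amp RMS of the per-channel background noise (microvolts).
#' @param noise_exponent exponent beta of the 1/f^beta background spectrum.
#' @param w_sssep_left,w_sssep_right,w_p300 named per-channel spatial gain
#'   maps (maximum 1); defaults give purely contralateral SSSEP projections
#'   with an anterior-posterior gradient (so bipolar derivations pick them
#'   up) and a centro-parietal P300 map.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(tuning_peak = 27, tuning_width = 6,
                            sssep_base_amp = 3, attention_gain = 1.3,
                            blocking_depth_db = 2.5,
                            blocking_window = c(0.05, 0.20),
                            p300_amp = 3, p300_latency = 0.35,
                            p300_width = 0.2, p300_nontarget_amp = 0,
                            alpha_amp = 1.5, noise_amp = 4,
                            noise_exponent = 1,
                            w_sssep_left = sssep_spatial_weights("left"),
                            w_sssep_right = sssep_spatial_weights("right"),
                            w_p300 = p300_spatial_weights()) {
  stopifnot(sssep_base_amp >= 0, attention_gain >= 0, p300_amp >= 0,
            noise_amp >= 0, alpha_amp >= 0)
  if (any(blocking_window < 0) || any(blocking_window > 0.5) ||
      blocking_window[1] >= blocking_window[2]) {
    stopf("blocking_window must be an increasing pair within [0, 0.5] s")
  }
  norm1 <- function(w) if (max(w) > 0) w / max(w) else w
  structure(list(tuning_peak = tuning_peak, tuning_width = tuning_width,
                 sssep_base_amp = sssep_base_amp,
                 attention_gain = attention_gain,
                 blocking_depth_db = blocking_depth_db,
                 blocking_window = blocking_window,
                 p300_amp = p300_amp, p300_latency = p300_latency,
                 p300_width = p300_width,
                 p300_nontarget_amp = p300_nontarget_amp,
                 alpha_amp = alpha_amp, noise_amp = noise_amp,
                 noise_exponent = noise_exponent,
                 w_sssep_left = norm1(w_sssep_left),
                 w_sssep_right = norm1(w_sssep_right),
                 w_p300 = norm1(w_p300)),
            class = "subject_profile")
}

# Gaussian frequency tuning; unit gain at the peak.
tuning_gain <- function(profile, freq) {
  if (freq < 17 || freq > 35) {
    stopf("stimulation frequency %g Hz outside the tuning-curve support", freq)
  }
  exp(-(freq - profile$tuning_peak)^2 / (2 * profile$tuning_width^2))
}

#' Default spatial weight maps
#'
#' SSSEP maps project purely to the hemisphere contralateral to the
#' stimulated hand with an anterior-posterior gradient; the P300 map is
#' centro-parietal and symmetric.  Weights are named by channel and
#' normalized to a maximum of 1; channels not named carry weight 0.
#'
#' @param hand `"left"` or `"right"` (the stimulated hand; the map lies on
#'   the opposite hemisphere).
#' @return named numeric vector.
#' @export
sssep_spatial_weights <- function(hand = c("left", "right")) {
  hand <- match.arg(hand)
  if (hand == "left") {
    # right-hemisphere channels (even suffixes)
    w <- c(FC4 = 1.0, FC2 = 0.55, C4 = 0.5, C2 = 0.3, C6 = 0.35,
           CP4 = 0.15, CP2 = 0.1, CP6 = 0.1, P4 = 0.05, P2 = 0.03,
           P6 = 0.03)
  } else {
    w <- c(FC3 = 1.0, FC1 = 0.55, C3 = 0.5, C1 = 0.3, C5 = 0.35,
           CP3 = 0.15, CP1 = 0.1, CP5 = 0.1, P3 = 0.05, P1 = 0.03,
           P5 = 0.03)
  }
  w
}

#' @rdname sssep_spatial_weights
#' @export
p300_spatial_weights <- function() {
  c(Cz = 1.0, CPz = 0.95, FCz = 0.7, Pz = 0.8, CP1 = 0.85, CP2 = 0.85,
    C1 = 0.8, C2 = 0.8, C3 = 0.55, C4 = 0.55, P1 = 0.6, P2 = 0.6,
    Fz = 0.4, CP3 = 0.4, CP4 = 0.4, P3 = 0.35, P4 = 0.35)
}

# Expand a named weight vector onto a channel vector (missing -> 0).
weights_on <- function(w, channels) {
  out <- stats::setNames(numeric(length(channels)), channels)
  common <- intersect(names(w), channels)
  out[common] <- w[common]
  out
}

#' Multichannel recording container
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels unique channel labels (rows of `data`).
#' @param events event table (see [make_event_table()]), or `NULL`.
#' @param ... further metadata stored on the object (e.g. `schedule`,
#'   `patterns`, `stim_freqs`, `paradigm`).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_labels, events = NULL,
                          ...) {
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (nrow(data) != length(channel_labels)) {
    stopf("data rows must match channel labels")
  }
  rownames(data) <- channel_labels
  dur <- ncol(data) / sample_rate
  if (!is.null(events) && nrow(events) &&
      (min(events$time_s) < 0 || max(events$time_s) > dur + 1e-9)) {
    stopf("event times must lie within the recording span")
  }
  structure(list(data = data, sample_rate = sample_rate,
                 channel_labels = channel_labels, events = events, ...),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$sample_rate,
              x$sample_rate))
  if (!is.null(x$events)) cat(sprintf("  %d events\n", nrow(x$events)))
  invisible(x)
}

#' Simulate background EEG activity
#'
#' Per-channel 1/f^beta noise (spectrally shaped white noise, exactly zero
#' mean, RMS `noise_amp`) plus an alpha-band sinusoid (random frequency in
#' 8-12 Hz, random phase) on EEG channels.
#'
#' @param duration seconds.
#' @param profile a [subject_profile()].
#' @param seed RNG seed.
#' @param channels channel labels to simulate.
#' @param sample_rate Hz.
#' @return channels x samples matrix.
#' @export
simulate_background <- function(duration, profile, seed = NULL,
                                channels = default_montage()$eeg_channels,
                                sample_rate = 600) {
  if (duration <= 0) stopf("duration must be positive")
  n <- round(duration * sample_rate)
  beta <- profile$noise_exponent
  m <- stats::nextn(n, c(2, 3, 5))   # highly composite length: fast FFT
  with_seed(seed, {
    data <- matrix(0, length(channels), n,
                   dimnames = list(channels, NULL))
    freqs <- sample_rate * (0:(m - 1)) / m
    fsym <- pmin(freqs, sample_rate - freqs)       # two-sided frequency axis
    w <- c(0, fsym[-1]^(-beta / 2))                # zero out DC
    t <- (seq_len(n) - 1) / sample_rate
    is_eog <- grepl("^EOG", channels)
    for (i in seq_along(channels)) {
      x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * w,
                         inverse = TRUE))[seq_len(n)] / m
      x <- x - mean(x)
      s <- stats::sd(x)
      x <- if (s > 0) x * (profile$noise_amp / s) else x
      if (!is_eog[i] && profile$alpha_amp > 0) {
        fa <- stats::runif(1, 8, 12)
        x <- x + profile$alpha_amp * sin(2 * pi * fa * t +
                                           stats::runif(1, 0, 2 * pi))
      }
      data[i, ] <- x
    }
    data
  })
}

#' Simulate the SSSEP component of a session
#'
#' Adds, for each hand, a sinusoid at that hand's stimulation frequency
#' during stimulation-on periods, scaled by the tuning-curve gain, the
#' contralateral spatial weight map, and (for the cued hand during the focus
#' period) the attention gain.  After each of a hand's twitches the amplitude
#' is multiplied by `10^(-blocking_depth_db/20)` inside the rectangular
#' blocking window.  The sinusoid phase is continuous within each trial.
#'
#' @param schedule a `bci_schedule` or `screening_schedule`.
#' @param patterns twitch patterns referenced by a BCI schedule (ignored for
#'   screening).
#' @param profile a [subject_profile()].
#' @param stim_freqs named c(left =, right =) stimulation frequencies in Hz
#'   (BCI paradigm).
#' @param seed RNG seed (random sinusoid phase per trial and hand).
#' @param channels channel labels to simulate.
#' @param duration total duration in seconds.
#' @param sample_rate Hz.
#' @return channels x samples matrix.
#' @export
simulate_sssep <- function(schedule, patterns, profile,
                           stim_freqs = c(left = 27, right = 23),
                           seed = NULL,
                           channels = default_montage()$eeg_channels,
                           duration = NULL, sample_rate = 600) {
  if (inherits(schedule, "screening_schedule")) {
    return(simulate_screening_sssep(schedule, profile, seed, channels,
                                    duration, sample_rate))
  }
  duration <- duration %||% (max(schedule$t_trial_end) + 2)
  n <- round(duration * sample_rate)
  data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  block_gain <- 10^(-profile$blocking_depth_db / 20)
  wmap <- list(left = weights_on(profile$w_sssep_left, channels),
               right = weights_on(profile$w_sssep_right, channels))
  with_seed(seed, {
    for (i in seq_len(nrow(schedule))) {
      s <- schedule[i, ]
      p <- patterns[[s$pattern_id]]
      i0 <- floor(s$t_stim_start * sample_rate) + 1
      i1 <- min(n, ceiling(s$t_trial_end * sample_rate))
      tt <- (seq(i0, i1) - 1) / sample_rate
      for (hand in c("left", "right")) {
        f <- stim_freqs[[hand]]
        amp0 <- profile$sssep_base_amp * tuning_gain(profile, f)
        amp <- rep(amp0, length(tt))
        attended <- (hand == "left" && s$class_label == "focus_left") ||
          (hand == "right" && s$class_label == "focus_right")
        if (attended) {
          amp[tt >= s$t_cue_onset] <- amp0 * profile$attention_gain
        }
        onsets <- if (hand == "left") p$onsets_left else p$onsets_right
        for (o in s$t_cue_onset + onsets) {
          idx <- samples_in(tt, o + profile$blocking_window[1],
                            o + profile$blocking_window[2])
          amp[idx] <- amp[idx] * block_gain
        }
        phase <- stats::runif(1, 0, 2 * pi)
        src <- amp * sin(2 * pi * f * (tt - tt[1]) + phase)
        w <- wmap[[hand]]
        nz <- which(w > 0)
        if (length(nz)) {
          data[nz, i0:i1] <- data[nz, i0:i1] + outer(w[nz], src)
        }
      }
    }
    data
  })
}

simulate_screening_sssep <- function(schedule, profile, seed, channels,
                                     duration, sample_rate) {
  iv <- schedule$intervals
  duration <- duration %||% (max(iv$t_end) + 2)
  n <- round(duration * sample_rate)
  data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  wmap <- list(left = weights_on(profile$w_sssep_left, channels),
               right = weights_on(profile$w_sssep_right, channels))
  with_seed(seed, {
    for (i in seq_len(nrow(iv))) {
      f <- iv$freq[i]
      amp <- profile$sssep_base_amp * tuning_gain(profile, f)
      i0 <- floor(iv$t_start[i] * sample_rate) + 1
      i1 <- min(n, ceiling(iv$t_end[i] * sample_rate))
      tt <- (seq(i0, i1) - 1) / sample_rate
      src <- amp * sin(2 * pi * f * (tt - tt[1]) + stats::runif(1, 0, 2 * pi))
      w <- wmap[[iv$finger[i]]]
      nz <- which(w > 0)
      data[nz, i0:i1] <- data[nz, i0:i1] + outer(w[nz], src)
    }
    data
  })
}

#' Simulate the P300 component of a session
#'
#' After each twitch on the cued hand (none in idle trials) a positive
#' raised-cosine bump of amplitude `p300_amp`, peaking `p300_latency` seconds
#' after twitch onset with total duration `p300_width`, is added through the
#' centro-parietal spatial map.  Non-target twitches receive a bump of
#' amplitude `p300_nontarget_amp` (default 0).
#'
#' @inheritParams simulate_sssep
#' @return channels x samples matrix.
#' @export
simulate_p300 <- function(schedule, patterns, profile, seed = NULL,
                          channels = default_montage()$eeg_channels,
                          duration = NULL, sample_rate = 600) {
  duration <- duration %||% (max(schedule$t_trial_end) + 2)
  n <- round(duration * sample_rate)
  data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  w <- weights_on(profile$w_p300, channels)
  nz <- which(w > 0)
  if (!length(nz)) return(data)
  # accumulate all bumps into one source time series, then project spatially
  src <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]
    p <- patterns[[s$pattern_id]]
    target_hand <- switch(s$class_label, focus_left = "left",
                          focus_right = "right", idle = NA_character_)
    for (hand in c("left", "right")) {
      onsets <- if (hand == "left") p$onsets_left else p$onsets_right
      amp <- if (!is.na(target_hand) && hand == target_hand)
        profile$p300_amp else profile$p300_nontarget_amp
      if (amp <= 0) next
      for (o in s$t_cue_onset + onsets) {
        start <- o + profile$p300_latency - profile$p300_width / 2
        i0 <- max(1, floor(start * sample_rate) + 1)
        i1 <- min(n, floor((start + profile$p300_width) * sample_rate))
        if (i1 < i0) next
        tt <- (seq(i0, i1) - 1) / sample_rate
        src[i0:i1] <- src[i0:i1] +
          amp * 0.5 * (1 - cos(2 * pi * (tt - start) / profile$p300_width))
      }
    }
  }
  data[nz, ] <- outer(w[nz], src)
  data
}

#' Simulate a full recording session
#'
#' Composes background, SSSEP and (for the BCI paradigm) P300 fragments into
#' a continuous multichannel recording with an embedded event table.
#' Optionally injects EOG activity with frontal-weighted leakage into the EEG
#' channels, and rare high-amplitude artifact spikes on randomly chosen
#' trials (for artifact-rejection tests).
#'
#' @param paradigm `"bci"` or `"screening"`.
#' @param profile a [subject_profile()].
#' @param seed session seed; all child seeds (patterns, schedule, fragments,
#'   artifacts) are derived from it deterministically.
#' @param stim_freqs named c(left =, right =) stimulation frequencies (BCI).
#' @param n_runs,trials_per_class_per_run,trials_per_run session layout.
#' @param channels channel labels to simulate (default: full 29 EEG + 3 EOG
#'   montage; a subset can be simulated for desk-scale analyses).
#' @param artifact_rate fraction of trials receiving a high-amplitude spike.
#' @param artifact_amp spike amplitude in microvolts.
#' @param eog_amp amplitude of injected EOG (blink-like) activity in
#'   microvolts (0 = none).
#' @param return_fragments if `TRUE`, attach the individual fragments for
#'   inspection (field `fragments`).
#' @param sample_rate Hz.
#' @return an [eeg_recording()] with `schedule`, `patterns`, `stim_freqs` and
#'   `paradigm` metadata.
#' @export
simulate_session <- function(paradigm = c("bci", "screening"), profile,
                             seed = NULL,
                             stim_freqs = c(left = 27, right = 23),
                             n_runs = 8, trials_per_class_per_run = 10,
                             trials_per_run = 10, channels = NULL,
                             artifact_rate = 0, artifact_amp = 150,
                             eog_amp = 0, return_fragments = FALSE,
                             sample_rate = 600) {
  paradigm <- match.arg(paradigm)
  montage <- default_montage()
  channels <- channels %||% c(montage$eeg_channels, montage$eog_channels)
  seed <- seed %||% 1L
  if (paradigm == "bci") {
    patterns <- generate_twitch_patterns(
      3, 7, 9.5, 0.25, freq_left = stim_freqs[["left"]],
      freq_right = stim_freqs[["right"]], seed = derive_seed(seed, 1))
    schedule <- generate_bci_schedule(n_runs, trials_per_class_per_run,
                                      patterns, seed = derive_seed(seed, 2))
    duration <- max(schedule$t_trial_end) + 2
    events <- make_event_table(schedule, patterns)
  } else {
    patterns <- NULL
    schedule <- generate_screening_schedule(seed = derive_seed(seed, 2),
                                            n_runs = n_runs,
                                            trials_per_run = trials_per_run)
    duration <- max(schedule$intervals$t_end) + 2
    events <- data.frame(
      time_s = schedule$intervals$t_start,
      event_type = paste0("stim_", schedule$intervals$finger),
      trial_id = schedule$intervals$trial_id,
      pattern_id = NA_integer_, stringsAsFactors = FALSE)
  }
  bg <- simulate_background(duration, profile, derive_seed(seed, 3),
                            channels, sample_rate)
  ss <- simulate_sssep(schedule, patterns, profile, stim_freqs,
                       derive_seed(seed, 4), channels, duration, sample_rate)
  data <- bg + ss
  fragments <- if (return_fragments) list(background = bg, sssep = ss)
  rm(bg, ss)
  if (paradigm == "bci") {
    p3 <- simulate_p300(schedule, patterns, profile, derive_seed(seed, 5),
                        channels, duration, sample_rate)
    data <- data + p3
    if (return_fragments) fragments$p300 <- p3
    rm(p3)
  }
  n <- ncol(data)
  t <- (seq_len(n) - 1) / sample_rate
  eog_idx <- grep("^EOG", channels)
  if (eog_amp > 0 && length(eog_idx)) {
    eog <- with_seed(derive_seed(seed, 6), {
      n_blinks <- max(1, round(duration / 4))
      sig <- matrix(0, length(eog_idx), n)
      for (j in seq_along(eog_idx)) {
        centers <- stats::runif(n_blinks, 0, duration)
        for (ctr in centers) {
          idx <- samples_in(t, ctr - 0.15, ctr + 0.15)
          sig[j, idx] <- sig[j, idx] +
            eog_amp * 0.5 * (1 + cos(pi * (t[idx] - ctr) / 0.15))
        }
      }
      sig
    })
    data[eog_idx, ] <- data[eog_idx, ] + eog
    # frontal-weighted leakage into EEG channels
    leak <- eog_leak_profile(channels)
    eeg_idx <- setdiff(seq_along(channels), eog_idx)
    for (j in seq_along(eog_idx)) {
      coef <- leak * c(1, 0.8, 0.6)[min(j, 3)]
      data[eeg_idx, ] <- data[eeg_idx, ] +
        outer(coef[eeg_idx], eog[j, ])
    }
  }
  if (artifact_rate > 0 && paradigm == "bci") {
    data <- with_seed(derive_seed(seed, 7), {
      hit <- which(stats::runif(nrow(schedule)) < artifact_rate)
      eeg_idx <- setdiff(seq_along(channels), eog_idx)
      for (i in hit) {
        ch <- sample(eeg_idx, 1)
        t0 <- stats::runif(1, schedule$t_cue_onset[i],
                           schedule$t_trial_end[i] - 0.1)
        idx <- samples_in(t, t0, t0 + 0.05)
        data[ch, idx] <- data[ch, idx] + artifact_amp
      }
      data
    })
  }
  eeg_recording(data, sample_rate, channels, events,
                schedule = schedule, patterns = patterns,
                stim_freqs = stim_freqs, paradigm = paradigm,
                fragments = fragments)
}

# Per-channel EOG leakage coefficients, strongest frontally.
eog_leak_profile <- function(channels) {
  coef <- numeric(length(channels))
  coef[grepl("^F[^C]|^Fz", channels)] <- 0.4
  coef[grepl("^FC", channels)] <- 0.25
  coef[grepl("^C[0-9z]", channels)] <- 0.15
  coef[grepl("^CP", channels)] <- 0.08
  coef[grepl("^P[0-9z]", channels)] <- 0.04
  coef[grepl("^PO", channels)] <- 0.02
  coef[grepl("^EOG", channels)] <- 0
  stats::setNames(coef, channels)
}

#' Ideal simulated stimulation signal
#'
#' The noiseless rectangular stimulation envelope at `freq` (50% duty cycle,
#' no carrier -- the SSSEP follows the envelope frequency) with one-period
#' interruptions at the given twitch onsets.  Used to validate the fast
#' lock-in amplifier setting on a signal whose transients are exactly known.
#'
#' @param freq stimulation frequency in Hz.
#' @param twitch_onsets onset times in seconds (quantized to the period grid
#'   internally so each twitch deletes exactly one envelope period).
#' @param duration seconds.
#' @param sample_rate Hz.
#' @return numeric signal (0/1 envelope with twitch gaps).
#' @export
simulate_ideal_stim_signal <- function(freq, twitch_onsets = numeric(0),
                                       duration = 10, sample_rate = 600) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  period <- 1 / freq
  env <- as.numeric((t %% period) < period / 2)
  if (length(twitch_onsets)) {
    onsets <- floor(twitch_onsets / period) * period
    env <- insert_twitches(env, onsets, freq = freq,
                           sample_rate = sample_rate)
  }
  env
}
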