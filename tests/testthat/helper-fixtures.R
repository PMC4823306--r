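# Shared fixtures, built in code.

# Low-noise profile for construction-oracle tests.
quiet_profile <- function(...) {
  args <- utils::modifyList(list(noise_amp = 0.2, alpha_amp = 0), list(...))
  do.call(subject_profile, args)
}

# The four electrodes feeding the two key bipolar channels.
key_channels <- c("FC3", "CP3", "FC4", "CP4")

# Channels needed for the full default montage (bipolar + monopolar sets).
montage_channels <- function() {
  m <- default_montage()
  unique(c(as.vector(m$sssep_pairs), m$p300_channels))
}

# Small epoched BCI session (n_runs runs x trials_per_class per class).
small_trials <- function(seed = 1, profile = subject_profile(), n_runs = 1,
                         trials_per_class = 2, channels = key_channels,
                         ...) {
  rec <- simulate_session("bci", profile, seed = seed, n_runs = n_runs,
                          trials_per_class_per_run = trials_per_class,
                          channels = channels, ...)
  reject_artifact_trials(epoch_trials(rec))
}

# Fabricate a minimal bci_trials object from hand-built monopolar data.
# `mono` is a list of channels x samples matrices (one per trial); twitch
# onsets are seconds relative to cue; cue is placed `cue_at` seconds into
# each epoch.
fake_mono_trials <- function(mono, twitch_left, twitch_right,
                             class_label, fs = 600, cue_at = 1) {
  nt <- length(mono)
  structure(list(
    bipolar = vector("list", nt), mono = mono,
    bipolar_labels = character(0),
    mono_labels = rownames(mono[[1]]),
    meta = data.frame(trial_id = seq_len(nt), class_label = class_label,
                      pattern_id = 1L, run = 1L,
                      focus_duration = vapply(mono, ncol, 1) / fs - cue_at,
                      stringsAsFactors = FALSE),
    cue_sample = rep(round(cue_at * fs) + 1L, nt),
    twitch_left = twitch_left, twitch_right = twitch_right,
    patterns = NULL, stim_freqs = c(left = 27, right = 23),
    sample_rate = fs,
    rejected_bipolar = rep(FALSE, nt), rejected_mono = rep(FALSE, nt),
    rejection_reason = rep(NA_character_, nt)),
    class = "bci_trials")
}

# Amplitude-series container for permutation-test unit tests.
fake_amp_trials <- function(amp_list, t0 = -1, fs = 600) {
  list(amp = amp_list, t0 = rep(t0, length(amp_list)), fs = fs,
       trial_index = seq_along(amp_list))
}
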