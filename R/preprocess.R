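#' Acquisition-stage filtering
#'
#' Zero-phase band-pass 0.5-200 Hz (Butterworth: 2nd-order high-pass,
#' 4th-order low-pass) and a 50 Hz notch, applied to every channel.  Mirrors
#' the amplifier settings of the recording setup.
#'
#' @param recording an [eeg_recording()].
#' @param highpass,lowpass,notch_freq edge frequencies in Hz.
#' @return the filtered recording.
#' @export
apply_acquisition_filters <- function(recording, highpass = 0.5,
                                      lowpass = 200, notch_freq = 50) {
  fs <- recording$sample_rate
  if (fs / 2 <= lowpass) {
    stopf("sample rate %g Hz too low for a %g Hz low-pass edge", fs, lowpass)
  }
  hp <- butter_filter(2, highpass, fs, "high")
  lp <- butter_filter(4, lowpass, fs, "low")
  nf <- iir_notch(notch_freq, fs)
  pad_hp <- round(3 * fs / highpass)
  for (i in seq_len(nrow(recording$data))) {
    x <- recording$data[i, ]
    x <- filtfilt_iir(hp, x, padlen = pad_hp)
    x <- filtfilt_iir(lp, x)
    x <- filtfilt_iir(nf, x, padlen = 200)
    recording$data[i, ] <- x
  }
  recording
}

#' Derive bipolar channels
#'
#' Each bipolar channel is anode minus cathode, labelled `"anode-cathode"`.
#'
#' @param recording an [eeg_recording()].
#' @param pairs two-column character matrix of (anode, cathode) labels.
#' @return an [eeg_recording()] holding the bipolar channels.
#' @export
derive_bipolar <- function(recording, pairs) {
  missing <- setdiff(unique(c(pairs)), recording$channel_labels)
  if (length(missing)) {
    stopf("channels missing from recording: %s",
          paste(missing, collapse = ", "))
  }
  data <- recording$data[pairs[, 1], , drop = FALSE] -
    recording$data[pairs[, 2], , drop = FALSE]
  eeg_recording(data, recording$sample_rate, bipolar_labels(pairs),
                recording$events, schedule = recording$schedule,
                patterns = recording$patterns,
                stim_freqs = recording$stim_freqs,
                paradigm = recording$paradigm)
}

#' Regression-based EOG artifact removal
#'
#' Estimates least-squares leakage coefficients of the EOG channels into each
#' EEG channel on a calibration segment (typically dedicated eye-movement /
#' blink recordings), then subtracts the weighted EOG channels from the EEG
#' channels of the recording.  This is the stationary special case of
#' adaptive autoregressive EOG-correction schemes.
#'
#' @param recording an [eeg_recording()] containing EEG and EOG channels.
#' @param calibration an [eeg_recording()] (or channels x samples matrix with
#'   the same channel labels) containing artifact-rich EOG activity.
#' @param eog_channels labels of the EOG channels.
#' @return the recording with corrected EEG channels (EOG channels are kept).
#' @export
remove_eog <- function(recording, calibration,
                       eog_channels = grep("^EOG",
                                           recording$channel_labels,
                                           value = TRUE)) {
  if (!length(eog_channels)) stopf("no EOG channels found")
  cal <- if (inherits(calibration, "eeg_recording")) calibration$data
         else calibration
  eeg_channels <- setdiff(recording$channel_labels, eog_channels)
  y <- cal[eog_channels, , drop = FALSE]
  y <- y - rowMeans(y)
  x <- cal[eeg_channels, , drop = FALSE]
  x <- x - rowMeans(x)
  cyy <- tcrossprod(y) / ncol(y)
  if (rcond(cyy) < 1e-12) {
    stopf("EOG covariance on the calibration segment is rank-deficient")
  }
  cxy <- tcrossprod(x, y) / ncol(y)
  coef <- cxy %*% solve(cyy)               # nEEG x nEOG
  recording$data[eeg_channels, ] <- recording$data[eeg_channels, ] -
    coef %*% recording$data[eog_channels, , drop = FALSE]
  recording
}

#' Epoch a BCI recording into trials
#'
#' Cuts the continuous recording into per-trial epochs spanning trial start
#' to trial end plus `margin`, and derives both channel sets: the bipolar
#' SSSEP set and the monopolar P300 set.  Sample times within each epoch are
#' referenced to the cue onset (t = 0 at cue).  Twitch onsets (relative to
#' cue) are attached per trial and hand.
#'
#' @param recording an [eeg_recording()] carrying a `bci_schedule` and its
#'   twitch `patterns` (as produced by [simulate_session()]), or pass them
#'   explicitly.
#' @param montage a [default_montage()]-style montage.
#' @param schedule,patterns override the recording's own metadata.
#' @param margin seconds kept beyond the trial end (so that twitch-locked
#'   windows -- up to +0.8 s for P300 epochs -- stay inside the epoch).
#' @param exclude_channels channels to drop before deriving the montage
#'   (bad-channel exclusion list).
#' @return object of class `bci_trials`: lists `bipolar` and `mono` of
#'   channels x samples matrices, `meta` (trial_id, class_label, pattern_id,
#'   run, focus_duration), `cue_sample` (index of t = 0 per epoch),
#'   `twitch_left`/`twitch_right` (onset lists, seconds relative to cue),
#'   rejection masks (all `FALSE`; see [reject_artifact_trials()]), labels
#'   and `sample_rate`.
#' @export
epoch_trials <- function(recording, montage = default_montage(),
                         schedule = recording$schedule,
                         patterns = recording$patterns, margin = 1,
                         exclude_channels = character(0)) {
  if (is.null(schedule)) stopf("no schedule attached to the recording")
  if (length(exclude_channels)) {
    keep <- !recording$channel_labels %in% exclude_channels
    recording$data <- recording$data[keep, , drop = FALSE]
    recording$channel_labels <- recording$channel_labels[keep]
  }
  labels <- recording$channel_labels
  pair_ok <- montage$sssep_pairs[, 1] %in% labels &
    montage$sssep_pairs[, 2] %in% labels
  pairs <- montage$sssep_pairs[pair_ok, , drop = FALSE]
  mono_ch <- intersect(montage$p300_channels, labels)
  if (!nrow(pairs) && !length(mono_ch)) {
    stopf("no montage channels present in the recording")
  }
  fs <- recording$sample_rate
  n <- ncol(recording$data)
  bip_data <- if (nrow(pairs)) {
    recording$data[pairs[, 1], , drop = FALSE] -
      recording$data[pairs[, 2], , drop = FALSE]
  }
  nt <- nrow(schedule)
  bipolar <- vector("list", nt); mono <- vector("list", nt)
  cue_sample <- integer(nt)
  twitch_left <- vector("list", nt); twitch_right <- vector("list", nt)
  for (i in seq_len(nt)) {
    s <- schedule[i, ]
    i0 <- max(1, floor(s$t_trial_start * fs) + 1)
    i1 <- min(n, ceiling((s$t_trial_end + margin) * fs))
    if (!is.null(bip_data)) {
      m <- bip_data[, i0:i1, drop = FALSE]
      rownames(m) <- bipolar_labels(pairs)
      bipolar[[i]] <- m
    }
    if (length(mono_ch)) {
      mono[[i]] <- recording$data[mono_ch, i0:i1, drop = FALSE]
    }
    cue_sample[i] <- round(s$t_cue_onset * fs) + 1 - i0 + 1
    p <- patterns[[s$pattern_id]]
    twitch_left[[i]] <- p$onsets_left
    twitch_right[[i]] <- p$onsets_right
  }
  structure(list(
    bipolar = bipolar, mono = mono,
    bipolar_labels = bipolar_labels(pairs), mono_labels = mono_ch,
    meta = data.frame(trial_id = schedule$trial_id,
                      class_label = schedule$class_label,
                      pattern_id = schedule$pattern_id,
                      run = schedule$run,
                      focus_duration = schedule$focus_duration,
                      stringsAsFactors = FALSE),
    cue_sample = cue_sample,
    twitch_left = twitch_left, twitch_right = twitch_right,
    patterns = patterns,
    stim_freqs = recording$stim_freqs,
    sample_rate = fs,
    rejected_bipolar = rep(FALSE, nt), rejected_mono = rep(FALSE, nt),
    rejection_reason = rep(NA_character_, nt)),
    class = "bci_trials")
}

# Time axis of epoch i, in seconds relative to cue onset.
trial_times <- function(trials, i) {
  ncol_i <- ncol(trials$bipolar[[i]] %||% trials$mono[[i]])
  (seq_len(ncol_i) - trials$cue_sample[i]) / trials$sample_rate
}

#' Threshold-based artifact trial rejection
#'
#' A trial is rejected for a feature stream when any sample magnitude in the
#' relevant channel set strictly exceeds the stream's threshold: monopolar
#' (P300 set) 90 uV, bipolar (SSSEP set) 60 uV.  The masks are stored on the
#' trials object; the SSSEP and blocking feature extractors honour the
#' bipolar mask, while P300 features use all trials by design.
#'
#' @param trials a `bci_trials` object.
#' @param threshold_mono,threshold_bipolar thresholds in microvolts.
#' @return the trials object with updated rejection masks and reason codes.
#' @export
reject_artifact_trials <- function(trials, threshold_mono = 90,
                                   threshold_bipolar = 60) {
  nt <- nrow(trials$meta)
  for (i in seq_len(nt)) {
    rb <- !is.null(trials$bipolar[[i]]) &&
      max(abs(trials$bipolar[[i]])) > threshold_bipolar
    rm_ <- !is.null(trials$mono[[i]]) &&
      max(abs(trials$mono[[i]])) > threshold_mono
    trials$rejected_bipolar[i] <- rb
    trials$rejected_mono[i] <- rm_
    trials$rejection_reason[i] <-
      if (rb && rm_) "bipolar+monopolar" else if (rb) "bipolar"
      else if (rm_) "monopolar" else NA_character_
  }
  trials
}
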