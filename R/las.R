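#' Lock-in amplifier settings
#'
#' Two presets are used throughout: the *standard* setting (2 Hz total
#' bandwidth, 1 s moving-average smoothing) for steady-state SSSEP strength,
#' and the *fast* setting (4 Hz bandwidth, no moving average) whose shorter
#' settling time resolves transient twitch-locked attenuations.  The
#' bandwidth is the total two-sided width around the demodulation frequency,
#' i.e. the low-pass cutoff is `bandwidth / 2`.
#'
#' @param preset `"standard"` or `"fast"`; explicit arguments override it.
#' @param bandwidth total demodulation bandwidth in Hz.
#' @param mav_length moving-average length in seconds, or `NULL` for none.
#' @param log_transform return log10 amplitude (logarithmic LAS features)?
#' @param filter_order low-pass order.
#' @return object of class `las_setting`.
#' @export
las_setting <- function(preset = c("standard", "fast"), bandwidth = NULL,
                        mav_length = NULL, log_transform = TRUE,
                        filter_order = 4) {
  preset <- match.arg(preset)
  if (is.null(bandwidth)) bandwidth <- if (preset == "standard") 2 else 4
  if (is.null(mav_length) && preset == "standard") mav_length <- 1
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  structure(list(bandwidth = bandwidth, mav_length = mav_length,
                 log_transform = log_transform, filter_order = filter_order),
            class = "las_setting")
}

#' Lock-in amplifier amplitude demodulation
#'
#' Quadrature demodulation at a reference frequency: the signal is multiplied
#' by unit sine and cosine at `freq`, each product is low-pass filtered
#' (zero-phase Butterworth, cutoff `bandwidth/2`), and the amplitude is
#' `2 * sqrt(I^2 + Q^2)`, so a pure sinusoid of amplitude A at `freq` reads A
#' in steady state.  An optional moving-average (MAV) filter and log10
#' transform follow, per the setting.
#'
#' @param x numeric signal.
#' @param freq demodulation (stimulation) frequency in Hz.
#' @param sample_rate Hz.
#' @param setting a [las_setting()].
#' @return amplitude time series, same length as `x`.
#' @export
lock_in_amplitude <- function(x, freq, sample_rate,
                              setting = las_setting("standard")) {
  if (freq >= sample_rate / 2) stopf("freq must be below Nyquist")
  if (setting$bandwidth / 2 >= freq) {
    stopf("bandwidth/2 = %g Hz >= freq = %g Hz: demodulation images overlap",
          setting$bandwidth / 2, freq)
  }
  lp <- butter_filter(setting$filter_order, setting$bandwidth / 2,
                      sample_rate)
  t <- (seq_along(x) - 1) / sample_rate
  padlen <- round(6 * sample_rate / setting$bandwidth)
  i <- filtfilt_iir(lp, x * cos(2 * pi * freq * t), padlen = padlen)
  q <- filtfilt_iir(lp, x * sin(2 * pi * freq * t), padlen = padlen)
  amp <- 2 * sqrt(i^2 + q^2)
  if (!is.null(setting$mav_length)) {
    amp <- moving_average(amp, round(setting$mav_length * sample_rate))
  }
  if (setting$log_transform) amp <- log10(pmax(amp, 1e-12))
  amp
}

# Centered moving average; edge windows are truncated to the available
# samples (no NA padding), keeping the series length.
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half_l <- floor((width - 1) / 2)
  half_r <- width - 1 - half_l
  lo <- pmax(seq_len(n) - half_l, 1)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' SSSEP features: mean log-LAS amplitude per trial
#'
#' For every non-rejected trial, the logarithmic LAS amplitude at each of the
#' two stimulation frequencies is extracted on every bipolar channel and
#' averaged over the window 1 to 8.5 s after cue onset, yielding
#' `n_channels x 2` features per trial (26 with the default montage).
#'
#' @param trials a `bci_trials` object (see [epoch_trials()]).
#' @param stim_freqs named c(left =, right =) stimulation frequencies in Hz
#'   (defaults to the trials' own metadata).
#' @param setting a [las_setting()]; the standard setting by default.
#' @param window averaging window in seconds relative to cue onset.
#' @return object of class `bci_features`: list with the feature matrix `x`
#'   (trials x features), `labels` (class factor), `trial_id`, and the
#'   feature `groups` vector.
#' @export
extract_sssep_features <- function(trials, stim_freqs = trials$stim_freqs,
                                   setting = las_setting("standard"),
                                   window = c(1, 8.5)) {
  keep <- which(!trials$rejected_bipolar)
  if (!length(keep)) stopf("no trials left after rejection")
  short <- trials$meta$focus_duration[keep] < window[2]
  if (any(short)) {
    stopf("trial(s) %s end before %g s after cue onset",
          paste(trials$meta$trial_id[keep][short], collapse = ", "),
          window[2])
  }
  freqs <- c(left = stim_freqs[["left"]], right = stim_freqs[["right"]])
  chans <- trials$bipolar_labels
  feat <- matrix(NA_real_, length(keep), length(chans) * 2)
  colnames(feat) <- as.vector(outer(chans, names(freqs),
                                    function(ch, h) {
                                      sprintf("%s@%gHz", ch, freqs[h])
                                    }))
  for (k in seq_along(keep)) {
    i <- keep[k]
    tt <- trial_times(trials, i)
    idx <- samples_in(tt, window[1], window[2])
    for (hand in names(freqs)) {
      for (ch in seq_along(chans)) {
        amp <- lock_in_amplitude(trials$bipolar[[i]][ch, ], freqs[[hand]],
                                 trials$sample_rate, setting)
        feat[k, (match(hand, names(freqs)) - 1) * length(chans) + ch] <-
          mean(amp[idx])
      }
    }
  }
  new_features(feat, trials$meta$class_label[keep],
               trials$meta$trial_id[keep], group = "sssep")
}

#' Blocking features: twitch-locked fast-LAS amplitude
#'
#' For every non-rejected trial and each finger, the fast-setting LAS
#' amplitude at that finger's stimulation frequency is epoched on the window
#' 0-400 ms after each of the finger's twitch onsets, averaged across the
#' twitches, and (by default) averaged over time, yielding
#' `n_channels x 2 fingers` features per trial.  Setting `decimation` to an
#' integer instead retains a block-mean decimated time course (the variant in
#' which the blocking features keep a time dimension).
#'
#' @inheritParams extract_sssep_features
#' @param setting a [las_setting()]; the fast setting by default.
#' @param window epoch window in seconds after each twitch onset.
#' @param decimation `NULL` (average over time) or a block length in samples
#'   for block-mean decimation of the averaged epoch.
#' @return a `bci_features` object with group `"blocking"`.
#' @export
extract_blocking_features <- function(trials, stim_freqs = trials$stim_freqs,
                                      setting = las_setting("fast"),
                                      window = c(0, 0.4), decimation = NULL) {
  keep <- which(!trials$rejected_bipolar)
  if (!length(keep)) stopf("no trials left after rejection")
  if (all(lengths(trials$twitch_left[keep]) == 0) &&
      all(lengths(trials$twitch_right[keep]) == 0)) {
    stopf("no twitch events present in the trials")
  }
  freqs <- c(left = stim_freqs[["left"]], right = stim_freqs[["right"]])
  chans <- trials$bipolar_labels
  fs <- trials$sample_rate
  wlen <- round((window[2] - window[1]) * fs)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    tt <- trial_times(trials, i)
    vals <- list()
    for (hand in names(freqs)) {
      onsets <- if (hand == "left") trials$twitch_left[[i]]
                else trials$twitch_right[[i]]
      if (!length(onsets)) stopf("trial %d has no %s-hand twitches",
                                 trials$meta$trial_id[i], hand)
      for (ch in seq_along(chans)) {
        amp <- lock_in_amplitude(trials$bipolar[[i]][ch, ], freqs[[hand]],
                                 fs, setting)
        ep <- sapply(onsets, function(o) {
          j0 <- which(tt >= o + window[1])[1]
          amp[j0:(j0 + wlen - 1)]
        })
        avg <- rowMeans(ep)
        v <- if (is.null(decimation)) mean(avg)
             else block_mean(avg, decimation)
        vals[[sprintf("%s@%gHz", chans[ch], freqs[[hand]])]] <- v
      }
    }
    rows[[k]] <- unlist(vals)
  }
  feat <- do.call(rbind, rows)
  new_features(feat, trials$meta$class_label[keep],
               trials$meta$trial_id[keep], group = "blocking")
}

block_mean <- function(x, block) {
  nb <- floor(length(x) / block)
  colMeans(matrix(x[seq_len(nb * block)], nrow = block))
}

new_features <- function(x, labels, trial_id, group) {
  structure(list(x = x,
                 labels = factor(labels,
                                 levels = c("focus_left", "focus_right",
                                            "idle")),
                 trial_id = trial_id,
                 groups = rep(group, ncol(x))),
            class = "bci_features")
}

#' Combine feature sets
#'
#' Column-binds feature sets (matched by trial id), optionally standardizing
#' each feature to zero mean / unit variance within its group, as used for
#' the combined SSSEP + P300 + blocking classification.
#'
#' @param ... `bci_features` objects.
#' @param standardize z-score each column?
#' @return a `bci_features` object.
#' @export
combine_features <- function(..., standardize = TRUE) {
  sets <- list(...)
  ids <- Reduce(intersect, lapply(sets, `[[`, "trial_id"))
  if (!length(ids)) stopf("no common trials across feature sets")
  mats <- lapply(sets, function(s) {
    m <- s$x[match(ids, s$trial_id), , drop = FALSE]
    if (standardize) {
      m <- scale(m)
      m[, attr(m, "scaled:scale") == 0] <- 0
    }
    m
  })
  first <- sets[[1]]
  structure(list(x = do.call(cbind, mats),
                 labels = first$labels[match(ids, first$trial_id)],
                 trial_id = ids,
                 groups = unlist(lapply(sets, `[[`, "groups"))),
            class = "bci_features")
}

#' Export / import feature matrices
#'
#' Tab-delimited text with a header row naming each feature
#' (`channel@frequency` etc.), the feature group, class label and trial id.
#'
#' @param features a `bci_features` object.
#' @param file path.
#' @export
write_features <- function(features, file) {
  df <- data.frame(trial_id = features$trial_id,
                   class_label = as.character(features$labels),
                   features$x, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Spectrogram specification
#'
#' Gaussian-window short-time Fourier transform parameters: a 4096-point FFT
#' with either a 3 s window / 2.95 s overlap (steady-state view) or a 1 s
#' window / 0.95 s overlap (transient view), trials aligned to trial start or
#' to the first twitch before averaging.
#'
#' @param window_length,overlap seconds; `overlap < window_length`.
#' @param fft_length FFT size in samples.
#' @param alignment `"trial_start"` or `"first_twitch"`.
#' @return object of class `spectrogram_spec`.
#' @export
spectrogram_spec <- function(window_length = 3, overlap = 2.95,
                             fft_length = 4096,
                             alignment = c("trial_start", "first_twitch")) {
  if (overlap >= window_length) stopf("overlap must be < window_length")
  structure(list(window_length = window_length, overlap = overlap,
                 fft_length = fft_length, alignment = match.arg(alignment)),
            class = "spectrogram_spec")
}

# Gaussian-window STFT; returns PSD (uV^2/Hz) as freq x time, one-sided.
stft_gauss <- function(x, fs, spec) {
  wl <- round(spec$window_length * fs)
  hop <- max(1, round((spec$window_length - spec$overlap) * fs))
  nfft <- spec$fft_length
  k <- seq_len(wl) - 1
  sigma <- (wl - 1) / 5                      # Gaussian window, alpha = 2.5
  w <- exp(-0.5 * ((k - (wl - 1) / 2) / sigma)^2)
  starts <- seq(1, length(x) - wl + 1, by = hop)
  nf <- nfft %/% 2 + 1
  psd <- matrix(0, nf, length(starts))
  scale <- fs * sum(w^2)
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + k] * w
    X <- stats::fft(c(seg, rep(0, nfft - wl)))[seq_len(nf)]
    p <- Mod(X)^2 / scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]       # one-sided
    psd[, j] <- p
  }
  list(psd = psd, freq = (seq_len(nf) - 1) * fs / nfft,
       time = (starts - 1 + wl / 2) / fs)
}

#' Trial-averaged spectrograms per twitch pattern
#'
#' Computes a Gaussian-window STFT power spectral density for one bipolar
#' channel of every trial, aligns trials belonging to the same twitch pattern
#' (to trial start or to the first twitch), averages their PSDs, and returns
#' the result in dB (reference 1 uV^2/Hz).
#'
#' @param trials a `bci_trials` object.
#' @param channel a bipolar channel label, e.g. `"FC3-CP3"`.
#' @param spec a [spectrogram_spec()].
#' @return list per pattern id with elements `psd_db` (freq x time), `freq`
#'   (Hz), `time` (s relative to the alignment anchor), and `n_trials`.
#'   Pattern groups with no trials are omitted with a warning.
#' @export
compute_spectrogram <- function(trials, channel = "FC3-CP3",
                                spec = spectrogram_spec()) {
  ch <- match(channel, trials$bipolar_labels)
  if (is.na(ch)) stopf("channel %s not in the bipolar set", channel)
  fs <- trials$sample_rate
  pat_ids <- sort(unique(trials$meta$pattern_id))
  out <- list()
  for (pid in pat_ids) {
    sel <- which(trials$meta$pattern_id == pid & !trials$rejected_bipolar)
    if (!length(sel)) {
      warning(sprintf("no trials for pattern %d; group omitted", pid))
      next
    }
    # common relative window across the group's trials
    anchor <- sapply(sel, function(i) {
      if (spec$alignment == "trial_start") {
        trial_times(trials, i)[1]
      } else {
        min(c(trials$twitch_left[[i]], trials$twitch_right[[i]]))
      }
    })
    t_lo <- max(sapply(seq_along(sel), function(k) {
      trial_times(trials, sel[k])[1] - anchor[k]
    }))
    t_hi <- min(sapply(seq_along(sel), function(k) {
      tt <- trial_times(trials, sel[k])
      tt[length(tt)] - anchor[k]
    }))
    if (t_hi - t_lo < spec$window_length) {
      warning(sprintf("pattern %d: common window shorter than the STFT window",
                      pid))
      next
    }
    acc <- NULL
    for (k in seq_along(sel)) {
      i <- sel[k]
      tt <- trial_times(trials, i) - anchor[k]
      idx <- samples_in(tt, t_lo, t_hi + 1 / fs)
      st <- stft_gauss(trials$bipolar[[i]][ch, idx], fs, spec)
      acc <- if (is.null(acc)) st$psd else acc + st$psd
    }
    psd <- acc / length(sel)
    out[[as.character(pid)]] <- list(
      psd_db = 10 * log10(pmax(psd, 1e-20)), freq = st$freq,
      time = st$time + t_lo, n_trials = length(sel))
  }
  out
}
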