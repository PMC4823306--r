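#' Tuning-curve map from a screening recording
#'
#' For every combination of stimulation frequency, finger and screening
#' bipolar channel, computes the percentage band-power increase of the
#' stimulation intervals relative to the same trial's reference period.
#' Band power is the variance of the signal band-passed in a 2 Hz band
#' centered on the stimulation frequency; only the last `analysis_window`
#' seconds of each 2.3 s stimulation interval are used.  A percentile
#' bootstrap confidence interval of the mean is attached per cell.
#'
#' @param recording a screening [eeg_recording()] (with its
#'   `screening_schedule` attached, as produced by [simulate_session()]), or
#'   pass `schedule` explicitly.
#' @param montage a [default_montage()]-style montage; the
#'   `screening_pairs` set is used.
#' @param schedule override the recording's schedule.
#' @param bandwidth band width in Hz around each frequency.
#' @param n_boot bootstrap samples for the confidence intervals.
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return a `data.frame` of class `tuning_map` with columns `freq`,
#'   `finger`, `channel`, `rel_bp` (%), `ci_low`, `ci_high`, `n`; the
#'   per-interval relative band powers are kept in the `"samples"` attribute.
#' @export
compute_tuning_map <- function(recording, montage = default_montage(),
                               schedule = recording$schedule,
                               bandwidth = 2, n_boot = 1000, level = 0.95,
                               seed = 1) {
  if (is.null(schedule)) stopf("no screening schedule available")
  iv <- schedule$intervals
  trials <- schedule$trials
  fs <- recording$sample_rate
  bip <- derive_bipolar(recording, montage$screening_pairs)
  chans <- bip$channel_labels
  freqs <- sort(unique(iv$freq))
  n <- ncol(bip$data)
  t <- (seq_len(n) - 1) / fs
  win <- schedule$analysis_window
  samples <- list()
  for (ch in seq_along(chans)) {
    for (f in freqs) {
      banded <- bandpass_demod(bip$data[ch, ], f, bandwidth, fs)
      ref_power <- vapply(seq_len(nrow(trials)), function(k) {
        idx <- samples_in(t, trials$t_ref_start[k],
                          trials$t_ref_start[k] + trials$ref_duration[k])
        stats::var(banded[idx])
      }, numeric(1))
      if (any(ref_power <= 0)) stopf("zero reference band power")
      sel <- which(iv$freq == f)
      for (j in sel) {
        idx <- samples_in(t, iv$t_end[j] - win, iv$t_end[j])
        bp <- stats::var(banded[idx])
        ref <- ref_power[match(iv$trial_id[j], trials$trial_id)]
        key <- paste(f, iv$finger[j], chans[ch], sep = "|")
        samples[[key]] <- c(samples[[key]], 100 * (bp - ref) / ref)
      }
    }
  }
  rows <- lapply(names(samples), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    x <- samples[[key]]
    ci <- bootstrap_ci(x, n_boot = n_boot, level = level,
                       seed = derive_seed(seed, which(names(samples) == key)))
    data.frame(freq = as.numeric(parts[1]), finger = parts[2],
               channel = parts[3], rel_bp = mean(x),
               ci_low = ci[1], ci_high = ci[2], n = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$finger, out$channel, out$freq), ]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  class(out) <- c("tuning_map", "data.frame")
  out
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param x numeric sample (>= 2 values).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return numeric c(low, high).
#' @export
bootstrap_ci <- function(x, n_boot = 1000, level = 0.95, seed = NULL) {
  if (length(x) < 2) stopf("bootstrap_ci needs at least 2 samples")
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    alpha <- (1 - level) / 2
    stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
}

#' Automatic stimulation-frequency selection
#'
#' Codifies the screening selection rule: over all ordered frequency pairs
#' (left response read at the right-hemisphere channel, right response at the
#' left-hemisphere channel) separated by at least one other grid frequency
#' (|f_L - f_R| >= `min_separation` Hz), pick the pair maximizing the smaller
#' of the two responses; ties are broken by the more similar responses, then
#' by the lower frequency sum.
#'
#' @param map a `tuning_map`.
#' @param left_channel channel carrying the left-finger response
#'   (contralateral, default `"FC4-CP4"`).
#' @param right_channel channel carrying the right-finger response
#'   (default `"FC3-CP3"`).
#' @param min_separation minimum |f_L - f_R| in Hz.
#' @return named numeric c(f_left, f_right).
#' @export
select_frequencies <- function(map, left_channel = "FC4-CP4",
                               right_channel = "FC3-CP3",
                               min_separation = 4) {
  resp <- function(finger, channel) {
    sub <- map[map$finger == finger & map$channel == channel, ]
    stats::setNames(sub$rel_bp, sub$freq)
  }
  rl <- resp("left", left_channel)
  rr <- resp("right", right_channel)
  if (!length(rl) || !length(rr)) stopf("tuning map incomplete")
  best <- NULL
  for (fl in as.numeric(names(rl))) {
    for (fr in as.numeric(names(rr))) {
      if (abs(fl - fr) < min_separation) next
      cand <- c(min(rl[as.character(fl)], rr[as.character(fr)]),
                -abs(rl[as.character(fl)] - rr[as.character(fr)]),
                -(fl + fr))
      if (is.null(best) || lexi_greater(cand, best$score)) {
        best <- list(score = cand, f = c(f_left = fl, f_right = fr))
      }
    }
  }
  if (is.null(best)) stopf("no feasible frequency pair")
  best$f
}

# Lexicographic comparison with tolerance on the leading criteria.
lexi_greater <- function(a, b, tol = 1e-9) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + tol) return(TRUE)
    if (a[i] < b[i] - tol) return(FALSE)
  }
  FALSE
}

#' Export a tuning map as delimited text
#'
#' @param map a `tuning_map`.
#' @param file path.
#' @export
write_tuning_map <- function(map, file) {
  utils::write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
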