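#' Permutation-test configuration for SSSEP blocking
#'
#' The twitch-locked blocking test scans 50 ms windows at lags from -500 to
#' +500 ms around twitch onsets (20 non-overlapping half-open windows
#' `[onset + lag, onset + lag + 0.05)`), on the two bipolar channels above
#' the hand areas, for both fingers, with a Bonferroni correction over
#' windows x fingers x channels.
#'
#' @param n_permutations Monte-Carlo permutations N (the paper-scale value is
#'   100,000; desk-scale runs use fewer).
#' @param window_length window length in seconds.
#' @param lag_grid window start lags in seconds relative to twitch onset.
#' @param alpha significance level before correction.
#' @param channels bipolar channels tested.
#' @return object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 100000, window_length = 0.05,
                        lag_grid = seq(-0.5, 0.45, by = 0.05), alpha = 0.01,
                        channels = c("FC3-CP3", "FC4-CP4")) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (length(lag_grid) > 1 &&
      any(diff(sort(lag_grid)) < window_length - 1e-12)) {
    stopf("lag windows must not overlap")
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 window_length = window_length, lag_grid = lag_grid,
                 alpha = alpha, channels = channels),
            class = "perm_config")
}

# Fast-LAS (pre-log) amplitude series for one bipolar channel at one
# frequency, for the non-rejected trials.  Returns amp (list), t0 (first
# sample time relative to cue) and fs.
blocking_amplitude_series <- function(trials, freq, channel,
                                      setting = las_setting(
                                        "fast", log_transform = FALSE)) {
  ch <- match(channel, trials$bipolar_labels)
  if (is.na(ch)) stopf("channel %s not in the bipolar set", channel)
  keep <- which(!trials$rejected_bipolar)
  amp <- lapply(keep, function(i) {
    lock_in_amplitude(trials$bipolar[[i]][ch, ], freq, trials$sample_rate,
                      setting)
  })
  t0 <- vapply(keep, function(i) trial_times(trials, i)[1], numeric(1))
  list(amp = amp, t0 = t0, fs = trials$sample_rate, trial_index = keep)
}

# Per-trial twitch-window sums for every candidate pattern and lag.
# Returns list(S, C): arrays [trial, pattern, lag] of window-mean sums and
# usable-window counts (windows outside the trial span are skipped).
window_sums <- function(amp_trials, patterns, finger, lags, window_length) {
  fs <- amp_trials$fs
  wlen <- max(1L, round(window_length * fs))
  nt <- length(amp_trials$amp)
  np <- length(patterns)
  S <- array(0, c(nt, np, length(lags)))
  C <- array(0L, c(nt, np, length(lags)))
  onsets_of <- lapply(patterns, function(p) {
    if (finger == "left") p$onsets_left else p$onsets_right
  })
  for (i in seq_len(nt)) {
    a <- amp_trials$amp[[i]]
    cs <- c(0, cumsum(a))
    len <- length(a)
    t0 <- amp_trials$t0[i]
    for (p in seq_len(np)) {
      for (l in seq_along(lags)) {
        starts <- onsets_of[[p]] + lags[l]
        j0 <- ceiling((starts - t0) * fs - 1e-9) + 1L
        ok <- j0 >= 1L & (j0 + wlen - 1L) <= len
        if (any(ok)) {
          j <- j0[ok]
          S[i, p, l] <- sum((cs[j + wlen] - cs[j]) / wlen)
          C[i, p, l] <- sum(ok)
        }
      }
    }
  }
  list(S = S, C = C)
}

#' Twitch-locked windowed amplitude statistic
#'
#' The mean SSSEP amplitude over all trials and twitches, each amplitude
#' averaged within the half-open window
#' `[onset + lag, onset + lag + window_length)`, with twitch onsets taken
#' from the pattern assigned to each trial.  Windows falling outside a
#' trial's span are skipped; it is an error if all windows are skipped.
#'
#' @param amp_trials per-trial amplitude series: a list with `amp` (list of
#'   numeric vectors, fast-LAS pre-log amplitude), `t0` (first-sample time of
#'   each series relative to cue onset, seconds) and `fs` (Hz), as built
#'   internally by [scan_blocking()].
#' @param assignment integer vector: pattern id per trial.
#' @param patterns list of `twitch_pattern`s.
#' @param finger `"left"` or `"right"`.
#' @param lag window start relative to twitch onset, seconds.
#' @param window_length window length, seconds.
#' @return the mean windowed amplitude (scalar).
#' @export
twitch_locked_statistic <- function(amp_trials, assignment, patterns, finger,
                                    lag, window_length = 0.05) {
  sc <- window_sums(amp_trials, patterns, finger, lag, window_length)
  idx <- cbind(seq_along(assignment), assignment, 1L)
  tot_c <- sum(sc$C[idx])
  if (tot_c == 0) stopf("all twitch windows fall outside the trial spans")
  sum(sc$S[idx]) / tot_c
}

#' Monte-Carlo permutation test for a single lag window
#'
#' Tests for a twitch-locked decrease in SSSEP amplitude: the null
#' distribution consists of the statistic under the real pattern-to-trial
#' assignment plus `n_permutations` random shuffles of the assignment vector
#' (preserving the overall distribution of twitch positions), and the false
#' positive probability (FPP) is the fraction of null values lower than or
#' equal to the observed one.  The FPP can never be smaller than
#' `1 / (N + 1)`.
#'
#' @inheritParams twitch_locked_statistic
#' @param config a [perm_config()].
#' @param seed RNG seed.
#' @return the FPP (scalar).
#' @export
permutation_test <- function(amp_trials, assignment, patterns, finger, lag,
                             config = perm_config(), seed = 1) {
  if (length(unique(assignment)) < 2) {
    stopf("need at least two distinct patterns in the assignment")
  }
  sc <- window_sums(amp_trials, patterns, finger, lag, config$window_length)
  S <- sc$S[, , 1]; C <- sc$C[, , 1]
  n <- length(assignment)
  idx <- cbind(seq_len(n), assignment)
  obs <- sum(S[idx]) / sum(C[idx])
  null <- with_seed(seed, {
    vapply(seq_len(config$n_permutations), function(j) {
      a <- sample(assignment)
      id <- cbind(seq_len(n), a)
      sum(S[id]) / sum(C[id])
    }, numeric(1))
  })
  (1 + sum(null <= obs)) / (config$n_permutations + 1)
}

#' Scan for significant twitch-locked SSSEP blocking
#'
#' Runs the Monte-Carlo permutation test on every (lag window x finger x
#' channel) cell: amplitude series are fast-setting (pre-log) LAS outputs at
#' each finger's stimulation frequency on the tested bipolar channels; all
#' non-rejected trials enter regardless of class.  Within each (finger,
#' channel) the same permutations are reused across lag windows.  Cells with
#' FPP below the Bonferroni-corrected level
#' `alpha / (n_lags * n_fingers * n_channels)` are flagged, and adjacent
#' significant lags are merged into reported blocking intervals.
#'
#' @param trials a `bci_trials` object.
#' @param stim_freqs named c(left =, right =) stimulation frequencies.
#' @param config a [perm_config()].
#' @param seed RNG seed.
#' @return object of class `blocking_scan`: arrays `fpp`, `observed`,
#'   `significant` (lag x finger x channel), `alpha_corrected`, and a
#'   data.frame `intervals` (finger, channel, lag_start_ms, lag_end_ms,
#'   min_fpp) of merged significant windows.
#' @export
scan_blocking <- function(trials, stim_freqs = trials$stim_freqs,
                          config = perm_config(), seed = 1) {
  patterns <- trials$patterns
  if (length(unique(trials$meta$pattern_id)) < 2) {
    stopf("need at least two distinct patterns across trials")
  }
  lags <- config$lag_grid
  fingers <- c("left", "right")
  dims <- c(length(lags), length(fingers), length(config$channels))
  dn <- list(lag = sprintf("%g", lags), finger = fingers,
             channel = config$channels)
  fpp <- array(NA_real_, dims, dimnames = dn)
  obs_arr <- array(NA_real_, dims, dimnames = dn)
  keep <- which(!trials$rejected_bipolar)
  assignment <- trials$meta$pattern_id[keep]
  n <- length(assignment)
  N <- config$n_permutations
  # shared permutations per seed: identical shuffles reused across cells
  perm_idx <- with_seed(seed, {
    m <- matrix(0L, N, n)
    for (j in seq_len(N)) m[j, ] <- sample.int(n)
    m
  })
  P <- matrix(assignment[perm_idx], N, n)
  LIN <- (P - 1L) * n + matrix(rep(seq_len(n), each = N), N, n)
  for (ci in seq_along(config$channels)) {
    for (fi in seq_along(fingers)) {
      amp <- blocking_amplitude_series(
        trials, stim_freqs[[fingers[fi]]], config$channels[ci])
      sc <- window_sums(amp, patterns, fingers[fi], lags,
                        config$window_length)
      for (l in seq_along(lags)) {
        S <- sc$S[, , l]; C <- sc$C[, , l]
        idx <- cbind(seq_len(n), assignment)
        o <- sum(S[idx]) / sum(C[idx])
        null <- rowSums(matrix(S[LIN], N, n)) /
          rowSums(matrix(C[LIN], N, n))
        fpp[l, fi, ci] <- (1 + sum(null <= o)) / (N + 1)
        obs_arr[l, fi, ci] <- o
      }
    }
  }
  alpha_c <- config$alpha / prod(dims)
  signif <- fpp < alpha_c
  intervals <- list()
  for (ci in seq_along(config$channels)) {
    for (fi in seq_along(fingers)) {
      flags <- signif[, fi, ci]
      r <- rle(flags)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (g in which(r$values)) {
        sel <- starts[g]:ends[g]
        intervals[[length(intervals) + 1]] <- data.frame(
          finger = fingers[fi], channel = config$channels[ci],
          lag_start_ms = 1000 * lags[starts[g]],
          lag_end_ms = 1000 * (lags[ends[g]] + config$window_length),
          min_fpp = min(fpp[sel, fi, ci]), stringsAsFactors = FALSE)
      }
    }
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(finger = character(), channel = character(),
               lag_start_ms = numeric(), lag_end_ms = numeric(),
               min_fpp = numeric())
  structure(list(fpp = fpp, observed = obs_arr, significant = signif,
                 alpha_corrected = alpha_c, intervals = intervals,
                 config = config, n_trials = n),
            class = "blocking_scan")
}

#' @export
print.blocking_scan <- function(x, ...) {
  cat(sprintf(
    "<blocking_scan> %d trials, N = %d permutations, corrected alpha %.3g\n",
    x$n_trials, x$config$n_permutations, x$alpha_corrected))
  if (nrow(x$intervals)) {
    cat("significant blocking intervals:\n")
    print(x$intervals, row.names = FALSE)
  } else cat("no significant blocking intervals\n")
  invisible(x)
}
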