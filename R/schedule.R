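#' Generate a cue-based BCI session schedule
#'
#' Builds the trial timeline of the three-class attention paradigm.  Each
#' trial starts with a beep (`t_trial_start`), stimulation of both fingers
#' begins 0.2 s later, a reference period of random length 1-1.5 s starts
#' 0.5 s after trial start, the cue (focus left / focus right / idle) appears
#' at the end of the reference period, and the focus/idle period lasts a
#' random 9.5-10 s.  Twitches occur only inside the focus period.  Trials end
#' with 2 s of feedback and a random 3-4 s break.  Class labels are balanced
#' and randomly ordered within each run; each trial is assigned one of the
#' available twitch patterns uniformly at random.
#'
#' @param n_runs number of runs.
#' @param trials_per_class_per_run trials per class in each run.
#' @param patterns list of `twitch_pattern`s (see
#'   [generate_twitch_patterns()]).
#' @param seed RNG seed; the schedule is bit-reproducible given the seed.
#' @return a `data.frame` of class `bci_schedule` with one row per trial:
#'   `trial_id`, `run`, `class_label`, `t_trial_start`, `t_stim_start`,
#'   `t_ref_start`, `ref_duration`, `t_cue_onset`, `focus_duration`,
#'   `t_trial_end`, `pattern_id` (times in seconds from session start).
#' @export
generate_bci_schedule <- function(n_runs = 8, trials_per_class_per_run = 10,
                                  patterns, seed = NULL) {
  if (!length(patterns)) stopf("at least one twitch pattern is required")
  if (n_runs < 1 || trials_per_class_per_run < 1) {
    stopf("invalid run/trial counts")
  }
  classes <- c("focus_left", "focus_right", "idle")
  with_seed(seed, {
    rows <- list()
    t0 <- 0
    trial_id <- 0L
    for (run in seq_len(n_runs)) {
      labels <- sample(rep(classes, trials_per_class_per_run))
      for (lab in labels) {
        trial_id <- trial_id + 1L
        ref_dur <- stats::runif(1, 1, 1.5)
        focus_dur <- stats::runif(1, 9.5, 10)
        cue <- t0 + 0.5 + ref_dur
        end <- cue + focus_dur
        rows[[trial_id]] <- data.frame(
          trial_id = trial_id, run = run, class_label = lab,
          t_trial_start = t0, t_stim_start = t0 + 0.2,
          t_ref_start = t0 + 0.5, ref_duration = ref_dur,
          t_cue_onset = cue, focus_duration = focus_dur,
          t_trial_end = end,
          pattern_id = sample.int(length(patterns), 1),
          stringsAsFactors = FALSE)
        t0 <- end + 2 + stats::runif(1, 3, 4)  # feedback + inter-trial break
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("bci_schedule", "data.frame")
    out
  })
}

#' Generate a screening session schedule
#'
#' Builds the frequency-screening timeline: `n_runs` runs of
#' `trials_per_run` trials; each trial starts with a reference period of
#' random length 3-3.5 s followed by 10 stimulation intervals of 2.3 s
#' (of which the last 2 s are analysed) separated by 0.25 s pauses.  The
#' (frequency, finger) assignment is balanced -- with the defaults each of
#' the 10 frequencies x 2 fingers occurs exactly 40 times (800 intervals) --
#' and the same (frequency, finger) pair never occurs in two consecutive
#' intervals within a run (including across trial boundaries).
#'
#' @param seed RNG seed.
#' @param n_runs,trials_per_run,intervals_per_trial session layout.
#' @param freqs stimulation frequency grid in Hz.
#' @param interval_length,pause_length,analysis_window interval timing (s).
#' @return list of class `screening_schedule` with elements `trials`
#'   (data.frame: run, trial_id, t_trial_start, ref_duration, t_ref_start)
#'   and `intervals` (data.frame: run, trial_id, interval, freq, finger,
#'   t_start, t_end).
#' @export
generate_screening_schedule <- function(seed = NULL, n_runs = 8,
                                        trials_per_run = 10,
                                        intervals_per_trial = 10,
                                        freqs = seq(17, 35, by = 2),
                                        interval_length = 2.3,
                                        pause_length = 0.25,
                                        analysis_window = 2) {
  combos <- expand.grid(freq = freqs, finger = c("left", "right"),
                        stringsAsFactors = FALSE)
  n_per_run <- trials_per_run * intervals_per_trial
  if (n_per_run %% nrow(combos) != 0) {
    stopf("intervals per run (%d) must be a multiple of %d combinations",
          n_per_run, nrow(combos))
  }
  reps <- n_per_run / nrow(combos)
  with_seed(seed, {
    trials <- list(); intervals <- list()
    t0 <- 0; trial_id <- 0L
    for (run in seq_len(n_runs)) {
      pool <- combos[rep(seq_len(nrow(combos)), reps), ]
      ord <- shuffle_no_adjacent(paste(pool$freq, pool$finger))
      pool <- pool[ord, ]
      k <- 0L
      for (tr in seq_len(trials_per_run)) {
        trial_id <- trial_id + 1L
        ref_dur <- stats::runif(1, 3, 3.5)
        trials[[trial_id]] <- data.frame(
          run = run, trial_id = trial_id, t_trial_start = t0,
          ref_duration = ref_dur, t_ref_start = t0)
        t <- t0 + ref_dur
        for (iv in seq_len(intervals_per_trial)) {
          k <- k + 1L
          intervals[[length(intervals) + 1L]] <- data.frame(
            run = run, trial_id = trial_id, interval = iv,
            freq = pool$freq[k], finger = pool$finger[k],
            t_start = t, t_end = t + interval_length)
          t <- t + interval_length + pause_length
        }
        t0 <- t + 1  # short gap before the next trial
      }
    }
    structure(list(trials = do.call(rbind, trials),
                   intervals = do.call(rbind, intervals),
                   analysis_window = analysis_window),
              class = "screening_schedule")
  })
}

# Random permutation of indices such that no two adjacent elements of
# key[perm] are equal; random swap repair with reshuffle fallback.
shuffle_no_adjacent <- function(key, max_iter = 10000) {
  n <- length(key)
  for (restart in 1:100) {
    perm <- sample.int(n)
    for (it in seq_len(max_iter)) {
      bad <- which(key[perm][-1] == key[perm][-n]) + 1L
      if (!length(bad)) return(perm)
      i <- bad[1]
      j <- sample.int(n, 1)
      perm[c(i, j)] <- perm[c(j, i)]
    }
  }
  stopf("could not find an adjacency-free ordering")
}

#' Event table of a BCI schedule
#'
#' Flattens a schedule plus its twitch patterns into the marker stream
#' recorded alongside the EEG: trial starts/ends, cue onsets with class, and
#' per-hand twitch onsets (absolute session time).
#'
#' @param schedule a `bci_schedule`.
#' @param patterns the list of `twitch_pattern`s the schedule refers to.
#' @return data.frame with columns `time_s`, `event_type` (one of
#'   trial_start, cue_left, cue_right, cue_idle, twitch_left, twitch_right,
#'   trial_end), `trial_id`, `pattern_id`, ordered by time.
#' @export
make_event_table <- function(schedule, patterns) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    s <- schedule[i, ]
    p <- patterns[[s$pattern_id]]
    cue_type <- switch(s$class_label, focus_left = "cue_left",
                       focus_right = "cue_right", idle = "cue_idle")
    ev <- data.frame(
      time_s = c(s$t_trial_start, s$t_cue_onset,
                 s$t_cue_onset + p$onsets_left,
                 s$t_cue_onset + p$onsets_right, s$t_trial_end),
      event_type = c("trial_start", cue_type,
                     rep("twitch_left", length(p$onsets_left)),
                     rep("twitch_right", length(p$onsets_right)),
                     "trial_end"),
      trial_id = s$trial_id, pattern_id = s$pattern_id,
      stringsAsFactors = FALSE)
    ev[order(ev$time_s), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write event tables
#'
#' Tab-delimited text with header, one marker per line.
#'
#' @param events event table as returned by [make_event_table()].
#' @param file path.
#' @export
write_event_table <- function(events, file) {
  utils::write.table(events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
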