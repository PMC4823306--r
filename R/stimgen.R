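#' Tactile stimulation configuration
#'
#' Parameters of the vibrotactile stimulation: a 237 Hz sinusoidal carrier,
#' amplitude-modulated by a rectangular envelope at the per-hand stimulation
#' frequency (17-35 Hz in 2 Hz steps) with a duty cycle close to 50%,
#' realized so that every on-segment contains an integer number of full
#' carrier cycles (the carrier always starts and stops at phase zero).
#'
#' @param carrier_freq carrier frequency in Hz.
#' @param stim_freq_left,stim_freq_right stimulation (envelope) frequencies
#'   in Hz; must lie on the 17, 19, ..., 35 Hz grid.
#' @param sample_rate waveform sampling rate in Hz.
#' @param duty_cycle_target target on-fraction of each envelope period; the
#'   realizable duty cycle nearest to it is used.
#' @return object of class `stim_config`.
#' @export
stim_config <- function(carrier_freq = 237, stim_freq_left = 27,
                        stim_freq_right = 23, sample_rate = 600,
                        duty_cycle_target = 0.5) {
  grid <- seq(17, 35, by = 2)
  for (f in c(stim_freq_left, stim_freq_right)) {
    if (!f %in% grid) {
      stopf("stimulation frequency %g Hz not on the 17-35 Hz (step 2) grid", f)
    }
  }
  if (carrier_freq <= max(stim_freq_left, stim_freq_right)) {
    stopf("carrier frequency must exceed the stimulation frequencies")
  }
  if (duty_cycle_target <= 0 || duty_cycle_target >= 1) {
    stopf("duty_cycle_target must be in (0, 1)")
  }
  structure(list(carrier_freq = carrier_freq,
                 stim_freq_left = stim_freq_left,
                 stim_freq_right = stim_freq_right,
                 sample_rate = sample_rate,
                 duty_cycle_target = duty_cycle_target),
            class = "stim_config")
}

# Number of full carrier cycles per on-segment: nearest integer to
# target * carrier / stim, but at least 1.
carrier_cycles_on <- function(freq, config) {
  max(1L, round(config$duty_cycle_target * config$carrier_freq / freq))
}

#' Generate one stimulation waveform
#'
#' Builds the amplitude-modulated stimulation signal for one hand: a
#' sinusoidal carrier gated by a rectangular envelope at `freq`.  Each
#' envelope period starts with an on-segment that spans an integer count of
#' carrier periods, so the carrier starts and stops at phase zero; the
#' effective duty cycle is the realizable value nearest the configured
#' target.
#'
#' @param freq stimulation (envelope) frequency in Hz.
#' @param duration waveform duration in seconds.
#' @param config a [stim_config()].
#' @return object of class `stim_waveform`: list with `waveform`, `envelope`
#'   (the rectangular gate, 0/1), `sample_rate`, `freq`, `duty_cycle`.
#' @export
generate_stimulus_waveform <- function(freq, duration, config = stim_config()) {
  if (freq <= 0) stopf("stimulation frequency must be positive")
  if (config$carrier_freq <= 2 * freq) {
    stopf("carrier frequency must exceed twice the stimulation frequency")
  }
  if (duration < 0) stopf("duration must be >= 0")
  fs <- config$sample_rate
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 1 / freq
  m <- carrier_cycles_on(freq, config)
  on_time <- m / config$carrier_freq
  phase_in_period <- t %% period
  envelope <- as.numeric(phase_in_period < on_time)
  # carrier phase restarts at zero at each envelope period start
  waveform <- envelope * sin(2 * pi * config$carrier_freq * phase_in_period)
  structure(list(waveform = waveform, envelope = envelope,
                 sample_rate = fs, freq = freq,
                 carrier_freq = config$carrier_freq,
                 duty_cycle = on_time / period),
            class = "stim_waveform")
}

#' Insert twitches into a stimulation waveform or envelope
#'
#' A twitch is a complete interruption (100% attenuation) of the repetitive
#' stimulation for exactly one period of the stimulation frequency: the
#' signal is forced to zero on the half-open window `[onset, onset + 1/freq)`
#' for each twitch onset.
#'
#' @param x a `stim_waveform` or a numeric envelope sampled at `sample_rate`.
#' @param onsets twitch onset times in seconds (relative to the start of
#'   `x`).
#' @param freq stimulation frequency in Hz (taken from `x` when it is a
#'   `stim_waveform`).
#' @param sample_rate required when `x` is a bare numeric vector.
#' @return same type as `x`, with the twitch windows zeroed.
#' @export
insert_twitches <- function(x, onsets, freq = NULL, sample_rate = NULL) {
  if (inherits(x, "stim_waveform")) {
    freq <- freq %||% x$freq
    sample_rate <- x$sample_rate
    sig <- x$waveform
  } else {
    if (is.null(freq) || is.null(sample_rate)) {
      stopf("freq and sample_rate are required for a numeric envelope")
    }
    sig <- x
  }
  if (!length(onsets)) return(x)
  onsets <- sort(onsets)
  dur <- length(sig) / sample_rate
  if (any(onsets < 0) || any(onsets + 1 / freq > dur + 1e-9)) {
    stopf("twitch windows must lie within the signal span")
  }
  if (any(diff(onsets) < 1 / freq - 1e-12)) {
    stopf("twitch windows overlap")
  }
  t <- (seq_along(sig) - 1) / sample_rate
  for (o in onsets) {
    idx <- samples_in(t, o, o + 1 / freq)
    sig[idx] <- 0
  }
  if (inherits(x, "stim_waveform")) {
    x$waveform <- sig
    for (o in onsets) x$envelope[samples_in(t, o, o + 1 / freq)] <- 0
    x
  } else sig
}

#' Generate pseudo-randomized twitch patterns
#'
#' Draws `n_patterns` twitch patterns, each with `n_twitches` onsets per hand
#' inside the focus period, such that consecutive onsets pooled within and
#' across hands are separated by at least `min_isi`.  Onsets are drawn by
#' uniform rejection sampling (up to 10,000 attempts per pattern).  When the
#' per-hand stimulation frequencies are supplied, onsets are drawn directly
#' on that hand's envelope period grid (a twitch deletes exactly one envelope
#' period), so the ISI constraint holds exactly after quantization.
#'
#' @param n_patterns number of patterns.
#' @param n_twitches twitches per hand per pattern.
#' @param focus_duration length of the focus period in seconds; onsets are
#'   placed so the whole one-period interruption fits inside it.
#' @param min_isi minimum pooled inter-stimulus interval in seconds.
#' @param freq_left,freq_right stimulation frequencies in Hz, or `NULL` for
#'   continuous (unquantized) onsets.
#' @param seed RNG seed.
#' @return list of `twitch_pattern` objects with fields `pattern_id`,
#'   `onsets_left`, `onsets_right` (seconds, relative to focus-period start).
#' @export
generate_twitch_patterns <- function(n_patterns = 3, n_twitches = 7,
                                     focus_duration = 9.5, min_isi = 0.25,
                                     freq_left = NULL, freq_right = NULL,
                                     seed = NULL) {
  if (n_twitches > 0 && 2 * n_twitches * min_isi >= focus_duration) {
    stopf(paste0("infeasible parameters: 2 * n_twitches * min_isi = %.3g s ",
                 "must be smaller than focus_duration = %.3g s"),
          2 * n_twitches * min_isi, focus_duration)
  }
  with_seed(seed, {
    lapply(seq_len(n_patterns), function(pid) {
      if (n_twitches == 0) {
        return(structure(list(pattern_id = pid, onsets_left = numeric(0),
                              onsets_right = numeric(0)),
                         class = "twitch_pattern"))
      }
      draw_hand <- function(freq) {
        if (is.null(freq)) {
          sort(stats::runif(n_twitches, 0, focus_duration))
        } else {
          period <- 1 / freq
          ngrid <- floor(focus_duration / period) # onset k*period, window fits
          sort(period * (sample.int(ngrid, n_twitches) - 1L))
        }
      }
      for (attempt in seq_len(10000)) {
        left <- draw_hand(freq_left)
        right <- draw_hand(freq_right)
        pooled <- sort(c(left, right))
        if (all(diff(pooled) >= min_isi)) {
          return(structure(list(pattern_id = pid, onsets_left = left,
                                onsets_right = right),
                           class = "twitch_pattern"))
        }
      }
      stopf("could not satisfy pooled ISI >= %g s in 10000 attempts", min_isi)
    })
  })
}

validate_twitch_pattern <- function(p, focus_duration, min_isi = 0.25) {
  stopifnot(!is.unsorted(p$onsets_left, strictly = TRUE),
            !is.unsorted(p$onsets_right, strictly = TRUE))
  pooled <- sort(c(p$onsets_left, p$onsets_right))
  if (length(pooled) > 1 && any(diff(pooled) < min_isi - 1e-12)) {
    stopf("pattern %d violates the pooled ISI constraint", p$pattern_id)
  }
  if (length(pooled) && (min(pooled) < 0 || max(pooled) > focus_duration)) {
    stopf("pattern %d has onsets outside the focus period", p$pattern_id)
  }
  invisible(TRUE)
}
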