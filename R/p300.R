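#' P300 extraction configuration
#'
#' @param lowpass_cutoff low-pass edge in Hz applied to the monopolar
#'   channels before epoching.
#' @param filter_order Butterworth order of that low-pass.
#' @param epoch_window window after each twitch onset, seconds (half-open).
#' @param downsample_factor block-mean decimation factor applied after
#'   averaging; must divide the epoch sample count.
#' @return object of class `p300_config`.
#' @export
p300_config <- function(lowpass_cutoff = 10, filter_order = 3,
                        epoch_window = c(0, 0.8), downsample_factor = 10) {
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 filter_order = filter_order,
                 epoch_window = epoch_window,
                 downsample_factor = downsample_factor),
            class = "p300_config")
}

# Low-pass the monopolar channels of every trial and cut per-twitch epochs.
# Returns, per trial and hand, a 3-d array (channels x samples x twitches) of
# linearly detrended epochs.  Epochs running past the trial's data are
# dropped with a warning.
extract_p300_epochs <- function(trials, config = p300_config()) {
  if (!length(trials$mono_labels)) stopf("monopolar channels not present")
  fs <- trials$sample_rate
  lp <- butter_filter(config$filter_order, config$lowpass_cutoff, fs)
  wlen <- round((config$epoch_window[2] - config$epoch_window[1]) * fs)
  nt <- nrow(trials$meta)
  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    m <- trials$mono[[i]]
    filt <- t(apply(m, 1, function(x) filtfilt_iir(lp, x, padlen = 200)))
    tt <- trial_times(trials, i)
    per_hand <- list()
    for (hand in c("left", "right")) {
      onsets <- if (hand == "left") trials$twitch_left[[i]]
                else trials$twitch_right[[i]]
      eps <- list()
      for (o in onsets) {
        j0 <- which(tt >= o + config$epoch_window[1])[1]
        if (is.na(j0) || j0 + wlen - 1 > ncol(filt)) {
          warning(sprintf("trial %d: epoch at %0.2f s runs past trial end; dropped",
                          trials$meta$trial_id[i], o))
          next
        }
        seg <- filt[, j0:(j0 + wlen - 1), drop = FALSE]
        eps[[length(eps) + 1]] <- detrend_rows(seg)
      }
      if (!length(eps)) stopf("trial %d: no usable %s-hand epochs",
                              trials$meta$trial_id[i], hand)
      per_hand[[hand]] <- array(unlist(eps),
                                dim = c(nrow(filt), wlen, length(eps)))
    }
    out[[i]] <- per_hand
  }
  out
}

# Least-squares removal of a straight line from each row.
detrend_rows <- function(m) {
  n <- ncol(m)
  t <- seq_len(n) - (n + 1) / 2            # centered time regressor
  beta <- (m %*% t) / sum(t^2)
  m - rowMeans(m) - beta %*% t(t)
}

#' P300 features: averaged, downsampled twitch epochs
#'
#' The 10 monopolar channels are low-pass filtered at 10 Hz (3rd-order
#' Butterworth, zero-phase), segments 0-800 ms after each twitch onset are
#' extracted and linearly detrended, the segments of each hand are averaged
#' (all of them, or a random subsample of `n_averages`), and the average is
#' block-mean downsampled by the configured factor.  With the defaults this
#' yields 48 samples x 10 channels x 2 hands = 960 features per trial.
#' All trials are used (no artifact rejection for the P300 stream).
#'
#' @param trials a `bci_trials` object.
#' @param config a [p300_config()].
#' @param n_averages number of twitch segments to average per hand
#'   (`NULL` = all); when fewer than the available count, a random subsample
#'   is drawn.
#' @param seed RNG seed for the subsampling.
#' @param epochs optional precomputed result of the internal epoch extractor
#'   (used by [subsample_averages_analysis()] to avoid refiltering).
#' @return a `bci_features` object with group `"p300"`.
#' @export
extract_p300_features <- function(trials, config = p300_config(),
                                  n_averages = NULL, seed = NULL,
                                  epochs = NULL) {
  epochs <- epochs %||% extract_p300_epochs(trials, config)
  fs <- trials$sample_rate
  with_seed(seed, {
    rows <- lapply(seq_along(epochs), function(i) {
      unlist(lapply(c("left", "right"), function(hand) {
        ep <- epochs[[i]][[hand]]
        nav <- dim(ep)[3]
        sel <- seq_len(nav)
        if (!is.null(n_averages)) {
          if (n_averages > nav) {
            stopf("n_averages = %d exceeds the %d available epochs",
                  n_averages, nav)
          }
          if (n_averages < nav) sel <- sample(sel, n_averages)
        }
        avg <- apply(ep[, , sel, drop = FALSE], c(1, 2), mean)
        down <- t(apply(avg, 1, block_mean, block = config$downsample_factor))
        as.vector(t(down))                 # time fastest, channel slower
      }))
    })
    feat <- do.call(rbind, rows)
    nch <- length(trials$mono_labels)
    npts <- ncol(feat) / (2 * nch)
    colnames(feat) <- as.vector(outer(
      seq_len(npts), as.vector(outer(trials$mono_labels, c("L", "R"),
                                     paste, sep = "/")),
      function(k, ch) sprintf("%s#%d", ch, k)))
    new_features(feat, trials$meta$class_label, trials$meta$trial_id,
                 group = "p300")
  })
}

#' Accuracy as a function of the number of averaged twitch segments
#'
#' For each `n` in `n_range`, draws a random subsample of `n` twitch epochs
#' per hand and trial, builds P300 features from their average, and estimates
#' the three-class accuracy by repeated stratified cross-validation; the
#' subsampling is repeated `n_repeats` times.
#'
#' @param trials a `bci_trials` object.
#' @param config a [p300_config()].
#' @param n_range numbers of averages to evaluate.
#' @param n_repeats random subsampling repetitions per `n`.
#' @param seed RNG seed.
#' @param cv_repeats,cv_folds cross-validation layout.
#' @return data.frame with columns `n_averages`, `repetition`, `accuracy`
#'   (%), plus a `summary` attribute (mean and SD per `n`).
#' @export
subsample_averages_analysis <- function(trials, config = p300_config(),
                                        n_range = 1:7, n_repeats = 10,
                                        seed = 1, cv_repeats = 10,
                                        cv_folds = 10) {
  epochs <- extract_p300_epochs(trials, config)
  avail <- min(unlist(lapply(epochs, function(e) {
    c(dim(e$left)[3], dim(e$right)[3])
  })))
  if (max(n_range) > avail) {
    stopf("requested %d averages but only %d epochs available",
          max(n_range), avail)
  }
  rows <- list()
  for (n in n_range) {
    for (r in seq_len(n_repeats)) {
      fs <- extract_p300_features(trials, config, n_averages = n,
                                  seed = derive_seed(seed, n * 1000 + r),
                                  epochs = epochs)
      cv <- cross_validate(fs, n_repeats = cv_repeats, n_folds = cv_folds,
                           seed = derive_seed(seed, 500000 + r))
      rows[[length(rows) + 1]] <- data.frame(n_averages = n, repetition = r,
                                             accuracy = cv$accuracy)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ n_averages, out,
                          function(a) c(mean = mean(a), sd = stats::sd(a)))
  attr(out, "summary") <- data.frame(n_averages = agg$n_averages,
                                     mean = agg$accuracy[, "mean"],
                                     sd = agg$accuracy[, "sd"])
  out
}
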