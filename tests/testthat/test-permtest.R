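fs <- 600

# All distinct permutations of a small label vector.
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

# Two hand-made patterns with well-separated twitch onsets.
mk_patterns <- function() {
  list(structure(list(pattern_id = 1L, onsets_left = c(1, 3, 5),
                      onsets_right = c(2, 4, 6)), class = "twitch_pattern"),
       structure(list(pattern_id = 2L, onsets_left = c(1.5, 3.5, 5.5),
                      onsets_right = c(2.5, 4.5, 6.5)),
                 class = "twitch_pattern"))
}

test_that("the windowed statistic matches hand enumeration", {
  pats <- mk_patterns()
  # constant amplitude: statistic equals the constant for any assignment
  amp <- fake_amp_trials(list(rep(2, 9 * fs), rep(2, 9 * fs)))
  expect_equal(twitch_locked_statistic(amp, c(1L, 2L), pats, "left", 0),
               2)
  expect_equal(twitch_locked_statistic(amp, c(2L, 1L), pats, "left", -0.5),
               2)
  # dip to zero exactly in [onset + 0.05, onset + 0.10)
  a <- rep(1, 9 * fs)
  t <- -1 + (seq_along(a) - 1) / fs
  for (o in pats[[1]]$onsets_left) a[t >= o + 0.05 & t < o + 0.10] <- 0
  amp2 <- fake_amp_trials(list(a))
  expect_lt(twitch_locked_statistic(amp2, 1L, pats, "left", 0.05),
            twitch_locked_statistic(amp2, 1L, pats, "left", -0.5))
  # explicit enumeration oracle on a small instance (3 trials, 2 twitches)
  pats2 <- list(structure(list(pattern_id = 1L, onsets_left = c(1, 2),
                               onsets_right = c(1.5, 2.5)),
                          class = "twitch_pattern"),
                structure(list(pattern_id = 2L, onsets_left = c(1.25, 2.25),
                               onsets_right = c(1.75, 2.75)),
                          class = "twitch_pattern"))
  set.seed(40)
  amps <- lapply(1:3, function(i) stats::runif(4 * fs))
  amp3 <- fake_amp_trials(amps)
  assign3 <- c(1L, 2L, 1L)
  wlen <- round(0.05 * fs)
  oracle <- mean(unlist(lapply(1:3, function(i) {
    ons <- if (assign3[i] == 1) c(1, 2) else c(1.25, 2.25)
    vapply(ons, function(o) {
      j0 <- floor((o + 0.1 - (-1)) * fs) + 1   # first sample with t >= o+0.1
      mean(amps[[i]][j0:(j0 + wlen - 1)])
    }, numeric(1))
  })))
  expect_equal(twitch_locked_statistic(amp3, assign3, pats2, "left", 0.1),
               oracle, tolerance = 1e-12)
})

test_that("FPP matches its defining count, floor, and exchangeability", {
  pats <- mk_patterns()
  cfg <- perm_config(n_permutations = 200)
  # strong dips locked to each trial's true pattern: the observed statistic
  # sits at the bottom of the null distribution (shuffles reproducing the
  # true label vector tie with it, so the FPP equals the exact tie count)
  set.seed(41)
  assignment <- rep(c(1L, 2L), 4)
  amps <- lapply(seq_along(assignment), function(i) {
    a <- rep(1, 9 * fs)
    t <- -1 + (seq_along(a) - 1) / fs
    ons <- if (assignment[i] == 1) pats[[1]]$onsets_left
           else pats[[2]]$onsets_left
    for (o in ons) a[t >= o & t < o + 0.05] <- 0
    a
  })
  amp <- fake_amp_trials(amps)
  fpp <- permutation_test(amp, assignment, pats, "left", 0, cfg, seed = 2)
  # reproduce the same shuffles to obtain the defining count
  obs <- twitch_locked_statistic(amp, assignment, pats, "left", 0)
  set.seed(2)
  null <- vapply(1:200, function(j) {
    twitch_locked_statistic(amp, sample(assignment), pats, "left", 0)
  }, numeric(1))
  expect_equal(fpp, (1 + sum(null <= obs)) / 201)
  expect_gte(fpp, 1 / 201)
  expect_lt(fpp, 0.05)
  # all null values identical -> FPP = 1
  flat <- fake_amp_trials(lapply(1:4, function(i) rep(3, 9 * fs)))
  expect_equal(permutation_test(flat, c(1L, 2L, 1L, 2L), pats, "left", 0,
                                cfg, seed = 3), 1)
  # a single unique pattern is not exchangeable
  expect_error(permutation_test(flat, c(1L, 1L), pats, "left", 0, cfg),
               "distinct")
  # relabeling pattern ids leaves the FPP unchanged
  set.seed(42)
  amps_r <- lapply(1:6, function(i) stats::runif(9 * fs, 0.5, 1.5))
  amp_r <- fake_amp_trials(amps_r)
  asg <- c(1L, 2L, 1L, 2L, 1L, 2L)
  f1 <- permutation_test(amp_r, asg, pats, "left", 0.1, cfg, seed = 9)
  f2 <- permutation_test(amp_r, 3L - asg, rev(pats), "left", 0.1, cfg,
                         seed = 9)
  expect_equal(f1, f2)
})

test_that("Monte-Carlo FPP converges to the exhaustive enumeration", {
  pats <- mk_patterns()
  set.seed(43)
  n <- 5
  assignment <- c(1L, 1L, 1L, 2L, 2L)
  amps <- lapply(1:n, function(i) stats::runif(9 * fs, 0.5, 1.5))
  amp <- fake_amp_trials(amps)
  # exhaustive null: all distinct permutations of the label multiset
  perms <- unique(combinat_perms(assignment))
  stats_all <- vapply(perms, function(a) {
    twitch_locked_statistic(amp, a, pats, "left", 0.05)
  }, numeric(1))
  obs <- twitch_locked_statistic(amp, assignment, pats, "left", 0.05)
  exact <- mean(stats_all <= obs)
  N <- 4000
  mc <- permutation_test(amp, assignment, pats, "left", 0.05,
                         perm_config(n_permutations = N), seed = 5)
  se <- sqrt(exact * (1 - exact) / N)
  expect_lt(abs(mc - exact), 3 * se + 2 / N)
})

test_that("null FPPs are uniform on average", {
  pats <- mk_patterns()
  cfg <- perm_config(n_permutations = 99)
  set.seed(44)
  fpps <- vapply(1:60, function(r) {
    amps <- lapply(1:6, function(i) stats::runif(9 * fs, 0.5, 1.5))
    permutation_test(fake_amp_trials(amps), rep(1:2, 3), pats, "left",
                     0, cfg, seed = r)
  }, numeric(1))
  expect_equal(mean(fpps), 0.5, tolerance = 0.25)
})

test_that("the full-scale configuration can reach corrected significance", {
  cfg <- perm_config(n_permutations = 100000)
  n_cells <- length(cfg$lag_grid) * 2 * length(cfg$channels)
  expect_lt(1 / (cfg$n_permutations + 1), cfg$alpha / n_cells)
  expect_error(perm_config(n_permutations = 0), "n_permutations")
  expect_error(perm_config(lag_grid = c(0, 0.01)), "overlap")
})

test_that("scan results are reproducible and structurally sound", {
  tr <- small_trials(seed = 50, trials_per_class = 4)
  cfg <- perm_config(n_permutations = 300)
  s1 <- scan_blocking(tr, config = cfg, seed = 77)
  s2 <- scan_blocking(tr, config = cfg, seed = 77)
  expect_identical(s1$fpp, s2$fpp)
  expect_true(all(s1$fpp >= 1 / 301 & s1$fpp <= 1))
  expect_equal(dim(s1$fpp), c(20, 2, 2))
  # with N = 300 the corrected level is unreachable: nothing significant
  expect_false(any(s1$significant))
})
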