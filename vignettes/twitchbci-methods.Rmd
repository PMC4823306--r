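---
title: "Methods: SSSEPs, twitches, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSSEPs, twitches, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the design
was genuinely open.  It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The paradigm

Both index fingers are stimulated simultaneously with amplitude-modulated
vibrations: a 237 Hz sinusoidal carrier gated by a rectangular envelope at a
per-hand stimulation frequency from the 17–35 Hz grid (2 Hz steps).  The duty
cycle is realized as the integer number of full carrier cycles nearest to
half an envelope period (minimum one), so the carrier starts and stops at
phase zero within every burst.  A consequence worth knowing: the per-burst
phase restart makes the waveform periodic at the *envelope* frequency, so its
spectrum lives on envelope-frequency harmonics and peaks at the harmonic
nearest the carrier (245 Hz for a 35 Hz stimulus), not exactly at 237 Hz.

A *twitch* is a complete interruption of the stimulation for exactly one
envelope period, used as a rare countable target event.  Twitch onsets are
drawn by uniform rejection sampling on the envelope-period grid of the
corresponding hand (so a twitch deletes exactly one period), subject to a
pooled inter-stimulus interval of at least 250 ms within and across hands;
seven twitches per hand are placed in each 9.5–10 s focus period, and only
there — never in the reference period.  Three patterns are drawn per session
and assigned to trials uniformly at random.

Sessions follow two paradigms.  *Screening*: 8 runs × 10 trials, each trial a
3–3.5 s reference period followed by ten 2.3 s stimulation intervals
(analysis uses the last 2 s) with balanced random (frequency, finger)
assignments, never repeating the same pair in consecutive intervals; with the
defaults every pair occurs exactly 40 times (800 intervals).  The no-repeat
constraint is enforced within runs only (runs are separated by breaks).
*BCI*: 8 runs × 10 trials per class (focus left / focus right / idle), each
trial a 1–1.5 s reference period, then a cue and a 9.5–10 s focus period.
All times are seconds from session start; windows are half-open `[start,
end)`.

## The synthetic EEG generator

No public recordings accompany the paradigm, so the generator emulates the
signal structure the analysis assumes.  Each component is controlled by a
`subject_profile()` parameter:

* **SSSEP**: a sinusoid at each hand's stimulation frequency (the envelope
  frequency — the carrier itself is not assumed to appear in the EEG),
  scaled by a unimodal Gaussian tuning curve (peak 27 Hz, width 6 Hz,
  unit peak gain), projected through a fixed per-channel spatial map.
  The map is purely contralateral with an anterior–posterior gradient:
  a dipolar-like gradient is necessary for bipolar derivations to see the
  source at all, and exactly-zero ipsilateral weights make the ipsilateral
  null in the blocking analysis exact.  Spatial mixing by fixed gain maps
  replaces volume-conduction modeling, which is out of scope.
* **Attention**: the cued hand's SSSEP amplitude is multiplied by
  `attention_gain` (default 1.3) from cue onset to trial end.
* **Blocking**: after each twitch of a hand, that hand's SSSEP amplitude is
  multiplied by `10^(-blocking_depth_db/20)` inside a rectangular window
  (defaults: 2.5 dB, 50–200 ms after twitch onset).  A rectangular
  multiplicative window is the simplest testable choice; the time–frequency
  uncertainty of any narrowband analysis precludes recovering the true
  blocking shape anyway.
* **P300**: a raised-cosine positive bump (default 3 µV, peak 350 ms after
  the twitch, 200 ms wide) added after attended twitches only, through a
  centro-parietal map; a configurable non-target amplitude (default 0)
  exists to emulate the confound of P300s to non-target twitches.
* **Background**: independent per-channel `1/f^β` noise (default β = 1,
  4 µV RMS) plus an alpha-band sinusoid (default 1.5 µV, random 8–12 Hz
  frequency and phase per channel).  No inter-channel noise correlation is
  modeled; it is irrelevant to the tested statistics.
* **Artifacts**: optional blink-like EOG activity leaked into EEG channels
  with frontally weighted coefficients, and optional high-amplitude spikes
  on a configurable fraction of trials, for testing the rejection and EOG
  regression stages.

Amplitudes in microvolts are free parameters (the paradigm literature reports
none).  They were fixed once, before any acceptance measurement, from a
signal-to-noise calculation: with a 3 µV SSSEP source, a 0.85 effective
bipolar weight and 4 µV RMS 1/f noise, the in-band noise of a 4 Hz lock-in
bandwidth is ≈ 0.9 µV against a ≈ 2.6 µV signal, which makes a 2.5 dB
amplitude dip comfortably detectable from 60 trials × 7 twitches while
leaving single-window amplitude estimates clearly noisy.  These values are a
*stated world*, not a tuning dial: tests were written against them, not the
other way around.

**What a green test does not establish.**  The generator's SSSEP amplitude is
trial-wise deterministic given the class, its noise is stationary and
uncorrelated across channels, and its P300 has fixed latency and shape.
Real EEG has none of these properties, and empirical classification
accuracies (roughly 46–51% in three-class setups of this kind) are far below
what the clean synthetic world yields.  Recovery tests therefore validate
the *implementation* of the estimators, not their field performance.

## Lock-in amplitude (LAS)

The lock-in amplifier is realized as textbook quadrature demodulation:
multiply the signal by unit sine and cosine at the stimulation frequency,
low-pass each product with a 4th-order Butterworth filter applied
forward–backward (zero phase), and take `2·sqrt(I² + Q²)`, so a pure
sinusoid of amplitude A reads A at steady state.  "Bandwidth of X Hz around
the frequency" is interpreted as the total two-sided bandwidth: the low-pass
cutoff is X/2.  The *standard* setting (2 Hz bandwidth, 1 s moving average,
log10 output) measures steady-state SSSEP strength; the *fast* setting (4 Hz,
no moving average) trades noise for settling time to resolve twitch-locked
transients.  The moving average truncates its window at the series edges
rather than padding; features are extracted from the amplitude series, not
the raw signal, with half-open onset-inclusive windows.

Because no IIR design facility exists in the target environment, Butterworth
low/high-pass design (bilinear transform with pre-warping), zero-phase
filtering with odd-reflection padding, and a biquad notch are implemented in
the package and verified in the tests against frozen reference coefficients.

A quantitative property of this design worth recording: a one-period
interruption of a 35 Hz stimulus is a 28.6 ms gap, and after zero-phase
smoothing at a 2 Hz cutoff the amplitude dip it produces is approximately the
gap duration times the smoothing kernel's peak — about 11% of the steady
level (about 24% even at a 4 Hz cutoff).  The dips are reliably present and
localized (every twitch produces a local minimum within 100 ms), but no
reading of a "4 Hz bandwidth" lock-in yields dips of 30% or more; the
standard setting's deviation stays below 2%.

## Features and classification

*SSSEP features*: mean log LAS amplitude (standard setting) over 1–8.5 s
after cue onset, per bipolar channel × 2 frequencies (26 features with the
13-pair montage).  *Blocking features*: fast-setting LAS at the
finger-matched frequency, epochs 0–400 ms after each of that finger's
twitches, averaged across the seven twitches and over time (26 features); a
decimation option retains a block-mean time course instead, since the two
readings of the source description conflict (time-averaged wording vs a
feature-count bookkeeping that implies a retained time dimension) — the
time-averaged variant is the default.  *P300 features*: 10 monopolar
channels low-passed at 10 Hz (3rd-order, zero-phase), 0–800 ms epochs per
twitch, per-epoch least-squares linear detrend, average per hand, block-mean
downsampling ×10 → 960 features.  Epochs overlapping a following twitch are
retained; epochs running past the available data are dropped with a warning.
Trials exceeding 60 µV on any bipolar channel (90 µV monopolar) are rejected
for the SSSEP/blocking streams — the comparison is strict, documented for
bit-exact tests — while the P300 stream uses all trials.

Classification is one-vs-all LDA on a pooled within-group covariance shrunk
toward its diagonal, `(1-λ)S + λ·diag(S)`, with λ estimated analytically
(the variance-over-dispersion ratio of the off-diagonal covariance entries,
clipped to [0, 1]).  The estimator is computed in an algebraically identical
`O(n²p)` form and, for p > n, the shrunk system is solved exactly via the
Woodbury identity — both equalities are unit-tested against literal
implementations.  Scores are mapped to probabilities by a softmax (the
mapping is unspecified in the source description; softmax is monotone in the
scores and yields a comparable 0–100% scale), two classifiers are fused by
taking the class of the larger maximum probability if it reaches 50%
(exact ties go to the first, SSSEP, classifier), and performance is
estimated by 10×10 stratified cross-validation (stratification is a declared
choice).  The chance level is the exact binomial threshold: the smallest
accuracy a uniform guesser exceeds with probability below α.

## Screening analysis

Band power is the variance of the signal band-passed in a 2 Hz band centered
on each stimulation frequency (implemented by complex demodulation —
numerically robust where direct narrowband IIR band-passes are not), over
the last 2 s of each stimulation interval; the relative increase is taken
against the same trial's reference-period band power and averaged over the
40 repetitions, with a percentile bootstrap (1000 resamples) for confidence
intervals.  Whether band power should be spectral or LAS-based is not pinned
down by the source description; variance-of-band-passed-signal is the
declared choice.  One bias is inherent and documented rather than corrected:
with a 1/f background the reference power falls with frequency, which tilts
relative band power upward in frequency and can shift the measured tuning
argmax one 2 Hz grid step above the true tuning peak.

Frequency selection codifies a manual procedure: over ordered pairs
(left response at FC4-CP4, right response at FC3-CP3) separated by at least
4 Hz, maximize the smaller response; ties prefer more similar responses,
then the lower frequency sum.

## The blocking permutation test

Under the null hypothesis that twitches do not depress the SSSEP, the
assignment of twitch patterns to trials is exchangeable.  The statistic is
the mean fast-LAS amplitude (pre-log — the log is a feature convention, not
part of the test) in `[onset + τ, onset + τ + 50 ms)` over all trials and
twitches of one finger at one channel, with onsets read from each trial's
assigned pattern.  The null distribution is the observed statistic plus N
random shuffles of the per-trial pattern labels (preserving pattern counts);
the false-positive probability is the fraction of null values ≤ the observed
one, hence never below 1/(N+1).  The scan covers τ from −500 to +450 ms in
50 ms steps (20 non-overlapping windows), both fingers, and the two bipolar
channels over the hand areas, with Bonferroni correction over all 80 cells;
adjacent significant windows merge into reported intervals whose endpoints
are window boundaries.  Within a scan the same shuffles are reused across
cells (each cell is corrected as a separate test; sharing randomness does
not change any cell's marginal null).  The finger-matched convention is
used throughout: left-hand twitches are tested on the left stimulation
frequency.

At the paper-scale N = 100,000 the smallest attainable FPP (≈ 1e-5) lies
below the corrected threshold (1.25e-4), so significance is attainable; at
desk-scale N = 2,000 it is not — a null-calibration run at that N must and
does produce zero significant cells, and the uniformity of the FPP itself is
tested separately.

## Numerical choices and degenerate inputs

Reflection padding for zero-phase filtering defaults to three filter lengths
but is extended to several filter time constants for narrowband low-passes;
LAS output is floored at 1e-12 before the log.  Diagonal covariance entries
are floored at 1e-12 of their maximum before solving (guarding standardized
all-zero feature columns).  Zero-duration waveforms are empty; empty twitch
lists are identities; all-zero EOG calibration, single-pattern permutation
tests, sub-2-sample bootstraps, and classes smaller than the fold count are
errors by design.  Every stochastic function takes a seed and is
bit-reproducible given it; session-level seeds derive per-stage child seeds
deterministically, all below 2³¹.

## Known limitations

* The 13-pair bipolar and 10-channel monopolar sets are only partially fixed
  by the source description (FC3-CP3, FC4-CP4, Fz, Cz, Pz); the remainder of
  the shipped montage is a declared symmetric approximation, and both sets
  are configurable via plain-text montage files.
* EOG removal is stationary multichannel regression — the stationary special
  case of adaptive autoregressive correction schemes; fully adaptive
  estimation is out of scope.
* The generator emits exactly seven twitches per hand; trigger loss is not
  modeled.
* Online operation (causal filtering, classifier-update staging, feedback
  presentation) is out of scope; all analyses are offline.
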