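---
title: "Methods: simulating and analyzing closed-loop slow-oscillation TMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing closed-loop slow-oscillation TMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsleep)
```

## Overview

`clsleep` implements the computational pipeline of a closed-loop targeted
memory reactivation (CL-TMR) experiment: during NREM sleep, slow oscillations
(SOs, high-amplitude 0.5--2 Hz waves) are detected in real time on a frontal
EEG channel and brief auditory memory cues are delivered at a chosen SO phase
-- the depolarizing up-state (90°, peak) for one memory, the hyperpolarizing
down-state (270°, trough) for another, while a third memory is never cued.
Consolidation is read out the next morning as the overnight change in motor
sequence speed per condition.

Because the human recordings such a study produces are access-restricted, the
package pairs every analysis stage with a synthetic-data generator with known
ground truth. All properties asserted by the test suite are statements about
the pipeline's behavior on that generator, not about real sleep EEG.

## The synthetic night

`generate_sleep_eeg()` builds a multichannel recording (µV, default 1000 Hz;
the examples here use 500 Hz, the closed-loop device's rate) as a sum of
three components:

* **Slow oscillations** — one period of a raised-cosine biphasic wave:
  a negative half-wave (default trough −80 µV) followed by a positive one
  (default peak-to-peak 150 µV), at 1 Hz. The two half-wave durations are
  split inversely to the lobe amplitudes so each cycle integrates to zero.
  This matters: a cycle with net DC leaves a slow rebound after the
  detector's 0.3-Hz high-pass, which stretches the positive half-wave past
  the detector's 1-s duration bound and silently deletes compliant events.
* **Sleep spindles** — sinusoids at 13 Hz (sigma band) under a Tukey
  (tapered-cosine) envelope with 15% ramps, default 1 s, 30 µV peak. A fully
  Hann-shaped envelope was rejected: it crosses the spindle detector's RMS
  threshold at ~19% of peak amplitude, so the detected duration of a "1-s"
  burst can never exceed ~0.72 s; with tapered-cosine ramps detected and
  nominal durations agree to better than 0.2 s.
* **Background** — Gaussian noise with an aperiodic 1/f spectrum above a
  1-Hz spectral knee (flat below it) plus an equal-variance white
  sensor-noise floor, scaled to a broadband SD (default 10 µV, a package
  default chosen to be documented rather than inferred: published protocols
  for this class of experiment do not state background levels). The knee and the white floor
  are both standard features of measured neural spectra, and they keep the
  background from generating its own SO-scale half-waves. A *pure* 1/f
  background concentrates variance below 1 Hz; at a trough-amplitude SNR of
  5 its slow swells merge with the SO's positive half-wave often enough to
  cap detector recall at ~0.89 no matter how the detector is implemented.
  With the default background, recall at SNR 5 is 0.95--0.97. Real NREM
  sleep is *richer* in delta than this background, so recall on real data
  will be lower; the tests demonstrate algorithmic correctness, not field
  performance.

The generator plants events only in N2/N3 epochs of the hypnogram, returns
the exact event list as ground truth, and is bit-reproducible under a seed.
It does not simulate artifacts (EMG, eye movements, cardiac), REM
microstructure, or scalp topography: events are identical across channels.

`generate_hypnogram()` expands a stage plan into 30-s epochs;
`synthesize_cue_sounds()` builds the three 100-ms cues (543-Hz harmonic
complex with decreasing partial amplitudes, 100--1000 Hz band-passed noise,
1480-Hz complex with increasing partials; 10-ms linear ramps).

## The closed-loop simulator

`run_closed_loop()` replays the experimental night sample by sample at
500 Hz:

* **Scheduling.** 3-min stimulation intervals alternate between up- and
  down-targeting, separated by 1-min rests. The schedule only advances while
  the hypnogram is in N2/N3 (the experimenter's manual start/stop); the
  session hard-stops 3 h after the first cue.
* **Arming.** A causal 50-sample moving average filters the stream. A down
  candidate arms when the trace crosses the sex-specific trough threshold
  (−41 µV females, −39.5 µV males — the male threshold is conventionally quoted
  unsigned and is interpreted as negative by symmetry with the female one). An up
  candidate additionally requires the running peak-to-peak excursion since
  the trough to reach 77 µV (F) / 74 µV (M).
* **Firing.** After arming, the endpoint-corrected Hilbert transform (ecHT)
  phase of the raw stream is evaluated each sample; the cue fires when the
  estimate crosses the target phase (90° up / 270° down), or immediately if
  the estimate already sits within the quadrant past the target at arming —
  on transient (isolated) SOs the causal estimate can overshoot the trough
  phase before the amplitude criterion is met, and waiting for a strict
  crossing would silently skip most down deliveries.
* **Lockout.** After each cue the algorithm pauses until the next
  positive-to-negative zero crossing of the moving-average trace, so one SO
  is never cued twice while consecutive SOs remain eligible.
* **Online validation and balancing.** Each cue is scored against an
  order-500 linear-phase FIR (0.1--4.5 Hz, delay-compensated) version of the
  trace: valid if it lies within an oscillation whose trough reaches −40 µV
  and whose peak-to-peak reaches 75 µV. Whenever validated down cues
  outnumber validated up cues at a down interval's start, that interval is
  silenced, producing the characteristic 5-min no-stimulation span
  (1 min rest + 3 min silenced + 1 min rest).

### The ecHT phase estimator

`echt_phase()` computes the analytic signal of a 2-s causal buffer via the
one-sided FFT spectrum, applies the complex frequency response of a causal
Butterworth band-pass (0.1--4.5 Hz) in the frequency domain, and reads the
phase at the buffer's final sample. Two numerical choices matter:

* The device band is not centered on the SO frequency, so the causal filter
  has a non-zero phase response there (about −10° at 1 Hz for a 2nd-order
  design). The estimator compensates by subtracting the filter's phase at
  the dominant frequency of the (filtered) buffer, estimated as the
  power-weighted spectral centroid.
* The filter order is 3 by default: on trains of contiguous SO cycles this
  keeps the circular mean error of delivered-cue phases below 10° in both
  conditions, where order 2 leaves ~11° on the up side.

Phase convention throughout: 0° at the negative-to-positive zero crossing,
90° at the peak, 270° at the trough.

Accuracy caveat: for a *single isolated* SO cycle surrounded by flat
background, any causal estimator anticipates the phase (the window has not
yet seen the second half of the wave); delivered up-cue phases then center
near 60--70° rather than 90°. On SO trains — the physiological deep-NREM
regime the estimator targets — the error is <10°. The offline accuracy
criterion (a 180° window around the target) is insensitive to this bias.

## Offline validation

`classify_cue_accuracy()` re-filters the whole night with a zero-phase
0.1--4.5 Hz band-pass, takes the non-causal analytic phase, and classifies
each cue: *true SO* if the oscillation nearest the cue (negative half-wave
plus adjacent positive half-waves, using a ±5 µV hysteresis around zero so
noise ripples do not fragment half-waves) meets the sex-specific trough and
PTP criteria; *accurate* if additionally the phase falls in `[0°, 180°]`
(up) or `[180°, 360°)` (down). The boundary assignment — both 180° edges to
the half-plane containing the target — is a documented package convention.

`circular_summary()` reports the circular mean, resultant length and a
large-sample (Fisher) 95% CI; antipodal samples (resultant ≈ 0) are flagged
as having no defined mean. `assign_sham_cues()` gives every not-stimulated
SO one up-sham and one down-sham time by drawing a phase (with replacement,
seeded) from the corresponding true-positive phase list and interpolating
the SO's own analytic phase to a time sample.

## Offline event detection

`detect_slow_oscillations()`: zero-phase 0.3--2 Hz filter with a 0.2-Hz
raised-cosine transition (−6 dB at 0.2/2.1 Hz), realized in the frequency
domain — an equivalent FIR at this transition width would need thousands of
taps on hours of signal. Negative peaks in [−200, −40] µV and positive peaks
in [10, 150] µV are paired (each negative half-wave with the immediately
following positive one), then five logical thresholds apply: negative
half-wave duration 0.3--1.5 s, positive 0.1--1 s, negative amplitude
magnitude 40--300 µV, positive 10--200 µV, PTP 75--500 µV. The source
protocol prints two inconsistent negative-amplitude ranges (−40..−200 in the
peak-picking clause, 40--300 magnitude in the threshold list); both are kept
in their respective stages, and `audit_so_events()` re-checks every returned
event against the logical thresholds.

`detect_spindles()`: three criteria must hold simultaneously — relative
sigma (8--18 Hz) power above 0.2 (STFT, 2-s Hann windows, 200-ms steps),
moving RMS of the sigma-filtered signal (300-ms window, 100-ms step) above
its NREM mean + 1.5 SD (baseline statistics over the whole recording's NREM
samples), and a 300-ms moving Pearson correlation between the broadband
(1--30 Hz) and sigma signals above 0.65. Candidate runs are refined to the
span where the instantaneous sigma envelope exceeds the equivalent amplitude
threshold (RMS × √2), which removes the ±150-ms smearing of the RMS window;
events outside 0.3--3 s are discarded, and `merge_cross_channel()` collapses
events whose onsets lie within 500 ms across channels (transitive closure —
they are taken to reflect one physiological spindle).

`event_metrics_by_interval()` computes per-condition densities (events/min),
mean amplitude and mean frequency over the up / down / not-stimulated
interval sets; condition effects across subjects reuse `rm_anova()`.

## ERPs and time-frequency power

`make_epochs()` band-passes 0.1--30 Hz (zero phase), downsamples to 100 Hz
(anti-alias cutoff 40 Hz), and segments around lock times: −2.5..2 s for cue
locking, −2..2 s for trough locking. Manual artifact cleaning is not
reproducible, so rejection is a caller-supplied boolean mask; epochs
touching masked samples or the recording edge are dropped and counted.

`compute_tfr()` uses the adaptive Hanning-taper approach: at each frequency
f in 5--30 Hz, a window of five cycles (5/f s) slides in 20-ms steps; power
is scaled so a sinusoid of amplitude A yields A²/2. Power is computed per
epoch and then averaged (induced + evoked). `baseline_normalize()` converts
to relative change (P−B)/B with B the mean over −2.5..−2 s (cue lock) or
the whole epoch (trough lock); the trough-lock baseline is taken on the
epoch-averaged power rather than per epoch (both are defensible; the
epoch-average reading is the package's choice).

## Cluster-based permutation statistics

`paired_cluster_test()` takes subject × channel × [frequency ×] time arrays
for two conditions. Pointwise paired t-values exceeding the two-sided
α = 0.01 critical value form candidate samples; connected sets (adjacent
time bins, adjacent frequency bins, and montage neighbor channels from
`build_adjacency()`) become clusters scored by the sum of t-values. The null
distribution is generated by flipping the sign of each subject's condition
difference — the standard paired-design realization of "randomly assigned
conditions within each individual"; epoch-level label exchange is the
alternative reading and is not implemented. With n subjects and 2^n ≤
permutations the enumeration is exhaustive; otherwise 500 random flips with
Monte-Carlo p = (r+1)/(n+1). A single max-|mass| distribution across both
signs controls the family-wise error over positive and negative clusters
(with per-sign distributions the realized type-I rate doubles to ~0.10;
measured calibration with the max-|mass| correction is ~0.05). Cohen's d per
cluster is mean/SD of the subject-level mean differences across cluster
members. Testing three condition contrasts at the study's Bonferroni level
means comparing cluster p-values to 0.05/3 ≈ 0.0167.

## Behavioral analysis

`build_session_schedule()` lays out the bimanual serial reaction time task:
63 pre-night training blocks (21 per 5-element sequence: A = 4 7 2 8 3,
B = 1 6 3 5 2, C = 7 3 8 4 6), a 9-block pre-night test, 63 post-night
blocks, and 4-block pseudo-random sessions (12 patterns × 5 keys) before and
after; sequential blocks are 20 presses, random blocks 60. Sequence order,
sequence→condition and condition→sound assignments are seeded bijections.

`score_trials()` flags outliers among correct trials with Tukey fences
(Q1 − 1.5·IQR, Q3 + 1.5·IQR, per subject × session × condition — the fence
multiplier defaults to the conventional 1.5), then takes block medians of surviving trials. `offline_change()` is
(pre − post)/pre × 100 over the 3 pre-test and first 3 post-night block
medians — positive = faster after sleep (the standard sign convention for
offline gains). Pre-test medians are averaged as
medians-of-blocks, not pooled trials. TMR indices are the per-subject
differences against the not-reactivated condition.

`rm_anova()` delegates the F statistic to `stats::aov` with an
`Error(subject/condition)` stratum; the Greenhouse-Geisser epsilon comes
from the double-centered sample covariance matrix and corrects the degrees
of freedom whenever ε < 1; partial η² = SS_cond/(SS_cond + SS_err) (the convention
G*power-style calculators use when deriving an effect size from a
repeated-measures F and its degrees of freedom). Posthocs are all pairwise paired t-tests with
Benjamini-Hochberg FDR and paired Cohen's d.

### The behavioral generator and the planted effect size

`generate_behavior()` draws per-subject, per-condition overnight gains
around planted means (defaults up +8%, down +2%, not +7%), splits
between-subject variability into a shared component and a
condition-specific component (defaults 4.8% each, implying a
repeated-measures correlation of 0.5), and synthesizes per-press response
times along an exponential learning curve (420 → 280 ms) with 40-ms trial
noise and a 5% error rate. The first three post-night blocks sit on the
consolidation plateau; practice-driven improvement resumes afterwards, so
the offline-change estimator is unbiased by construction.

The default gain SDs realize a condition effect of η² ≈ 0.13 in the
G*power sense (f = √(η²/(1−η²)) with ρ = 0.5, λ = n·k·f²/(1−ρ)). Under the alternative
"realized partial η² = 0.13" reading, the noncentrality at n = 28 gives only
~70% power and no generator could meet a 90% power target at that sample
size; the G*power reading is therefore the one implemented. Measured power
at n = 28 is ~0.93--0.95.

## Problem sizes used by tests and the acceptance script

Simulated nights are 10--60 min at 500 Hz (the device rate), not full 7.5-h
nights; detector and closed-loop properties are asserted on 1-h recordings.
Behavioral Monte-Carlo loops generate only the blocks the estimator reads
(3 pre-test + first 3 post-night blocks per condition) with 150--300
replicates; cluster type-I calibration uses 200 null datasets of 20 subjects
× 2 channels × 25 samples at 500 permutations each. These sizes make the
Monte-Carlo error comfortably smaller than the asserted margins.

## Known limitations

* Events are planted identically on all channels; no forward model, so
  channel-level adjacency merging is exercised with perfectly coherent
  events only.
* The background has less low-frequency power than real NREM EEG (see
  above); detector recall figures do not transfer to real recordings.
* The ecHT anticipates the phase of isolated SO transients; phase-targeting
  accuracy statements hold for SO trains.
* Online validation near recording edges is indeterminate and counted
  invalid rather than modelled.
* No audio playback, hardware latency, or experimenter-in-the-loop behavior
  beyond hypnogram gating.
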