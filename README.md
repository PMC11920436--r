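# clsleep

Simulation and analysis toolkit for **closed-loop targeted memory
reactivation (CL-TMR)** during sleep.

During NREM sleep, slow oscillations (SOs) — high-amplitude ~0.5–2 Hz waves
with a hyperpolarized trough (down-state) and a depolarized peak (up-state)
— orchestrate memory consolidation. In a CL-TMR experiment, sounds paired
with previously learned material are played in real time at a chosen SO
phase: one memory cue at the up-state (90°), another at the down-state
(270°), and a third memory is never cued. The behavioral read-out is the
overnight ("offline") change in motor-sequence speed per condition, and the
electrophysiological read-outs are cue- and trough-locked evoked responses
and sigma-band (12–16 Hz, spindle) power.

`clsleep` is aimed at sleep/EEG researchers who want a tested, fully
reproducible implementation of that pipeline. Because the human recordings
such studies produce are access-restricted, every stage is paired with a
synthetic-data generator with known ground truth:

* **`generate_sleep_eeg()`** — NREM EEG with planted SOs (raised-cosine
  biphasic cycles), spindles (tapered sigma-band bursts) and an aperiodic
  1/f background; hypnograms, cue sounds and SRTT behavior generators
  alongside.
* **`run_closed_loop()`** — the real-time algorithm: threshold arming on a
  50-sample moving average (trough −41 µV / PTP 77 µV in females, −39.5 /
  74 µV in males), phase-targeted firing via the endpoint-corrected Hilbert
  transform (ecHT, causal 0.1–4.5 Hz), a per-SO lockout, 3-min alternating
  up/down intervals with 1-min rests, online validation (−40 µV trough,
  75 µV PTP, order-500 FIR) and dynamic silencing of down intervals to
  balance validated cue counts.
* **`classify_cue_accuracy()` / `circular_summary()` /
  `assign_sham_cues()`** — offline scoring: a cue is accurate if it fell in
  the 180° window around its target phase during a true SO.
* **`detect_slow_oscillations()` / `detect_spindles()`** — offline
  detectors with the standard logical thresholds (SO: half-wave durations
  0.3–1.5 s / 0.1–1 s, amplitudes 40–300 / 10–200 µV, PTP 75–500 µV;
  spindles: relative sigma power > 0.2, RMS > mean + 1.5 SD, broadband/sigma
  moving correlation > 0.65, duration 0.3–3 s, 500-ms cross-channel merge).
* **`make_epochs()` / `compute_tfr()` / `paired_cluster_test()`** —
  cue/trough-locked ERPs at 100 Hz, adaptive Hanning-taper time-frequency
  power (5 cycles per frequency, 20-ms steps, 5–30 Hz), and cluster-based
  permutation tests over channel×time(×frequency) with within-subject sign
  flips (cluster-forming α = 0.01, 500 permutations, max-|mass| correction).
* **`score_trials()` / `offline_change()` / `rm_anova()`** — SRTT scoring
  with Tukey outlier fences, offline change `(pre − post)/pre × 100`, TMR
  indices, and one-way repeated-measures ANOVA with Greenhouse–Geisser
  correction, partial η², and FDR-corrected paired posthocs.

## Worked example

Simulate half an hour of N3 sleep with planted SOs, run the closed-loop
stimulator, and score it offline:

```r
library(clsleep)

gen <- generate_sleep_eeg(duration_s = 1800, fs = 500, channels = "Fpz",
                          so = list(rate_per_min = 6),
                          spindle = list(rate_per_min = 0),
                          noise = list(sd_uV = 5), seed = 7)
log <- run_closed_loop(gen$recording,
                       stimulation_config("F", echt_filter_order = 3),
                       seed = 7)
log
#> <cue_log> 128 cues (69 up / 59 down), 15 interval spans, status: ok
#>   online-validated: up 69, down 59

acc <- classify_cue_accuracy(log, gen$recording, sex = "F")
acc$accuracy_pct
#> [1] 100
circular_summary(acc$records$phase_deg[acc$records$condition == "down"])[1:2]
#> $mean_deg
#> [1] 249.627
#> $resultant_length
#> [1] 0.9877956

nrow(detect_slow_oscillations(gen$recording, "Fpz"))
#> [1] 159   # all 159 planted SOs recovered
```

Every cue was delivered inside a true SO; down cues cluster just before the
trough (the causal estimator anticipates transient waves slightly), with a
resultant length of 0.99 (tight phase locking). The stimulator balanced the
two conditions (69 vs 59 validated cues).

The behavioral arm — 28 simulated participants with planted overnight gains
(up +8%, down +2%, not-reactivated +7%):

```r
sch <- build_session_schedule(seed = 11)
sim <- generate_behavior(sch, behavior_sim_params(n_subjects = 28, seed = 11),
                         sessions = c("pre_test", "post_training"))
changes <- consolidation_table(score_trials(sim$trials)$blocks)
rm_anova(changes)
#> One-way rmANOVA: F(2,54) = 22.129, p = 9.564e-08 (GG-corrected 1.97e-07, epsilon 0.945), partial eta^2 = 0.450
#> Posthoc paired t tests (FDR-corrected):
#>     contrast      t df         p cohens_d     p_fdr
#>   up vs down  6.214 27 1.206e-06   1.1743 3.619e-06
#>    up vs not  1.970 27 5.923e-02   0.3722 5.923e-02
#>  down vs not -4.356 27 1.716e-04  -0.8232 2.574e-04
```

This realization reproduces the qualitative fingerprint of up-state TMR:
up ≈ not > down — down-reactivated sequences consolidate less than both the
up-reactivated and the uncued control sequences.

File interchange helpers (`write_edf()`/`read_edf()`, hypnogram/cue/event
TSV, behavior CSV via base R, `write_wav()`) round-trip the standard
formats.

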