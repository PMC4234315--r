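---
title: "Methods: irrelevant-probe ERPs as a cognitive-workload measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: irrelevant-probe ERPs as a cognitive-workload measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

When a person performs a demanding sensorimotor task, fewer neural
resources remain to process task-irrelevant stimuli. The irrelevant-probe
paradigm exploits this: rare novel sounds are played at random moments
while the participant controls a virtual prosthetic arm, and the
event-related potentials (ERPs) evoked by those sounds index the *spare*
attentional capacity. The harder the primary task, the smaller the probe
ERPs. Four components are scored as window means at midline sites:

| component | window (ms) | polarity | primary site(s) |
|-----------|-------------|----------|-----------------|
| N100      | 105–120     | negative | Cz              |
| P200      | 190–205     | positive | Fz, Cz, Pz      |
| P300      | 295–330     | positive | Pz              |
| LPP       | 570–590     | positive | Pz              |

The design crosses two myoelectric control schemes (direct control, DC,
and pattern-recognition control, PRC) with three workload conditions
(passive viewing, a 1-DOF "easy" task, a 3-DOF "hard" task). The
statistical endpoints are 3 × 2 repeated-measures ANOVAs per component ×
electrode, Tukey-adjusted pairwise workload contrasts, paired DC-vs-PRC
t-tests on components with workload effects, behavioral summaries
(percent completed; completion time over successful trials), a 7-item
Likert difficulty score (items 1, 3, 7 reverse scored), and simple
correlations among the three measure families.

Because no raw recordings are distributed with the study this package
emulates, the package pairs the analysis pipeline with a seeded
synthetic-session generator whose ground truth is known exactly. Every
inferential claim a green test makes is therefore about *recovery of
injected structure*, never about reproducing the human F or t values.

## The synthetic world

### Session structure

Each of `n_participants` (default 18) completes both schemes; scheme
order alternates across participants, and within each scheme-order
stratum half the participants see the view condition first and half last
(easy always precedes hard). With an even cohort exactly 50% are
view-first — counterbalancing is a deterministic design, not a random
draw. Trials are: 2 s inter-trial interval, 4 s planning window, then
movement until success or the 24 s timeout. Easy has 24 trials per DOF ×
3 DOFs, hard 32 trials; the view condition replays the 3-DOF task, so it
receives 32 trials and hard-like durations (its trial count is not
stated in the source protocol; equality with hard is assumed).

### Behavior

Completion times are log-normal, truncated at the timeout by rejection,
with the body mean/SD set to the published cell summaries (DC easy
2.4 ± 0.81 s, PRC easy 2.8 ± 0.81 s, DC hard 15.1 ± 2.18 s, PRC hard
12.5 ± 2.19 s; under these parameters the truncated mass is below 0.1%,
so sample means match the targets). The published SDs are
between-participant; reusing them as trial-level scale is a simplifying
choice, harmless here because no acceptance quantity depends on the
within-cell time variance. Success is Bernoulli per trial (0.97 easy,
0.78/0.80 hard); percent correct was published only graphically, so
these are realistic values with no scheme difference, matching the
reported null. Failures are logged at the timeout and excluded from
timing summaries.

### Probe placement

The protocol says probes arrived "at random intervals (0–3 per trial)".
Two count models are implemented. The default, `"interval"`, advances
through each trial's active window with inter-stimulus intervals uniform
on 3–6 s, capped at 3 probes: long (hard/view) trials then carry ~3
probes and easy trials 0–1. The alternative, `"uniform"`, draws the count
uniformly from {0..3} irrespective of trial length. The interval model is
the default because it is the only reading under which the study's own
inclusion rule is survivable: with uniform counts a 32-trial condition
expects ~39 clean epochs (SD ≈ 6) after blink rejection, and the
probability that a clean participant clears "≥ 30 clean epochs in every
cell" in all six cells is only ~0.84 — the published outcome (18 of 20
retained, both exclusions for noise) would be a fluke. With interval
placement hard/view cells expect ~78 clean epochs and easy ~47, and the
inclusion rule behaves as published. Whether probes could fall inside the
4 s planning window is unstated; `probes_in_planning` exposes the choice
(default `FALSE`).

### EEG composition

Channels (default Fz, Cz, Pz, VEOG, HEOG; 1000 Hz, A1 reference) carry
the sum of:

* **Pink noise**, spectral amplitude ∝ f^(−1/2) above 0.5 Hz (FFT
  synthesis, Gaussian spectral coefficients), RMS 4.5 µV per channel,
  independent across channels.
* **Alpha**, a spatially coherent 10 Hz sinusoid with random phase,
  2 µV RMS at its posterior maximum (Pz weight 1, Cz 0.6, Fz 0.3).
  Because 10 Hz lies inside the 1–15 Hz analysis band, alpha survives
  filtering and is the main reason ≥ 30-trial averaging is genuinely
  needed.
* **Component templates** at each probe. A component is a zero-mean
  biphasic raised cosine, `h(t) = A·[2·hann(t, hw) − hann(t, 2·hw)]` on
  support ±2·hw around the peak: a central lobe of the nominal polarity
  with gentle flanks that cancel the DC content exactly. Unipolar bumps
  were rejected deliberately: the 1 Hz high-pass of the mandated band
  turns their DC content into a ±1 s undershoot that leaks a spurious
  ~0.7 µV workload effect into the N100 window, contradicting the
  required N100 null. Peaks sit at the window centers (112, 198, 312,
  580 ms); half-widths (35, 45, 70, 80 ms) are bounded above by the
  window spacing (a P200 support reaching the N100 window would
  contaminate it) and below by band-limitation. Base peak amplitudes are
  5, 5, 8, 4 µV with scalp topographies maximal at the canonical site of
  each component.
* **Workload structure**: multiplicative attenuation per condition —
  1.0 / 0.6 / 0.25 for view / easy / hard on P200, P300, LPP; N100 is
  constant across conditions (its null is part of the stated world). The
  scheme effect is additive: +0.8 µV on LPP for PRC in the hard condition
  only (direction from the published finding; magnitude a simulation
  parameter). Each participant carries a per-component amplitude trait,
  Normal(1, 0.15), shared across conditions and schemes — so paired
  scheme contrasts cancel it, as participant traits do in a real
  within-subject design.
* **Eyeblinks**, 400 ms, 150 µV raised-cosine transients on VEOG with
  scalp spread 0.4 / 0.15 / 0.05 to Fz / Cz / Pz, Poisson at 8 per
  minute. "Noisy" participants (used to exercise the inclusion rule) get
  10× that rate.

Noise level rationale: the design target is roughly −10 dB single-trial
SNR *for the attenuated components* — the hard-condition LPP peaks near
1 µV against ~3.2 µV of in-band noise. Anchoring −10 dB to the
unattenuated amplitudes instead would make the generator's own stated
power properties (workload effects detected in ≥ 90% of cohorts; the LPP
scheme contrast resolvable at n = 18) unattainable, so the anchor was
fixed to the attenuated case a priori and not revisited.

## The analysis pipeline

* **Filtering**: 4th-order Butterworth, 1–15 Hz, applied
  forward-backward (zero phase, so component latencies are not shifted).
  The filter is designed by bilinear transform and realized as
  second-order sections: at this band on 1000 Hz data the single
  direct-form recursion amplifies rounding noise by ~10^13 at the lower
  band edge and is numerically unusable, while the SOS cascade with
  step-matched initial conditions is exact to ~1e-13 against an
  independent reference implementation.
* **Epochs**: −100…1000 ms around each probe, both endpoints included at
  the native rate (1101 samples at 1000 Hz). Events whose window crosses
  a recording edge are dropped and logged, never padded.
* **Baseline**: per epoch and channel, the mean over [−100, 0) ms is
  subtracted (the onset sample is excluded; stated once here, tested
  everywhere).
* **Artifact rejection**: the source analysis inspected epochs visually;
  the reproducible proxy flags an epoch when any EOG channel exceeds
  100 µV peak-to-peak or any EEG channel exceeds ±75 µV, with reasons
  recorded. Rejection is idempotent and clean + flagged + dropped always
  equals the event count.
* **Inclusion**: a participant enters the cohort statistics iff every
  scheme × condition cell retains ≥ 30 clean epochs.
* **Scoring**: participant × scheme × condition averages (arithmetic
  mean over clean epochs), window means with inclusive endpoints at
  Fz/Cz/Pz. Grand averages weight participants equally. Two window
  modes: the fixed printed windows (default) or `recenter = TRUE`, which
  re-centers each window (width preserved) on the grand-average peak
  found in the component's standard search range (N100 80–160 ms
  negative at Cz; P200 150–250 at Cz; P300 250–450 at Pz; LPP 450–800 at
  Pz, positive). The source text supports both readings; the package
  makes them explicit modes and asserts neither as "the" published one.
* **Statistics**: the two-way within-subject ANOVA is computed from the
  classical sums-of-squares decomposition (each effect tested against
  its own subject-interaction), reported with uncorrected integer df —
  the convention of the source report — plus Greenhouse–Geisser
  corrected p as a supplementary column (epsilon from the covariance of
  orthonormalized effect contrasts, clamped to [1/df, 1]). Post-hoc
  workload contrasts are paired t statistics referred to the studentized
  range distribution (q = |t|·√2, 3 means, n−1 df) — a within-subject
  Tukey HSD; the exact published procedure is unspecified, so this
  choice is documented rather than asserted. Paired t and Pearson r are
  classical; degenerate inputs yield defined results (all-zero
  differences: t = 0, p = 1; zero variance: an explicit undefined flag).
  DC-vs-PRC contrasts are computed only for components whose omnibus
  workload effect is significant, mirroring the source's
  multiplicity-limiting rule; correlations are reported as the full
  matrix because the exact published pairings are unspecified.

## Ground truth and what "recovery" means

The chain from injected template to measured window mean is linear, so
the deterministic part of every measurement is computable exactly: the
package renders each unit template through the filter + baseline chain
once and stores its window gains (`template_window_gain()`), including
cross-window leakage. Ground truth carries both the raw injected peak
amplitude and this *expected* window amplitude. Recovery bias is
asserted against the expected value: the 15 Hz low-pass necessarily
transmits the narrow N100/P200 templates at gain < 1 (their half-widths
are pinned by the 70 ms spacing of the printed windows), a deterministic
attenuation identical for every epoch, not an estimator bias. Against
the raw injected peak the same measurements would show −0.3 to −1.5 µV
systematic offsets — real, reported, and irrelevant to the unbiasedness
of the averaging/windowing estimator.

## Scaling of the Monte-Carlo suites

Criteria that need hundreds to thousands of cohorts (type-I calibration,
qualitative-pattern power) run at the *amplitude level* of the generative
hierarchy: measured cell amplitude = expected amplitude (participant
trait × attenuation through the linear chain) + Gaussian measurement
noise whose SD is estimated at run time by pushing pure-noise cells
through the full EEG chain (40 epochs averaged per cell, 120 cells;
SD ≈ 0.55–0.63 µV per window). Rendering 10^3 full cohorts of continuous
EEG would take days; the amplitude-level shortcut is distributionally
faithful for the statistics tested precisely because the chain is linear
and the background additive — which the EEG-level recovery and
calibration tests themselves verify at smaller n.

One acceptance reading is worth stating plainly: the qualitative-pattern
criterion requires the cohort to *show higher* LPP for PRC than DC in
the hard condition. Demanding *significance* of that contrast jointly
with an N100 null would cap the achievable rate at ~0.90 in any world
(0.95 N100 specificity × ≤0.95 contrast power at the stated 0.8 µV
delta), so the joint check uses the direction, and the significance rate
is reported alongside (~0.90 of cohorts on its own).

## Known limitations

* The generator's noise is stationary and spatially simple (independent
  pink noise + one coherent alpha source); real EEG has nonstationary
  rhythms, line noise, and richer spatial covariance. A green recovery
  test establishes correctness of the pipeline's algebra and its
  statistical calibration under the stated model, not robustness to
  every real-world artifact.
* Blink morphology is a single stereotyped transient; ocular correction
  (ICA/regression) is deliberately out of scope — contaminated epochs
  are discarded, as in the emulated analysis.
* The published F/t/r magnitudes depend on the unreleased human
  recordings and are not reproduction targets; only degrees of freedom,
  design structure, directions of effects, and calibration properties
  are.
* EDF output quantizes to 16 bits over the per-channel data range
  (~0.005 µV steps for typical amplitudes); exactness tests use the
  native float container.
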