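---
title: "Methods: peri-stimulation single-unit modulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-stimulation single-unit modulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbsmod)
```

## The experimental structure being analyzed

`tbsmod` analyzes single-neuron firing around brief trains of intracranial
theta-burst stimulation (TBS) delivered during a visual recognition-memory
task. One trial is a 3 s image presentation followed by an ~6 s
interstimulus interval; on a randomly interleaved half of the trials a 1 s
TBS train (50 Hz pulses nested in eight ~8 Hz bursts, 50% duty cycle)
starts the moment the image leaves the screen. Four 1 s, half-open analysis
epochs are anchored to that moment (t0 = image offset = stimulation onset
on stim trials):

* **PRE** `[image_onset - 1, image_onset)` — the final second of the
  preceding fixation period, used as the within-trial baseline;
* **IMG** `[image_onset, image_onset + 1)` — the image-onset response;
* **DUR** `[t0, t0 + 1)` — during stimulation (or the matching window on
  image-only trials);
* **POST** `[t0 + 1, t0 + 2)` — immediately after stimulation.

Every epoch is exactly 1 s, so spike counts are firing rates in Hz and the
contrasts below are unbiased by window length. Intervals are half-open and
left-closed; a spike landing exactly on a boundary belongs to the window it
opens. This convention is a package choice (nothing in the data forces
it); it makes boundary assignment deterministic and testable.

## The modulation test

For each unit, condition (stim / no-stim) and contrast (PRE vs DUR, PRE vs
POST, and PRE vs IMG for image responsiveness), the package computes the
Wilcoxon signed-rank statistic W across trials: zero paired differences are
dropped, tied absolute differences get midranks, and W is the rank mass of
the positive differences. Significance comes from a permutation null in
which each trial's pair of epoch labels is independently swapped with
probability 1/2 and W recomputed (1000 permutations by default).

Two facts make this implementation exact and fast. Swapping the two epoch
labels of a trial negates the paired difference and leaves its absolute
value — hence its rank — unchanged, so the label-swap null *is* the
sign-flip null over the fixed rank masses. The null is therefore sampled by
flipping signs of the observed rank vector, never by re-ranking.

The decision rule is two-tailed: a unit is significant when the observed W
falls outside the central 95% interval of its permutation null (the
interval rule mirrors a shaded null band; `decision = "pvalue"` instead
thresholds the center-symmetric permutation p, which always carries the +1
correction so it cannot reach zero). A unit is **modulated** if either the
DUR or the POST contrast is significant; the epoch class records which
(during-only, post-only, both). Direction (enhanced / suppressed) follows
the sign of the mean rate difference. No multiple-testing correction is
applied across units or contrasts; the permutation null is the
false-positive control, and the type-I calibration of the whole pipeline
is verified by simulation in the test suite (flagged fraction of
exchangeable-null units within [0.03, 0.07] at alpha 0.05).

Open choices resolved here, exposed as arguments:

* The epoch-label shuffle is a *pairwise* swap within the tested contrast,
  preserving trial pairing; a `shuffle = "threeway"` option permutes all
  three labels (PRE/DUR/POST) within each trial for comparison.
* The baseline rate used by the inclusion filter pools stim and no-stim
  trials ("trial-averaged" without restriction maximizes the trials behind
  the estimate); `baseline_rate(condition =)` restricts it if desired.
* The per-unit effect size is the mean test-epoch rate minus the mean PRE
  rate in units of the across-trial SD of PRE rates; it is undefined (NA,
  excluded from summaries) when the baseline SD is zero. This PRE-
  normalized reading is one of several possible z-scorings; it is the one
  the package commits to.

Units with a pooled baseline rate below 0.1 Hz are excluded before testing
(sparse firing gives the contrast no power); the threshold is a parameter
and the sensitivity of the conclusions to it is an explicit control
analysis (below).

## Cell-type clustering

Two morphology metrics are measured on each unit's averaged waveform: the
valley-to-peak width (VP; global valley to the subsequent maximum) and the
peak half-width (PHW; width of the post-valley peak at half its height
above the zero line, with sub-sample linear interpolation of the
crossings). The half-height reference is the zero line — the reference
level is otherwise undefined for these recordings. K-means with k = 2 and
50 seeded restarts runs on raw millisecond coordinates (both metrics share
units and ranges; standardization is a switch). The cluster with the
shorter mean VP is labeled I (fast-spiking, putative inhibitory), the
other E (regular-spiking, putative excitatory). Published centroid
listings for this kind of data are not fully consistent about which
centroid carries which label; this package follows the physiological rule
(fast-spiking = shorter waveform) deterministically, and the synthetic
cohort is generated accordingly (I units at VP 0.32 / PHW 0.31 ms, E units
at 0.50 / 0.51 ms, 85%/15% E/I).

## Population and multiunit analyses

The pseudo-population matrix stacks all units (pooled across sessions) as
rows of trial-averaged firing rates in 100 ms bins spanning -3 to +2 s
around t0, one block per condition concatenated along time; each row is
z-scored across the concatenated axis so the two conditions share a scale,
and zero-variance units are dropped with a report. PCA treats time bins as
observations, so the leading components are population-coactivity time
courses; the 100 ms bin reuses the smoothing bin width (the PCA bin width
is otherwise unconstrained). Trials are averaged per condition without
reweighting when condition counts differ.

Autocorrelograms histogram all within-trial pairwise differences between
distinct spikes (5 ms bins, ±250 ms), summed over trials and normalized to
a maximum of 1; the zero-lag bin is excluded from the peak search, and the
analysis is intended for units firing at ≥1 Hz. Multiunit activity is
counted as negative threshold crossings (-3.5 × RMS, 1 ms dead time) of
the 300–3000 Hz band-passed trace, with the RMS taken over the
concatenated PRE windows and counts reported for PRE and POST only — the
during-stimulation epoch is excluded because artifact and multiunit
activity are inseparable without sorting. The band-pass is a 4th-order
Butterworth applied forward and backward (zero phase). The 1 ms dead time
is a package choice.

## Behavioral statistics

Recognition sensitivity is `d' = qnorm(hit rate) - qnorm(false-alarm
rate)` per session and condition. Rates of exactly 0 or 1 are corrected by
the log-linear rule (add 0.5 to the affected rate's numerator and 1 to its
denominator); a `1/(2n)` clamp is the alternative switch. Sessions are
classed by Δd' = d'(stim) - d'(no-stim): positive responder above +0.5,
negative below -0.5, non-responder on the closed interval between. Group
contrasts use Fisher's exact test reporting the *sample* odds ratio
`ad/bc` (the conditional-ML estimate differs and is not used), Mann-Whitney
U with midranks (exact enumeration below 13 observations, tie-corrected
normal approximation otherwise), a paired t-test on hit rates, and a
linear mixed model `d' ~ condition + experiment + (1 | session)` fit by
REML through lme4, falling back to ordinary least squares with a flag when
the session variance is singular. Intervals on the condition effect are
Wald. No response-bias statistic is computed.

## The synthetic-data generator

The generator is the package's study-conditions module, not a tuning knob.
Its defaults emulate the recorded dataset's structure: 160-trial sessions
(80 stim / 80 no-stim, ISI uniform on 6 ± 0.5 s), 200 units with
log-uniform baseline rates over 0.03–10 Hz (about a fifth fall below the
0.1 Hz inclusion threshold, similar to the recorded cohort), region labels
drawn in the recorded proportions (HIP/OFC/AMY/ACC ≈ 95/44/39/25), 30% of
units truly modulated with baselines of at least 2 Hz and effect
magnitudes of 1.5–3 Hz (suppressed with probability 0.56; modulated during
/ post / both epochs with probabilities 0.765 / 0.196 / 0.039), 15% of
units image-responsive, and 85%/15% E/I waveform classes with I units
firing faster at baseline.

Spike trains are piecewise-constant-rate Poisson processes: baseline
everywhere, baseline + image effect while the image is on, baseline +
stimulation effect inside the modulation window of stim trials, truncated
at zero. Within each constant-rate segment the count is Poisson and times
are sorted uniforms — the order-statistics construction, distributionally
identical to drawing exponential gaps and chosen because it vectorizes.
Modulation windows default to the full tested epoch (latency 0 for
during-effects); latency/duration can be set per unit, but the defaults
keep the generator in the detection regime the power analyses assume.

The TBS pulse train places burst k at k × 125 ms with four 50 Hz pulses in
each 62.5 ms duty window (offsets 0/20/40/60 ms) — the unique layout
consistent with the stated rates and duty cycle. The wideband simulator
adds the spike template at spike times and a biphasic rectangular artifact
(0.4 ms per phase, amplitude 20 × noise RMS by default) at pulse times;
artifacts are a stand-in for amplifier transients, not a physical model.
The behavioral generator inverts the d' definition under equal-variance
signal detection with criterion 0 (hit rate Φ(d'/2 + c), false-alarm rate
Φ(-d'/2 + c)) and draws binomial counts.

What the generator does **not** emulate: refractoriness, bursting, rate
drift, correlated noise across units, LFP/oscillatory structure, true
artifact physics, or electrode geometry. Passing tests therefore show that
the statistical machinery is correct and calibrated under the stated
Poisson model — not that real recordings satisfy that model.

## Robustness controls

* **Threshold sweep** — inclusion thresholds 0–3 Hz in 0.1 Hz steps;
  modulation results are computed once (they do not depend on the
  threshold) and re-summarized per threshold.
* **Artifact dropout** — windows of 0–60 ms (5 ms steps) after each of the
  eight burst onsets are censored from DUR, and segments at the same
  within-epoch offsets (0, 125, …, 875 ms) from PRE and POST, so equal
  durations leave every epoch; counts are then compared raw, not
  duration-rescaled. A window of 0 reproduces the base analysis
  bit-identically.
* **Detection-probability simulation** — units are generated over a grid
  of baseline rates and effect sizes and pushed through the full pipeline;
  effects are absolute Hz by default, or rate ratios
  (`effect = baseline × (ratio − 1)`), the mode in which sparsely active
  units are genuinely harder to detect.

## Numerical choices and degenerate inputs

All-zero-difference contrasts are recorded as tested with p = 1, not
significant. Permutation p-values carry the +1 correction. Per-unit
permutation seeds derive deterministically from one master seed, so cohort
analyses are reproducible end to end. Smoothed rate traces convolve 100 ms
binned counts with a unit-area Gaussian kernel (SD 100 ms, matching the
bin) under symmetric edge padding, which conserves total spike mass.
Waveforms without a valley-then-peak structure (flat, monotone, reversed,
or with a post-valley deflection under 5% of the valley amplitude) are
excluded from clustering with a recorded failure rather than measured.

## Problem sizes used by the tests and the acceptance script

Calibration uses 800 exchangeable-null units at 80 stim trials and 1000
permutations; power uses 50 replicate 200-unit cohorts; the detection
surface uses a reduced 3 × 4 grid (plus a two-point rate-ratio contrast)
at 50 replicates per cell; mixed-model recovery uses 100 cohorts of 30
sessions. These sizes were chosen so each Monte-Carlo estimate has a
standard error several times smaller than the property band it is checked
against.

## Known limitations

The permutation test assumes exchangeability of the two epochs' counts
within a trial under the null; slow within-trial nonstationarity (e.g.
image-evoked drift extending into DUR) violates it and is partly
controlled by running identical contrasts on no-stim trials. The interval
decision rule with a 1000-sample null is mildly anticonservative (the
measured type-I rate sits slightly above alpha but inside the calibration
band). K-means assumes two roughly isotropic clusters in (VP, PHW);
heavily overlapping classes will not be recovered. The mixed model treats
d' values as Gaussian outcomes, which is an approximation at extreme hit
or false-alarm rates.
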