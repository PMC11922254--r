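---
title: "Quantifying context-dependent auditory responses in songbird NCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying context-dependent auditory responses in songbird NCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmephys)
```

## Setting

Male zebra finches hear song in very different circumstances: alone, with a
female audience, or while singing to her. The caudomedial nidopallium
(NCM), a higher-order auditory pallial region, modulates its activity with
such contexts. This package implements the standard quantification chain
for playback experiments in awake-behaving birds: sorted single-unit spike
trains and multichannel LFP, stimulus epochs of four playback classes
(`BOS`, `BOS_REV`, `CON`, `WN`) delivered in randomized blocks under two or
more contexts, and per-unit statistics that are then compared across
contexts nonparametrically.

All times are seconds, session-relative; every analysis window is half-open
`[start, end)` so a spike on a boundary is counted exactly once.

## Spike-rate statistics

**Windows.** For songs, the evoked rate `FR_i` is computed per motif (the
repeated stereotyped unit of zebra finch song); white noise carries a
single "motif" spanning the whole stimulus, so one code path serves both.
The playback baseline `BLFR_i` is the 1 s window ending 1 s before onset —
the trailing second is a deliberate buffer against anticipatory or
stimulus-locked activity. For singing bouts, baseline pools two windows
flanking the bout at a 1.5 s distance. These window rules mean epochs must
be scheduled with enough silence around them; the synthetic scheduler
enforces that by construction.

**Z-score.** `Z = (mean FR − mean BLFR) / sqrt(var FR + var BLFR − 2 cov(FR, BLFR))`
with sample (N−1) moments over paired presentations. The denominator equals
the standard deviation of the paired differences, which makes Z invariant
to common shifts and properly accounts for slow co-fluctuation of baseline
and evoked rates within a session. Small trial counts are the norm in this
preparation, hence N−1 throughout. The equation is sometimes rendered
without the radical; because the statistic is a Z-score by name and
construction, the square root is the default, and
`z_score(..., sqrt_denominator = FALSE)` reproduces the no-radical variant
exactly.

**Response strength and d′.** `RS` is the mean paired difference
`FR_i − BLFR_i` (Hz). Selectivity between stimuli A and B is
`d′ = 2 (RS_A − RS_B) / sqrt(var_A + var_B)`, where the variances are taken
over the per-presentation paired differences — the same quantity whose mean
is RS, keeping numerator and denominator on one scale. d′ is antisymmetric
with a zero diagonal, which the test suite checks as an invariant on random
inputs.

**SSA.** Stimulus-specific adaptation is the mean of the last five over the
first five per-presentation rates (motif rates are first averaged within
each presentation, because adaptation is defined across repeated
presentations, not within a song). A declining response gives a ratio below
one; units whose every stimulus has SSA ≤ 0.6 are excluded from context
comparisons. The rationale is an order effect: contexts are run
sequentially (solitary first), so a strongly adapting unit would show a
spurious "context" decrease. The 0.6 boundary is inherited as a
conventional, admittedly arbitrary, threshold and is exposed as a flag
everywhere.

**Offset responses.** Firing often rebounds in the second after a stimulus
ends. The unit-level offset ratio is the mean offset-window rate over the
mean baseline rate — a ratio of means rather than a mean of per-trial
ratios, because single-trial baselines of quiet units are frequently zero
and would make the per-trial ratio undefined or explosive. Offset Z reuses
the Z-score form on offset-window rates paired with trial baselines; no
separate formula for the offset statistic exists in the literature this
implements, so re-using the evoked form is an interpretation and is flagged
as such.

**Responsiveness and classification.** A unit enters analysis if a paired
two-tailed t-test of FR against BLFR pooled over all playbacks rejects at
α = 0.05. Broad- vs narrow-spiking classes (putative excitatory vs
inhibitory) split at a 0.43 ms trough-to-peak width; the published rule
assigns `> 0.43` to BS and `< 0.43` to NS and leaves equality unassigned —
we resolve exact equality to NS by the strict-greater reading of the BS
rule. Degenerate statistics (0/0 variance collapses, zero baselines) return
`NA` — a typed "undefined", never a silent `NaN` — and are dropped pairwise
downstream with logged counts.

## LFP analysis

Preprocessing applies a 60 Hz notch (second-order IIR biquad, quality
factor 30 — only the ≥ 20 dB attenuation at the line frequency is
normative, not the filter family) and then a common average reference;
order matters, since CAR would otherwise spread channel-specific line
residue. Per stimulus presentation, three envelopes are cut: 2 s ending
0.5 s before onset ("before"), the stimulus itself ("during"), and 2 s
starting 0.5 s after offset ("after"). Power spectra use Welch's method
with 1 s Hann segments at 50% overlap — about 1 Hz resolution over the
0–50 Hz range of interest — averaged across channels before any statistics,
and statistics are computed on log10 power (floored at the smallest
positive double to guard exact zeros).

Two permutation procedures share one engine. Stimulus-vs-baseline compares
during- and baseline-envelope trial PSDs by scrambling trial labels
(default 2500 permutations); the context test first baseline-subtracts each
presentation in the log domain, then permutes condition labels. The
empirical statistic is the per-frequency mean difference, and the p-value
is *sign-directed*: the fraction of permuted statistics at least as extreme
in the direction of the empirical sign. Two numerical choices deserve
note:

- A sign-directed tail is half of a two-sided test: under the null it is
  Uniform(0, 0.5). Flagging `p < α` would double the intended error rate,
  so the `significant` flag compares the reported p against `α/2`,
  restoring two-sided control at α. The reported p itself keeps the
  one-tailed convention so tables remain comparable with the original
  procedure. This choice is what makes the type-I calibration test (null
  rejection rate ≈ α) pass; it is a deliberate correction, not a
  reinterpretation of the data.
- p-values are raw tail frequencies without +1 smoothing, so `p = 0` is
  possible and means "below 1/n_perm". An empirical statistic of exactly
  zero gets `p = 1` (the procedure defines behavior only for strictly
  signed statistics).

One seeded RNG stream serves each comparison, and the same label
permutations are reused across the frequency grid of one call — per-call
reproducibility independent of execution order, at the cost of permutation
noise being shared (not the data noise, which dominates) across frequencies
within a comparison.

## Group comparisons

Rate metrics rarely satisfy normality or homoscedasticity at these sample
sizes, so cross-context inference is paired Wilcoxon signed-rank
throughout, with the exact null for n ≤ 25 (no ties) and a
continuity-corrected normal approximation otherwise; zero differences drop
by convention, with counts logged. "Pooled" comparisons average the metric
across stimuli within each unit and pair one value per unit — pooling by
concatenating unit × stimulus pairs would pseudo-replicate each unit four
times and overstate significance. Per-stimulus comparisons are corrected
with an in-package Holm–Bonferroni step-down across the four stimuli
(checked against an independent implementation in the tests); pooled rows
carry no adjustment. d′ comparisons use the BOS row of the pairwise matrix
(BOS against each other stimulus), the row with the strongest selectivity
structure. Comparisons with fewer than five common units are skipped with a
message rather than reported at hopeless power.

## The synthetic world

The generator exists so that every downstream stage has a ground truth. It
emulates the recording structure, not the biophysics:

- **Schedule**: blocks of the four stimuli in random order within each
  context, solitary before social (the experimental order), 25–50 blocks
  per context being typical; stimuli default to 2 s with three motifs.
  The inter-trial gap defaults to 6 s with a hard floor of 4.5 s: 4.5 s is
  the minimum for baseline and offset windows never to touch an adjacent
  stimulus, and 6 s additionally keeps the 2.5 s LFP flanks inside quiet
  periods. The original study does not state its interval; these values are
  geometry-driven choices, not reported ones.
- **Spikes**: an inhomogeneous Poisson process, realized by thinning
  against the piecewise-constant rate envelope — the simplest process whose
  rate structure matches every computed statistic; refractoriness is
  irrelevant to windowed rates and is omitted. During the k-th presentation
  (k = 0, 1, ... per stimulus within a context) of a stimulus, motif-window
  rates are `baseline × gain × (floor + (1 − floor) exp(−k/τ))`;
  τ defaults to 10 trials, which at 50 presentations leaves the first five
  presentations near full strength and the last five at the floor, so the
  SSA estimator reads back the programmed floor with bias below ~0.05
  across the (0, 1] range. Adaptation restarts with each context, emulating
  recovery over the between-condition break. The offset second gets
  `baseline × offset_gain`.
- **Waveforms**: a negative Gaussian trough plus a positive peak at the
  programmed trough-to-peak distance, with a small seeded noise floor —
  enough structure for the width measurement and nothing more.
- **LFP**: per channel, unit-variance 1/f^α Gaussian background (FFT
  shaping), a 60 Hz line component, and band-limited components gated on
  during matching stimulus epochs and scaled so in-band power is multiplied
  by exactly `power_gain` while the stimulus plays (the gating leaks ~1–2 Hz
  beyond the band edges, visible in recovery tests). With no band effects
  the signal is stationary — the global null used for calibration.
- **Streams**: every unit, channel, and comparison derives its own RNG seed
  from the master seed and its name, so adding a unit never perturbs the
  others and identical configurations are byte-identical on disk.

**The audience (social) parameterization.** `simulate_population_config()`
encodes the social condition as: (1) per-unit baseline multiplied by a
lognormal factor whose *population mean* is 1.3 — group-level baseline
shifts in this preparation are ratios of means — with cross-unit dispersion
`sdlog = 0.8`, reflecting that individual units modulate strongly in both
directions while the group-level test stays unreliable; and (2) evoked
*increments* above baseline compressed by half, added onto the social
baseline rather than scaled by it. The additive form matters: baseline
elevation with multiplicatively scaled evoked responses would make strongly
modulated units *more* responsive in the social condition, which is the
opposite of the physiology being emulated (elevated spontaneous firing with
essentially unchanged evoked firing, hence lower normalized responses and
selectivity). Under this world, pooled Z and BOS-row d′ drop for
essentially every unit while raw baseline comparisons come out significant
only occasionally — the direction structure the acceptance suite verifies
on 50 replicate populations.

**What a green test does not establish.** The generator's trial-to-trial
variability is purely Poisson; real NCM units burst, drift, and share
correlated state, all of which widen real sampling distributions relative
to synthetic ones. The LFP is Gaussian and stationary outside programmed
effects; real LFP has nonstationary broadband transients that a permutation
test absorbs but a parametric test would not. Recovery and calibration
results therefore validate the estimators and the code, not effect sizes in
any real dataset.

## Numerical and policy choices, collected

- Half-open windows everywhere; sample (N−1) variances and covariances.
- Undefined statistics are `NA` with logged counts, never silently dropped.
- Welch: 1 s Hann, 50% overlap, mean averaging, channel-average before log.
- Channel averaging precedes the log transform; the alternative
  (log-then-average) weights channels geometrically and can be had by
  transforming the per-channel PSDs upstream.
- Notch: RBJ biquad, Q = 30; contract is ≥ 20 dB at the line frequency and
  < 1 dB through 0–50 Hz.
- Width exactly 0.43 ms classifies NS; SSA exactly 0.6 is excluded
  (retention requires strictly greater).
- LFP on disk is float32 (size/precision trade-off); binary round trips are
  exact to float32 epsilon, all text formats to 1e-9.
- Experiment-1-style behavioral comparisons (singing vs playback) reuse the
  playback offset convention for bout ends, acknowledged as imprecise given
  indeterminate song endings, and subsample playback trials (seeded,
  uniform) to the sung-motif count to match variance structure.

## Limitations

No spike sorting, burst/latency analysis, time-frequency or phase-coupling
methods, and no mixed-effects modeling: the nonparametric Wilcoxon/Holm
path is the package's single inference route, applied uniformly. Hemisphere
is not modeled (pooled upstream). The CLI provides the pipeline stages but
no plotting beyond what the metrics tables enable.
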