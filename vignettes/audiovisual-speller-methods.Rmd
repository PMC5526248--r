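---
title: "Methods: simulation and offline decoding of an audiovisual P300 speller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and offline decoding of an audiovisual P300 speller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpspeller)
```

This vignette documents the models, parameter choices and numerical
conventions behind `erpspeller`, and states what the synthetic-data
validation does and does not demonstrate about real EEG.

## The experiment being modelled

An ERP speller presents a small set of stimuli repeatedly while the user
attends one of them (the oddball paradigm). Attended ("target") stimuli
evoke larger late components — most prominently the P3 around 350 ms —
than unattended ones, and a classifier trained on single-epoch features
can identify the attended stimulus by aggregating evidence over
repetitions. The paradigm simulated here uses 4 stimuli per repetition,
10 repetitions per block, a 330 ms stimulus-onset asynchrony (130 ms
stimulus duration + 200 ms inter-stimulus interval), and a 2 s quiet
interval between the target cue and each block onset. Two stimulation
conditions ("congruent" and "incongruent" audiovisual pairing) differ in
overall ERP amplitude but not — by construction — in target/non-target
discriminability. This is the configuration in which a speller can show
*larger ERPs yet unchanged accuracy*, the scenario the analysis pipeline
is designed to resolve.

## Synthetic EEG generator

**Components.** Each evoked component is a Gaussian bump
`A · exp(−(t−τ)²/2σ²)` with peak latency τ, half-width-at-half-maximum
h (σ = h/√(2 ln 2)), hard-truncated beyond 3h from the peak (tail
< 0.3% of A). A Gaussian was chosen because the morphology is not
otherwise constrained, and a two-parameter unimodal bump makes every
downstream measurement (amplitude, latency, window content)
analytically checkable. Defaults:

| component | peak (ms) | HWHM (ms) | target (µV) | non-target (µV) |
|---|---|---|---|---|
| N2 | 200 | 40 | −5.0 | −2.0 |
| P3 | 350 | 60 | +6.0 | +2.0 |
| N4 | 440 | 45 | −2.5 | −1.0 |
| P5 | 620 | 70 | +2.0 | +1.0 |

Topographies are unitless gain maps over the 64-channel extended 10–20
montage (gain 1 at the peak electrode, 0.7 at near neighbours, 0.35 at
the fringe): N2 fronto-central (Cz), P3 centro-parietal (Pz), N4/P5
posterior (POz). Amplitudes were set to produce single-trial accuracies
and r² maps in the range reported for audiovisual spellers (~0.1 peak
r², 70–85% single-trial accuracy) under the default noise.

**Congruency.** The incongruent condition multiplies the
class-independent (common) part of the N2 and P3 amplitudes by 1.5 while
keeping the target-minus-non-target contrast fixed: non-target amplitude
`a_N → 1.5·a_N`, target amplitude `1.5·a_N + (a_T − a_N)`. Both classes
therefore gain amplitude but the discriminative signal is unchanged —
larger ERPs, identical class separation.

**Noise.** Independent per channel: 1/f-shaped noise (spectral exponent
1, sd 4 µV) generated by spectral shaping of white noise, band-limited
alpha (8–12 Hz, sd 1.5 µV), and white noise (sd 1 µV). The defaults give
a per-sample background of ≈ 4.5 µV sd against a 4 µV P3 contrast at the
peak electrode — a realistic pre-averaging SNR for scalp ERP work.

**Overlap.** Because the SOA (330 ms) is much shorter than the analysis
epoch (1 s), the renderer adds each stimulus' response additively at its
own onset, so neighbouring responses overlap exactly as in the real
paradigm. This matters: a condition effect on N2/P3 re-enters the epoch
through the *next* stimulus' response (≈ 530 ms and later) and through
the baseline window (the previous P3 peaks 20 ms post-baseline-onset),
so FDR maps legitimately show condition differences outside the nominal
component windows. The replica test only requires differences *inside*
the N2/P3 ranges for this reason.

**What the simulator does not emulate:** ocular/muscle artifacts (the
amplitude-rejection hook stands in for component-based artifact removal,
which is a recording-level concern), volume conduction (channels share
topographic gains but their noise is independent, so spatial noise
correlation is absent), non-stationarity, and between-channel impedance
differences. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration, not robustness to real
artifacts.

**Determinism.** Every generator call seeds R's RNG from its config
seed; identical configs give bit-identical recordings. The study driver
derives per-stage seeds deterministically from one master seed.

## Preprocessing

The chain is re-reference → band-pass → down-sample → epoch → baseline,
in that order, enforced by the driver.

* *Re-referencing*: every channel minus the mean of M1/M2. Invariant to
  common-mode signals; verified by construction tests.
* *Band-pass 0.5–40 Hz*: zero-phase (forward–backward) Butterworth,
  applied as a 2nd-order high-pass then a 2nd-order low-pass (effective
  order 4 after the two passes). Separate sections keep the extreme
  low-edge filter (0.5 Hz at fs 500) numerically stable where a single
  8-pole band-pass is not. Mid-band gain is within 5% of unity;
  100 Hz is attenuated by more than 20 dB.
* *Down-sampling 500 → 200 Hz*: cubic-spline interpolation onto the
  target grid. The signal is already band-limited to 40 Hz — well below
  the new 100 Hz Nyquist — so no additional anti-alias filter is
  needed, and spline interpolation of a 40 Hz-limited signal sampled at
  500 Hz is accurate to well under 1%. (A polyphase resampler was
  rejected after it showed several percent passband ripple on pure
  tones in this configuration.)
* *Epoching*: half-open window [−200, 800) ms, so 200 Hz gives exactly
  200 samples; the endpoint convention is a package choice. Events too
  close to a recording edge are dropped with a counted warning.
* *Baseline*: per epoch/channel mean over [−200, 0) ms subtracted;
  idempotent by construction.

## Classifiability and features

`r_squared()` implements the squared point-biserial correlation with the
**population** (biased) pooled standard deviation. That convention makes
the statistic exactly the squared Pearson correlation between feature
and 0/1 label, which is the identity the test suite verifies against an
independent correlation oracle; the sample standard deviation would
break it. Features with zero pooled variance score 0 (not an error), so
maps over degenerate channels stay total.

Feature extraction reduces each window to consecutive non-overlapping
block means at 40 Hz (5-sample blocks at 200 Hz) — block averaging
rather than decimation, for noise reduction and phase insensitivity.
The default channels and windows are the fixed published speller set;
`select_channels()` offers the data-driven re-ranking by window-averaged
r², but the fixed set is the default so that channel selection cannot
leak test data into training.

## Classifiers

**SWLDA** is implemented from scratch. Labels are coded +1/−1 and
weighted by OLS. Forward steps add the candidate with the smallest
partial-F p-value while it is below 0.10; backward steps drop the worst
retained feature while its coefficient p-value exceeds 0.15; the cycle
repeats to stability or the 60-feature cap. The 0.10/0.15 thresholds
are the long-standing convention for stepwise P300 classifiers; the cap
is implemented as a cap (not an exact count) because informative
features may run out first. Tie-breaks: smallest p-value, then lowest
feature index. Candidates numerically inside the current design span
are skipped. The decision threshold for single-trial accuracy is 0.

**Linear maximum-margin classifier**: soft-margin linear SVM, penalty C
selected by stratified 10-fold cross-validation over a small grid
(ties toward the smallest C). The quadratic program is delegated to
libsvm (`e1071`); the hyperplane is re-expressed as explicit weights and
oriented so targets score higher, since libsvm's decision sign depends
on label ordering.

## Character decoding

Scores are summed over the first k repetitions in presentation order and
the argmax stimulus is the decision (ties to the lowest id, so the rule
is deterministic). Summation equals averaging for a fixed k and is the
standard aggregation for linear P300 decoders. The recognition curve is
the fraction of blocks decoded correctly at each k.

The study driver evaluates accuracy and curves by rotating the 3/4–1/4
block split over all four folds (each block tested once, trained on the
other three). A single random split is also provided (`split_blocks()`)
and matches the published protocol, but with only four blocks it yields
a 0/1-valued curve per subject; rotation uses every epoch once for
testing at the same train fraction and gives the paired condition tests
usable per-subject resolution.

## Statistics

**Bootstrap t-test**: the observed paired t statistic, with a p-value
from resampling the mean-centered differences (default 1000 draws) and
recomputing t — a percentile-t null that assumes no normality. The
p-value is the plug-in fraction `#{|t*| ≥ |t_obs|}/iters`, with
resolution 1/iters; 0 means "beyond bootstrap resolution". The smoothed
`(count+1)/(iters+1)` estimator was deliberately not used: its ~1e−3
floor makes BH-FDR over a 62 × 200 point grid unable to reject anything
at 1000 iterations, even for effects with |t| > 6. Degenerate
zero-variance differences give t = 0 (p = 1) when the mean difference is
also zero and ±∞ (p = 0) otherwise. Type-I error at α = 0.05 with n = 11
calibrates to ≈ 0.05 (tested over 500 null replicates).

**ERP-map comparison**: the same bootstrap at every (channel, time)
point, with one shared set of resample draws across points so the whole
sweep reduces to two matrix products, followed by BH correction jointly
across all points. Sharing draws across points does not change any
single point's marginal p-value; it only correlates them, which BH
tolerates. FDR correction delegates to `stats::p.adjust(method = "BH")`;
the test suite holds it against a brute-force step-up implementation.

**Components**: amplitude is the polarity-matching extremum in the
window, latency its time; flat windows are flagged degenerate. Default
windows bracket the nominal peaks: N2 150–280 ms (−), P3 280–450 ms (+),
N4 400–480 ms (−), P5 550–700 ms (+). The default measurement electrodes
are Cz, POz and FC5.

## Validation scale

The test suite validates at these problem sizes, chosen to exercise
every claim at full fidelity where it matters (the 11-subject replica,
the 500-replicate calibration) while staying desk-sized: oracle
identities on 1000 random instances; bootstrap calibration over 500
null replicates of n = 11; FDR map calibration over 20 null studies of
a 10 × 40 grid; parameter recovery on a 160-epoch single-subject
session; and the full two-condition replica with 11 subjects, 4 blocks
× 10 repetitions × 4 stimuli per condition, 64 channels at 500 Hz, both
classifiers, and 1000-iteration statistics.

## Known limitations

* The simulator's noise is spatially independent across channels;
  spatial whitening or correlated-noise classifiers cannot be
  meaningfully benchmarked against it.
* Single-trial accuracy under class imbalance: with the 1:3
  target:non-target ratio an uninformative classifier at threshold 0
  converges to the majority-class rate (0.75), not 0.5; chance-level
  claims in the package are therefore stated via the character-decoding
  floor (1/4), which is imbalance-free.
* The EDF writer emits plain continuous EDF (16-bit, single data
  record); annotations are not embedded — events travel in the
  tab-separated sidecar.
* ANOVA-style multi-factor comparisons are not implemented; every
  reported contrast is a paired two-condition test.
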