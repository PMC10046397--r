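---
title: "Methods: cuffless PPG blood-pressure estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless PPG blood-pressure estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The estimation problem

A reflective PPG sensor emits light into the skin and measures the
returned intensity. The signal decomposes into a large, slow **DC**
component (tissue, bone, venous blood, respiration) and a small pulsatile
**AC** component that follows each heartbeat. The AC beat morphology —
upstroke speed, the relative position and size of the systolic and
diastolic peaks, areas under the two phases — co-varies with arterial
pressure, but only *relatively*: PPG cannot produce absolute mmHg on its
own. The approach implemented here therefore (i) extracts a fixed set of
waveform features per time window, (ii) regresses SBP and DBP on those
features with a Gaussian process, and (iii) anchors the resulting relative
scale with one cuff reference reading per subject.

## Synthetic data: what it emulates and what it does not

The generator is first-class, tested code — it defines the study
conditions for every quantitative claim in this package.

Each beat is the sum of two Gaussian lobes on a zero baseline. With beat
period $T = 60/\mathrm{HR}$:

$$b(t) = A\left[e^{-(t - c_s T)^2 / 2(w_s T)^2}
        + r\, e^{-(t - (c_s + 0.28) T)^2 / 2(0.11\,T)^2}\right]$$

with $w_s = 0.07$ and the BP link

* $A = 0.6 + 0.010\,(\mathrm{SBP} - 60)$ — amplitude grows with systolic
  pressure;
* $c_s = 0.32 - 9{\times}10^{-4}\,(\mathrm{SBP} - 60)$ — the systolic time
  *shrinks* as systolic pressure rises (faster upstroke);
* $r = 0.20 + 4.5{\times}10^{-3}\,(\mathrm{DBP} - 40)$ — the
  diastolic-to-systolic ratio grows with diastolic pressure (stronger
  reflected wave).

The link is deliberately simple: deterministic, injective, and monotone in
each coordinate, which is exactly what makes recovery testable (a
nearest-neighbour inverse on a dense grid must return the true pressures).
It is an *assumption of the phantom*, not a physiological model: no real
arterial tree produces so clean a map, and passing recovery tests on this
phantom demonstrates the pipeline's correctness, not clinical accuracy.

Beats are concatenated foot-to-foot; a DC baseline (constant offset at
10× the AC amplitude plus a respiration sinusoid at 0.2× the AC
amplitude) and white noise are added. The three perceptual quality levels
used by human raters — *fair* (peaks not distinguishable from noise),
*good* (systolic clear, diastolic not), *excellent* (both clear) — are
operationalized as SNR tiers of 5, 15, and 30 dB, with random baseline
steps added at the fair tier to emulate micromotion. Real artifacts the
phantom does not model: pulse-shape variability between beats, arrhythmia,
sensor decoupling, ambient-light interference, and skin-optics differences
beyond a simple amplitude scale (phototype III scales AC by 0.8). All
randomness flows from one caller-supplied seed; identical inputs give
bit-identical records.

## Signal processing

**AC/DC split.** The DC estimate is a zero-phase (forward–backward)
Butterworth low-pass of the input and AC is the residual, so
reconstruction is exact by definition. The cutoff is 0.5 Hz: respiration
sits below ≈0.4 Hz and the slowest plausible cardiac fundamental (40 bpm)
at 0.67 Hz. We use order 4 rather than 2: applied forward and backward, a
2nd-order filter still leaks ≈6% of the power of a 1.2 Hz cardiac
fundamental into the DC estimate, while order 4 keeps cardiac-band
retention in AC above 99%. The input mean is removed before filtering and
restored afterwards, so a constant record splits exactly into itself and
zero. Mirror padding (3 s) suppresses edge transients.

**Segmentation.** Feet are local minima preceding upstrokes whose slope
exceeds half the 98th percentile of positive slopes — an adaptive
threshold with no amplitude units. The slope search runs on an 8 Hz
low-passed copy: beat morphology lives below ≈3 Hz, and wideband noise
otherwise fragments the upstroke runs (at the 15 dB tier an unsmoothed
search finds no valid beats at all). Beats shorter than 60/180 s or longer
than 60/40 s are discarded, as is the trailing partial beat. Indices are
0-based; intervals are foot-inclusive, next-foot-exclusive.

**Peaks and quality.** The systolic peak is the global maximum after the
foot; the diastolic peak is the most prominent later local maximum whose
prominence exceeds 5% of pulse amplitude (detects dicrotic-wave humps,
rejects noise ripples). A beat whose global maximum falls past 60% of its
length violates systolic-first morphology and is flagged invalid rather
than corrected — at exactly half we would misflag a symmetric beat. Pulse
SNR is estimated as in-band (10 Hz low-passed) power over residual power;
*excellent* requires both peaks and SNR ≥ 12 dB, *good* a clear systolic
peak only, *fair* otherwise. The thresholds are operational surrogates for
human-rater judgment and are configurable.

## The ten features

Per 15-s window (non-overlapping, aligned to the record start), on
baseline-subtracted beats with the systolic/diastolic split at the
systolic peak: systolic and diastolic areas over total area, both areas
over pulse amplitude, maximal amplitude over time (amplitude divided by
systolic time — an upstroke-slope proxy), systolic time, diastolic time,
mean peak-to-peak interval, pulse amplitude, and width at half amplitude.
Splitting at the peak rather than the dicrotic notch keeps the area
partition exact (the two area fractions sum to 1 by construction) and
works on fair-quality beats where the notch is undetectable. Windows
summarize per-beat values by the **median** for robustness to residual
artifact beats; the peak-to-peak interval is the mean spacing of
successive systolic peaks, which is why a window needs at least two usable
beats.

Two numerical choices matter. Landmarks are integer sample indices, which
at 256 Hz quantizes time features in 3.9-ms steps — larger than the
per-mmHg morphology changes. The feature computation therefore refines the
systolic peak by 3-point parabolic interpolation and moves the area split
continuously (a partial trapezoid strip between the sample peak and the
refined peak time, with the diastolic area taken as total minus systolic
so the partition stays exact). The half-amplitude width interpolates its
crossings linearly for the same reason.

## Gaussian-process regression and fine-tuning

One model per target under the exponential kernel
$k(x, x') = S^2 \exp(-\lVert x - x'\rVert/\ell)$, with observation noise
$\sigma_n^2$ on the diagonal and a jitter of $10^{-8} S^2$. Features are
standardized by training-column mean/SD before distances are computed
(the features mix seconds, ratios, and amplitudes); the constants ship
with the model. The prior mean is the training-response mean.

Initialization follows the scheme in which the kernel scale is searched
over $[0.001, 1] \times \mathrm{XMaxRange}$, where XMaxRange is the
largest column range of the predictor matrix, and the signal SD starts at
the pooled sample SD of the predictor entries,
$S = \sqrt{\tfrac{1}{N-1}\sum_i |X_i - \mu|^2}$ with $\mu$ the mean over
all entries. The pooled (axis-free) reading is used because no axis is
specified for $\mu$; and the square root is taken so the quantity is a
standard deviation as named.

**Fine-tuning** re-trains on new data with the kernel scale and signal SD
frozen at their pretrained values — 11.9 and 9.6 in the shipped
configuration — so the optimizer runs over the noise SD only (a 1-D
bounded marginal-likelihood search instead of a 3-D one). The model object
records which hyperparameters were searched, and the test suite asserts
the fixed-kernel path never explores the kernel. Whether a deployed device
would also freeze the noise variance is unknowable from the outside; we
re-estimate it, since the new data's noise level is precisely what
transfers least from a pretraining corpus.

The predictive SD includes the noise term, so far from all training data
the posterior reverts to the prior mean with spread
$\sqrt{S^2 + \sigma_n^2}$.

## Calibration

Calibration stores an additive offset per target — cuff reading minus
model prediction at the calibration features — making the estimate at the
calibration operating point equal the cuff value exactly, and leaving all
*changes* to the GP. An additive anchor is the minimal mechanism
consistent with PPG estimating only BP changes; whether a real device
instead re-fits its model with the cuff pair appended is not public, and
the offset has the testable property that shifting all training responses
by a constant leaves calibrated estimates unchanged. Only the most recent
calibration is retained. Estimates with SBP ≤ DBP are flagged invalid,
never silently reordered. The automated cuff-to-wearable calibration
handshake is modeled as a deterministic eight-state machine (default →
paired → started → measured → transferred → calibrated → confirmed, plus
aborted); any out-of-order event aborts with a diagnostic, and replaying
the last consumed event is idempotent.

## Protocol and validation statistics

The same-arm sequential schedule alternates reference and test readings,
starting with the reference: eight slots in week 1 (BP1 'calibrated' /
BP2 'calibration' plus three comparison pairs), six in weeks 2–5, with at
least 60 s between readings. Pairing compares the **mean of the two
blinded observers** at each reference slot with the immediately following
test slot — supervisor readings never enter pairing, since their role in
the analysis is not specified — so 30 complete subjects give 90 pairs per
week. Timestamps are validated but not enforced in simulation, where
sessions are instantaneous.

Validation statistics, all reorder-invariant and inclusive at their
boundaries: pooled mean and sample SD (N−1) of test-minus-reference
differences with the criterion-1 decision |mean| ≤ 5 and SD ≤ 8.0 mmHg;
the criterion-2 statistic (SD across per-subject mean differences)
against the fixed bounds 6.89 (SBP) and 6.84 (DBP) mmHg — stated as fixed
bounds rather than recomputed from the general ISO probability formula;
cumulative percentages of |difference| within 5/10/15 mmHg; the BHS grade
as the best grade whose three thresholds are *all* met (A: 60/85/95,
B: 50/75/90, C: 40/65/85, else D); Bland–Altman limits mean ± 1.96 SD;
and the Pearson correlation with its t-distribution p-value.

## The simulated study

`run_pipeline()` mirrors a complete validation campaign at desk scale:
a 35-subject pretraining cohort and a 25-subject fine-tuning cohort
(60-s recordings, four 15-s windows each, so roughly 140 and 100 training
windows), then 30 validation subjects followed over 5 weekly sessions.
Subject pressures are drawn with SBP in [95, 165] and DBP in [60, 100]
mmHg (pulse pressure ≥ 25), heart rates in [55, 95] bpm; week-to-week BP
drifts as a random walk with 2 mmHg SD, slot-to-slot variation is 1 mmHg
SD, and each observer reading adds 1.5 mmHg SD of measurement noise.
Each subject is calibrated once, at week-1 BP1/BP2, and never
recalibrated — so weeks 2–5 measure how the uncalibrated estimates hold
up as the cohort's pressures drift. These problem sizes keep a full run
to a few tens of seconds while leaving every statistic well-populated
(90 pairs per week). Under these conditions the simulated study passes ISO
criterion 1 in every week for both targets; that is a statement about
the phantom and the pipeline's internal consistency, not about clinical
performance, which can only be established on real subjects.

## Known limitations

* The BP→morphology link is invented plumbing; nothing here validates a
  physiological claim.
* Quality grading is an algorithmic surrogate for three human raters;
  agreement with human judgment is untested and untestable here.
* The GP is exact (dense Cholesky), fine for hundreds of windows; no
  sparse approximations are provided.
* Motion artifacts beyond baseline steps, arrhythmias, and
  sensor-coupling effects are out of the generator's scope, so the
  pipeline's robustness to them is unknown.
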