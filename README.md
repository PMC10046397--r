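# ppgbp

Cuffless blood-pressure (BP) estimation from single-channel reflective
photoplethysmography (PPG), with the full validation machinery used to
qualify BP monitors — for researchers and engineers developing or
evaluating wearable cuffless devices, and for anyone who needs the
ISO 81060-2 / BHS / Bland–Altman statistics as tested, reusable code.

A reflective PPG sensor sees a large, slowly varying **DC** level (tissue,
venous blood, respiration) with a small pulsatile **AC** component
synchronous with the heartbeat. Each AC beat carries a systolic peak and a
smaller, later diastolic peak; how the beat's shape changes tracks *changes*
in arterial pressure, so a single cuff reading is needed to anchor the
estimates to absolute mmHg.

The pipeline:

1. **Synthesis** (`synth_recording`): a two-Gaussian-lobe beat phantom with
   a deterministic, injective map from (SBP, DBP) to morphology, a
   respiration + offset DC baseline (DC:AC ≈ 10:1), and three noise tiers
   (fair 5 dB, good 15 dB, excellent 30 dB SNR). Ground truth and beat
   onsets are logged, so every downstream stage is testable without
   clinical data.
2. **Signal processing** (`acdc_split`, `segment_pulses`, `detect_peaks`,
   `grade_quality`): zero-phase 0.5 Hz low-pass DC/AC decomposition with
   exact reconstruction, foot-to-foot beat segmentation, peak landmarks,
   and fair/good/excellent quality grading.
3. **Features** (`extract_features`, `build_feature_matrix`): a fixed
   10-dimensional waveform vector per 15-s window — systolic/diastolic
   areas over total area and over pulse amplitude, maximal
   amplitude-over-time (upstroke-slope proxy), systolic and diastolic
   times, mean peak-to-peak interval, pulse amplitude, and half-amplitude
   width.
4. **Regression** (`gpr_fit`, `predict`, `gpr_finetune`): Gaussian-process
   regression with the exponential kernel
   `k(x, x') = S² exp(−‖x − x'‖ / ℓ)`, one model per target (SBP, DBP).
   The kernel scale is searched in `[0.001, 1] × XMaxRange` with
   `XMaxRange = max(max(X) − min(X))`, and the signal SD initialized as the
   pooled sample SD of the predictor entries. *Fine-tuning* re-trains on
   new data with `ℓ = 11.9` and `S = 9.6` held fixed, estimating only the
   noise level — much cheaper, and it shrinks the stored model.
5. **Calibration** (`calibrate`, `estimate_bp`): an additive offset per
   target anchored at a cuff reading, plus the eight-state automated
   calibration-session workflow.
6. **Protocol & validation** (`protocol_schedule`, `build_pairs`,
   `weekly_report`): the same-arm sequential schedule (BP1–BP8,
   alternating reference/test, calibration slots only in week 1), the
   reference-test pairing (mean of two blinded observers vs the following
   test slot, 3 pairs per subject-week), and ISO 81060-2 criteria 1
   (|mean| ≤ 5, SD ≤ 8 mmHg) and 2 (per-subject SD ≤ 6.89 / 6.84 mmHg),
   BHS A–D grading from cumulative percentages within 5/10/15 mmHg,
   Bland–Altman limits of agreement, and Pearson correlation.

## Worked example

```r
library(ppgbp)

prof <- subject_profile("s01", sbp_true = 128, dbp_true = 84, heart_rate = 72)
rec  <- synth_recording(prof, duration = 60, quality = "excellent", rng_seed = 42)
rec
#> <ppg_record> 60 s @ 256 Hz, quality 'excellent', truth 128/84 mmHg

pulses <- lapply(segment_pulses(acdc_split(rec)$ac, rec$fs), detect_peaks)
length(pulses)                       # 72 beats in 60 s at 72 bpm
grade_quality(pulses[[1]])
#> <ppg_pulse> 203 samples @ 256 Hz; systolic peak 54, diastolic peak 116, quality 'excellent'

round(extract_features(pulses[1:18], rec$fs), 4)
#>  sys_area_over_total  dia_area_over_total    sys_area_over_amp
#>               0.3117               0.6883               0.0770
#>    dia_area_over_amp    max_amp_over_time        systolic_time
#>               0.1725               5.9164               0.2249
#>       diastolic_time     mean_pp_interval      pulse_amplitude
#>               0.6073               0.8323               1.3230
#> pulse_width_half_amp
#>               0.1498
```

About 31% of the beat's area precedes the systolic peak; the upstroke takes
0.22 s of the 0.83-s beat; amplitudes are in arbitrary optical units.

A full simulated study — pretrain, fine-tune, calibrate 30 subjects once at
week 1, then five weekly sessions of alternating cuff/cuffless readings:

```r
res <- run_pipeline(default_config())
res$report
#> Blood-pressure validation report (test - reference, mmHg)
#>  week target  n      mean+/-SD   <=5   <=10   <=15 BHS ISO1 ISO2     r
#>     1    SBP 90 -0.12 +/- 2.49 95.6% 100.0% 100.0%   A pass pass 0.993
#>     1    DBP 90  0.35 +/- 4.00 80.0% 100.0% 100.0%   A pass pass 0.912
#>     2    SBP 90 -0.20 +/- 3.23 88.9% 100.0% 100.0%   A pass pass 0.989
#>     2    DBP 90  0.25 +/- 3.62 84.4% 100.0% 100.0%   A pass pass 0.933
#>  ...
```

Each row is one week × target over 90 test-vs-reference pairs (30 subjects
× 3 pairs): the pooled mean ± SD of the differences, the cumulative
percentages within 5/10/15 mmHg, the BHS grade, both ISO 81060-2 decisions,
and the correlation with the reference. These numbers describe the
synthetic cohort the generator defines, not any clinical population.

A command-line wrapper with `synth`, `segment`, `extract`, `train`,
`finetune`, `calibrate`, `predict`, `pairs`, `validate`, and `run`
subcommands is installed at `inst/cli/ppgbp.R`.

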