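---
title: "Methods: sound-quality descriptors, EEG band-power biomarkers, and the statistics that connect them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the design decisions that were
genuinely open.

## The measurement problem

A learner bowing a sustained open string produces a tone whose quality
can be read off the signal: a good tone holds a steady pitch, a steady
dynamic level, and a strongly periodic (non-scratchy) waveform. The
package turns each trial's recording into three descriptors built on the
Yin fundamental-frequency estimator, summarises them into one composite
learning score, and in parallel reduces the EEG recorded during the same
trials to clustered band power, asking how cortical activity reorganises
as the motor skill consolidates. The session design — a baseline block of
five trials followed by three learning blocks of five — anchors both
streams: every "change" quantity in the package is relative to the
baseline block.

## Audio stage

**Yin frame metrics.** Analysis windows of 33 ms slide with a 0.7 ms hop
(defaults; both configurable). Per window the squared-difference function
`d(tau)` is evaluated exactly via FFT cross-correlation plus running
energy sums, normalised to the cumulative-mean-normalised difference
`d'(tau)`, and the first dip of `d'` below the absolute threshold (0.15
by default) is refined by parabolic interpolation. Frames with no dip
below threshold are unvoiced: they carry no f0 but do carry power and
aperiodicity. Aperiodicity is `d(tau*) / (E0 + E(tau*))` at the best lag
— the fraction of total power unexplained by the best periodic model —
clamped to [0, 1]; for a silent frame it is defined as 1.

*Why 0.15:* mid-range of published practice for the cumulative-mean
normalised threshold; lower values fragment the voicing decision on
noisy bowing, higher values admit octave errors.

*The 0.7 ms hop* (about 1430 frames/s) is unusually dense but is the
stated analysis condition, so it is the default. The per-trial SD
descriptors are insensitive to hop density; the test-suite and the
acceptance runs therefore use a 7 ms hop where only descriptor-level
results are needed, purely a problem-size choice.

*f0 search range:* 100–2000 Hz by default. The lower bound sets the lag
range (441 samples at 44.1 kHz) and hence the extra signal each frame
needs beyond the window.

**Descriptors.** Dynamic instability and pitch instability are the
*population* SDs (1/N inside the root) of frame power and frame cents;
the quantities are deliberately oriented so that larger = worse sound.
Pitch SD uses voiced frames only — unvoiced frames have no defined f0 —
while power SD and the aperiodicity mean use all frames, because
unvoiced scratchy frames are exactly the bad-sound signal.

**Sound instability.** The composite standardises the descriptors across
a cohort and averages them per trial. Two genuinely open choices:

- *Centering vs z-scoring.* Averaging components measured in power²,
  cents and a dimensionless ratio is only meaningful after variance
  normalisation, so the default is the full z-score (population SD);
  plain mean-subtraction is available as `scale = "center"` for
  consumers who want the literal centering-only variant. Both leave the
  cohort mean at 0 by construction.
- *Standardisation cohort.* All trials of all subjects in the analysis
  run share one scale, because cross-group comparisons need commensurate
  composites. Per-subject standardisation would erase exactly the
  between-group differences of interest.

**Block percent change** is
`100 (mean(baseline) − mean(block)) / |mean(baseline)|`. The absolute
value in the denominator matters: a z-scored composite can have a
negative baseline mean (experts typically do), and without it the sign
of "improvement" would flip. The sign convention (positive = the score
fell = improvement) is recorded in the output's `direction` attribute.

The late block is trials 16–20. Blocks must be disjoint, and the
session's last period is the five final trials.

## EEG stage

**Welch PSD.** 2 s segments (0.5 Hz resolution), 50% overlap, periodic
Hann taper — the classic defaults of the overlapped-segment estimator;
both are configurable. The density scaling satisfies the discrete
Parseval relation (verified in the tests against sine and white-noise
oracles).

**Bands and clusters.** Theta 4–8, alpha 8–13, beta 13–24, gamma
30–50 Hz; the gamma cap respects the 64 Hz Nyquist of 128 Hz
recordings. Band power is the *mean* density over bins (µV²/Hz) rather
than the integral, so bands of different widths are comparable;
`mode = "integral"` is available. Cluster values are plain means over
member electrodes of the 13 standard clusters (frontal, midfrontal,
left/right frontal, posterior, left/right posterior, occipital,
left/right parietal, temporal, left/right temporal).

**Outlier masking.** Modified Z-scores `M = 0.6745 (x − median)/MAD`
with |M| > 3.5 flagged. The open question is the scope over which the
median and MAD are taken. Applying it across a subject's full 20-trial
series (per cluster and band) turns out to be self-defeating: when a
genuine block-level power shift exists — and a 0.7× density step, the
magnitude ERD studies report, is exactly that — the 15 post-baseline
trials dominate the median and the *entire baseline block* is flagged as
outliers whenever trial-to-trial spread is modest, which destroys the
ERD computation it was meant to protect. The default scope is therefore
within (subject, cluster, band, **block**): artifact trials are still
caught against their within-block peers, and block-level structure is
never mistaken for outliers. The subject-wide scope is retained as
`scope = "subject"`. With five values per cell the MAD is noisy and the
filter is trigger-happy (about a 4% per-cell flag rate on clean
Gaussian data); since flagged trials are merely dropped from five-trial
means, this costs a little efficiency, not validity.

**ERD/ERS.** `100 (baseline − test)/test`, with the *test-interval*
power in the denominator — this is the defining convention here, kept
exactly as stated even though the classic literature normalises by
baseline; `denominator = "baseline"` provides the classic form,
clearly non-default. Positive values are desynchronization. Baseline
power per (subject, cluster, band) is the mean over unmasked trials
1–5; block power the mean over the block's unmasked trials. No
re-referencing and no artifact rejection beyond the mask are applied
(an optional 1–60 Hz zero-phase pre-filter hook was considered and
dropped: the synthetic data is already band-limited and real pipelines
disagree on the filter; the masking stage is the only cleaning step).

## Statistics

**Information gain** uses supervised Fayyad–Irani MDL binary splitting
(the behaviour of the standard gain-attribute evaluators): recursive
entropy-minimising cuts accepted only when the gain exceeds the MDL
coding cost `(log2(N−1) + log2(3^k −2) − k·H + k1·H1 + k2·H2)/N`. A
feature that accepts no cut has zero gain. An equal-width discretizer
(k = 10) is kept as an oracle-friendly fallback. Rankings break ties by
feature name so they are deterministic. Rankings are computed on the
baseline block only — before any feedback or video review could
differentiate the groups.

**Test battery.** Shapiro–Wilk gates to nonparametric tests at α = 0.05
(a zero-variance group is treated as failing the gate). Rank tests use
`stats::wilcox.test`: exact p-values where R provides them (small
samples, no ties — all the study's group sizes are ≤ 9), mid-rank normal
approximation otherwise; the tests cross-check small-sample p-values
against an exhaustive permutation oracle. Bonferroni families follow the
analysis structure: the number of groups for block tests, the top-8
features for baseline EEG contrasts, the full cluster × band × block
grid for ERD-vs-zero tests (13 × 4 × 3 = 156, per-test threshold
0.05/156 ≈ 0.00032), the number of bands (4) for correlations, and the
number of shared material types for the behavioural comparisons. The
family sizes are computed from the actual test counts, never hard-coded.

**Correlation.** Per band, the Pearson correlation between the
trial-averaged frontal cluster power and the trial-averaged Sound
instability, over the session's 20 trials. By default the two beginner
groups are pooled (they share the learning trajectory that drives both
series); `correlation_groups` widens or narrows the pool.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces the *structure* the analysis assumes, not the
physics of a violin or a cortex:

- **Audio**: a 6-harmonic tone with 1/k rolloff, an 8-stroke bowing
  envelope with gentle (30%) dips, pitch following a mean-reverting
  AR(1) drift (150 ms correlation time, generated at 100 Hz and
  interpolated) with stationary SD equal to the programmed jitter in
  cents, a matching slow log-amplitude drift, and white noise at a
  programmed SNR. The drift is deliberately *slow*: i.i.d. per-frame
  jitter would be read by Yin as aperiodicity, not pitch instability.
- **EEG**: per channel, a sum over bands of white noise brick-wall
  filtered in the frequency domain (a zero-phase filter with exactly
  unit passband gain), each realisation rescaled so its variance equals
  density × bandwidth exactly. Measured Welch density then matches the
  target up to Hann-taper leakage at band edges (a few percent for the
  narrow theta band, less elsewhere). Targets are set per region
  (frontal / posterior / temporal); all 13 analysis clusters are
  subsets of single regions, so region targets fix every cluster's
  expectation.
- **Cohort defaults** (chosen once as plausible study conditions, not
  fitted to anything): groups of 7 experts and 9 + 9 beginners, 20
  trials; beginner pitch jitter 15 cents / expert 3 cents, beginner SNR
  18 dB / expert 35 dB, with beginner jitter shrinking over blocks
  (feedback group faster: ×0.75/0.60/0.50 vs ×0.85/0.75/0.65); baseline
  band densities theta 8, alpha 10, beta 5, gamma 2 µV²/Hz with
  beginner frontal beta ×2.9 and gamma ×1.16, beginner frontal gamma
  ×0.7 after baseline, mild posterior/temporal gamma decreases in all
  groups, an expert temporal beta rise; Poisson request counts with the
  feedback group's reference-video mean set above the no-feedback
  group's. Audio trials default to 2 s and EEG trials to 30 s — compute-
  friendly stand-ins for real trial lengths.

What it does **not** emulate: bowed-string physics (stick-slip,
transients), room acoustics, EEG artifacts (blinks, EMG), the 1/f
background spectrum, or trial-to-trial band-power variability beyond
estimator noise. The last point matters for interpretation: on real
EEG, where band power fluctuates tens of percent across trials, the
outlier mask and the ERD estimates will both be noisier than the clean
synthetic recovery shown by the tests. Passing tests demonstrate that
the *pipeline* recovers what was programmed; they are not evidence about
effect sizes in real data.

## Numerical choices and degenerate inputs

- The difference function is clamped at zero before normalisation
  (rounding can drive it slightly negative), and frames whose cumulative
  sum is zero (silence) are treated as unvoiced with aperiodicity 1.
- Parabolic interpolation is skipped at lag-range boundaries and when
  the curvature is non-positive.
- Zero-variance components under z-scoring raise an error naming the
  component; a cohort of identical trials is only representable with
  `scale = "center"` (composite 0 everywhere).
- A zero baseline mean makes percent change undefined and errors.
- MAD = 0 in the outlier filter warns and flags nothing.
- Wilcoxon signed-rank drops zero differences (noted in the result);
  all-zero differences short-circuit to p = 1. A paired t on constant
  nonzero differences reports p = 0 with an infinite statistic rather
  than erroring. A Friedman test on rows with zero spread
  short-circuits to statistic 0, p = 1.
- All floating-point table outputs are written with 6 significant
  digits; tests compare numerically with tolerances, never strings.

## Problem sizes used by the test-suite and acceptance runs

Pipeline-level tests use a 6-subject cohort (2 per group), 1 s audio
trials, 8 s EEG trials and a 7 ms analysis hop; the ERD recovery run
uses 30 s EEG trials (150 s per block) from 3 subjects; the Yin-oracle
comparison uses six tone frequencies spanning 196–660 Hz with 1–8
harmonics; calibration simulations use 1000–2000 replicates. These are
the package's own choices of desk-scale problem sizes; all of them are
parameters, and larger runs only change runtime.

## Known limitations

- WAV ingestion is deliberately minimal: mono integer PCM 16/24-bit;
  multi-channel files are rejected, not downmixed.
- EEG ingestion is CSV-only (one file per trial, or a continuous file
  plus an events table); EDF/BDF is out of scope.
- The composite is only defined relative to a cohort; single-trial
  scoring requires a reference cohort to standardise against.
- Information gain with MDL can legitimately return 0 for weakly
  informative features at small n (the coding cost is unbeatable);
  that is the referenced evaluators' behaviour, not a defect.
- ERD with the test-interval denominator is asymmetric: a halving of
  power maps to +100%, a doubling to −50%. Consumers comparing
  magnitudes across sign should use the baseline-denominator variant.
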