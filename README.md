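# bowlearn

Quantitative tracking of how people learn to produce a good violin tone,
from two synchronized data streams: the **sound** of each bowing trial and
the **EEG** recorded while playing. The package is aimed at researchers in
music-performance science and motor learning who want objective,
per-trial measures of sound quality, a composite learning score, EEG
band-power biomarkers of the same process, and the statistics to compare
learner groups — without hand-assembling a DSP + EEG + stats toolchain.

The experimental design it serves: subjects bow a sustained open A string
(440 Hz) for 20 trials split into four blocks of five — a **baseline**
block (trials 1–5, no help available) and early/middle/late learning
blocks — while three groups are compared: experts (EG), beginners with a
sound-quality visual feedback display (BF), and beginners without it
(BNF).

## What it computes

**Audio descriptors (Yin).** Each trial's mono 44.1 kHz recording is
analysed with the Yin fundamental-frequency estimator (33 ms windows,
0.7 ms hop): cumulative-mean-normalised difference function, absolute
threshold dip selection, parabolic interpolation. Per frame *i* this
yields power *p&#7522;*, pitch *f0&#7522;* in cents re 440 Hz, and aperiodicity
(aperiodic power / total power). Per trial:

- dynamic instability = population SD of *p&#7522;*,
- pitch instability = population SD of *f0&#7522;* (voiced frames),
- aperiodicity = mean frame aperiodicity,

and the **Sound instability** composite: each descriptor standardized
across the cohort, then averaged per trial (with or without
aperiodicity). Learning is summarised as the block percent change
`100 · (mean(baseline) − mean(block)) / |mean(baseline)|` (positive =
improvement), and the per-trial feedback screen content is available as a
JSON payload.

**EEG biomarkers.** 14-channel, 128 Hz recordings (AF3 F7 F3 FC5 T7 P7 O1
O2 P8 T8 FC6 F4 F8 AF4) are reduced to Welch PSDs (2 s windows, 50%
overlap, Hann), mean band densities for theta (4–8 Hz), alpha (8–13 Hz),
beta (13–24 Hz) and gamma (30–50 Hz), averaged over 13 named electrode
clusters. Outlier trials are masked by modified Z-score
(`M = 0.6745 (x − x̃)/MAD`, |M| > 3.5), and learning blocks are compared
to baseline as ERD/ERS:

```
ERD/ERS (%) = 100 · (baselineBandPower − testBandPower) / testBandPower
```

(positive = desynchronization).

**Statistics.** Information-gain feature ranking (Fayyad–Irani MDL
discretization, in bits) of audio and cluster-band features on the
baseline block; Shapiro–Wilk normality gate; Wilcoxon rank-sum /
signed-rank, Friedman, Mann-Whitney and paired-t comparisons with
Bonferroni control (the cluster × band × block ERD family of 13 × 4 × 3 =
156 tests uses the per-test threshold 0.05/156 ≈ 0.00032); per-band
Pearson correlation between trial-averaged frontal band power and Sound
instability.

**Synthetic cohort.** A deterministic generator produces the whole study
layout — harmonic bowing audio with programmed pitch/power jitter and
noise, EEG as band-limited noise hitting programmed per-region band
densities with per-block multipliers, behavioural request counts — so
every stage is testable end-to-end from a seed.

## Worked example

```r
library(bowlearn)

dir <- file.path(tempdir(), "demo")
spec <- synth_cohort_spec(group_sizes = c(EG = 2, BF = 2, BNF = 2),
                          audio = list(duration_s = 1),
                          eeg = list(duration_s = 8))
manifest <- synth_cohort(spec, dir, seed = 42)
report <- run_analysis(manifest, hop_s = 0.007, verbose = FALSE)
print(report)
#> <bowlearn_report> 6 subjects, 120 trials (config 49e89389)
#>   descriptors: 120 rows; band power: 6240 rows; ERD: 936 rows
#>   top audio feature by IG: aperiodicity (0.918 bits)
#>   top EEG feature by IG:   left_frontal_beta (0.943 bits)
#>   statistical tests: 19 (+468 ERD cells)

subset(report$percent_change, group == "BF")
#>  group  block percent_change
#>     BF  early       65.40160
#>     BF middle       84.64962
#>     BF   late       88.90180

subset(report$correlation, band == "gamma")
#>   band        r r_squared     p_value adjusted_alpha significant n_trials
#>  gamma 0.665627 0.4430593 0.001358685         0.0125        TRUE       20
```

Reading this: the feedback-group beginners' Sound instability dropped by
65–89% relative to their baseline block (positive = improvement), the
audio descriptors separate beginners from experts at about 0.9 bits of
information gain on the baseline block, and trial-averaged frontal gamma
band power correlates with Sound instability across the session
(R² = 0.44 here, significant at the Bonferroni-adjusted 0.0125 level).
`write_report(report, out_dir)` writes the full TSV set plus a JSON
provenance block. A command-line wrapper with `synth | audio | eeg |
report` subcommands is installed at `inst/cli/bowlearn.R`.

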