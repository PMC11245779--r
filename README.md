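# cyclokin

Hip–knee cyclogram coordination metrics and one-dimensional statistical
parametric mapping (SPM) for clinical gait analysis.

## What it is for

Gait deficits in Parkinson's disease (PD) and other movement disorders show
up not just in how far each joint moves, but in how the hip and knee move
*together* across the gait cycle, and in how that coordination adapts to
walking speed and medication.  `cyclokin` is an R implementation of the
full analysis chain used in case-control cyclogram studies, for
biomechanists and clinical movement scientists:

- **Cycle preparation** — segment sagittal hip/knee angle time series at
  initial-contact events, linearly time-normalize each cycle to a 101-point
  percent-gait-cycle grid, mean-center per joint (cyclogram centroid at the
  origin), apply configurable QC.
- **Cyclogram metrics** — per-trial range of motion (ROM, degrees); the
  angular coefficient of correspondence
  `ACC = mean_i sqrt( (mean_j cos θ_ij)² + (mean_j sin θ_ij)² )`,
  the per-frame circular resultant of cyclogram segment directions θ across
  cycles (1 = perfectly repeatable coordination); the sum of squared
  distances `SSD = sqrt( (1/N) Σ_i ‖p_i^A − p_i^B‖² )` between cyclogram
  shapes (RMS convention, degrees); minimum/maximum cyclogram points
  (extrema of combined centered flexion `hip + knee`, late stance ≈ 46% and
  mid-swing ≈ 76% of the cycle); and between-speed adaptation ratios of
  extremal-point magnitudes.
- **1D SPM** — node-wise two-sample and paired t continua; global FWHM from
  normalized residual gradients; random-field-theory threshold solving
  `P(T>u) + resels·√(4 ln 2)/(2π)·(1+u²/ν)^{−(ν−1)/2} = α/2`; cluster
  extents in % gait cycle with RFT p-values; a permutation twin (max-|t|
  and max-cluster-extent nulls); min–max amplitude normalization for
  temporal (timing) comparisons.
- **Cohort statistics** — Shapiro-Wilk-gated t / Mann-Whitney tests,
  repeated-measures ANOVA / Friedman with Bonferroni / Conover–Iman post
  hocs, Wilcoxon signed-rank (exact for small n), Pearson chi-squared,
  single-pass z-score / Tukey-fence outlier removal.
- **Synthetic gait generator** — normative Fourier-series hip/knee
  templates at three walking speeds, with per-speed group effects (ROM
  scaling, swing-confined hip-peak delay, swing knee deficit) and
  cycle-to-cycle variability, so the entire pipeline runs with no data
  downloads.

## Worked example

```r
library(cyclokin)

coh <- simulate_cohort(cohort_config(n_per_group = 12, n_off = 0,
  groups = c("control", "pd_on"), speeds = c("slow", "preferred", "fast"),
  seed = 42))
m <- cohort_metrics(coh$trials)
head(m, 4)
#>   subject_id   group     speed rom_hip rom_knee  acc  ssd min_pct max_pct
#> 1        C01 control      slow   30.36    54.37 0.98 1.61    45.4    76.8
#> 2        C01 control preferred   36.89    58.51 0.98 3.31    45.6    76.2
#> 3        C01 control      fast   43.77    62.20 0.97 6.20    47.0    77.4
#> 4        C02 control      slow   31.77    64.75 0.97 3.49    45.0    76.0
```

Each row is one trial: hip/knee ROM in degrees, ACC near 1 (regular
coordination), within-trial SSD in degrees, and the minimum/maximum
cyclogram points in late stance (~46%) and mid-swing (~76%).  The PD arm is
simulated with reduced knee ROM and a delayed hip-flexion peak; the group
difference is recovered by the scalar tests and located by SPM:

```r
compare_two_groups(m$rom_knee[m$group == "control" & m$speed == "preferred"],
                   m$rom_knee[m$group == "pd_on"   & m$speed == "preferred"])
#> two-sample t: statistic = 5.068, p = 4.467e-05  [gate: normal]

YA <- subject_mean_curves(coh$trials, "control", "preferred", "knee")
YB <- subject_mean_curves(coh$trials, "pd_on",   "preferred", "knee")
spm_ttest2(YA, YB)
#> SPM{t} ttest2 (rft)
#>   n = 12 vs 12, df = 22, FWHM = 13.38, resels = 7.47
#>   alpha = 0.05 (2-tailed), t* = 3.396
#>   cluster 1: 0.0% - 13.9% of gait cycle, p = 0.0001
#>   cluster 2: 27.4% - 55.6% of gait cycle, p = 0.0000
#>   cluster 3: 67.3% - 86.3% of gait cycle, p = 0.0000
#>   cluster 4: 96.2% - 100.0% of gait cycle, p = 0.0005
```

The swing-phase cluster (67–86% of the cycle) is where the reduced knee
flexion of the PD arm is largest — the part of the cycle where such
deficits are reported clinically.  Speed adaptation is summarized by
extremal-point magnitude ratios; e.g. the control fast-vs-slow
ratio-of-ratios median here is 1.142, i.e. a 14% difference
(`ratio_percent_difference(1.142)`).

The end-to-end pipeline (simulate → QC → prep → metrics → SPM → stats →
report files) is one call:

```r
run_pipeline(run_config(simulate = cohort_config(seed = 1), out_dir = "results"))
```

and a thin CLI over the same functions ships in `inst/cli/cyclokin.R`
(`simulate` and `all` subcommands).

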