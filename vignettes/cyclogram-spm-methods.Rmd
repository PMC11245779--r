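---
title: "Hip–knee cyclogram coordination metrics and 1D SPM: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip–knee cyclogram coordination metrics and 1D SPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Walking is a cyclical, multi-joint activity.  In movement disorders such as
Parkinson's disease (PD), the question is not only *how much* each joint
moves, but *how the joints move together* — inter-joint coordination — and
how that coordination adapts to walking speed and to dopaminergic
medication.  `cyclokin` implements a complete desk-scale analysis chain for
sagittal hip–knee coordination:

1. a **synthetic gait generator** producing event-annotated hip/knee angle
   time series for cohorts (controls, PD on medication, a paired
   off-medication subset) at three walking speeds;
2. **cycle preparation**: segmentation at initial contacts, linear time
   normalization to a fixed percent-gait-cycle grid, mean-centering, QC;
3. **cyclogram metrics**: ROM, the angular coefficient of correspondence
   (ACC), the sum of squared distances (SSD), extremal cyclogram points and
   between-speed adaptation ratios;
4. **1D statistical parametric mapping (SPM)**: two-sample and paired t
   continua with random-field-theory (RFT) thresholds, cluster inference
   and a permutation twin;
5. **scalar cohort statistics**: normality-gated two-group and
   three-condition comparisons with post hocs, paired signed-rank tests,
   chi-squared tests.

Everything runs from code; no external recordings are needed.

## Cycle preparation

A gait cycle is the half-open sample slice between consecutive
initial-contact events.  Cycles are linearly interpolated onto 101 equally
spaced points spanning 0–100% of the cycle (0 and 100% map exactly to the
first and last raw samples).  The 101-point grid is the field convention
for gait curves and doubles as the SPM continuum.  Mean-centering subtracts
each joint's own cycle mean, which places the cyclogram centroid at the
origin; all cyclogram metrics are translation-invariant as a result.

The exclusion criteria used on real clinical recordings are study-specific,
so QC is a pluggable hook.  The defaults reject physiologically impossible
angles (|angle| > 120°) and near-constant trials (any cycle ROM < 5°);
both thresholds are configurable in `qc_rules()`.

## Cyclogram metrics

**ROM** is `max − min` of a joint's angle over a cycle, averaged over the
cycles of a trial (degrees).

**ACC** quantifies how repeatable the *direction* of cyclogram motion is
across cycles.  For every frame (pair of adjacent grid points), each
cycle's segment `(Δhip, Δknee)` is reduced to its direction cosines; across
the M cycles of a trial the circular mean resultant length of these unit
vectors is computed per frame, and ACC is the mean over frames.  Identical
cycles give exactly 1; independent random directions give values near
`sqrt(pi) / (2 sqrt(M))`.  Because the exact aggregation behind the
published scalar is not specified to the digit anywhere we could verify, a
consecutive-pair variant (mean of two-cycle resultants over consecutive
cycle pairs) is available via `acc(..., variant = "consecutive")`; the
all-cycle resultant is the default.  Zero-length segments (possible only in
pathological flat data) inherit the previous frame's direction.  Per-frame
resultants within 1e-12 of unity are snapped to exactly 1 so that the
perfect-consistency identity is exact in floating point.

**SSD** measures shape discrepancy between two cyclograms as the
root-mean-square Euclidean distance between corresponding grid points.
The RMS convention keeps SSD commensurate with degrees — typical healthy
within-trial values sit in the 2–6° range, matching the magnitudes reported
for this family of metrics in the clinical literature — and this convention
must be kept in mind when comparing absolute SSD values across software;
the raw sum of squares is available via `convention = "sum"`.  Trial-level
SSD averages consecutive cycle pairs (within-trial variability);
condition-level SSD can also compare two average cyclograms directly.
Both usages are exposed because summary tables in the clinical literature
are ambiguous about which is reported; within-trial is the package default.

**Extremal points** are the minimum and maximum of the combined centered
flexion `hip + knee` over the grid.  The minimum falls in late stance —
weight transfer onto the forefoot just before toe-off — and the maximum at
peak combined flexion in mid-swing.  On the package's normative templates
the minimum sits at 45% and the maximum at 76% of the gait cycle, inside
the 46 ± 2% and 76 ± 1% windows reported for healthy and Parkinsonian gait
alike.  Ties are broken toward the earliest percent; constant combined
flexion raises an error rather than returning an arbitrary point.

**Speed-adaptation ratios** divide the extremal-point magnitudes (distance
from the centroid, degrees) of a faster condition by those of a slower one;
the quotient `ratio_min / ratio_max` summarizes whether adaptation to speed
happens early (late-stance propulsion, high values) or late (mid-swing
correction, low values) in the cycle.  A ratio r maps to a percent
difference as `(r − 1) × 100`.

## The synthetic generator

The generator's purpose is to emulate the statistical structure of a
case-control walking study closely enough that the full pipeline — and its
expected clinical pattern — can be exercised end to end.

**Templates.**  Normative sagittal hip and knee curves are built from
keypoints of standard adult gait (hip ~30° flexion at initial contact, peak
extension ~−10° in late stance, ~31° peak flexion in late swing; knee with
a loading-response bump and a ~65° swing peak), interpolated periodically
and projected onto an 8-harmonic Fourier basis.  The Fourier projection
guarantees exact periodicity and smooth derivatives.  Speed is encoded by
per-joint amplitude scales (hip ROM 46/41/33°, knee ROM 64/62/59° at
fast/preferred/slow — the within-control speed gradient of group medians),
toe-off timing (58/60/62%) and nominal cycle duration (0.95/1.10/1.40 s).

**Effects.**  Group contrasts are expressed per speed as multiplicative ROM
scales about the curve mean (so a scale of k changes measured ROM by
exactly k), a swing-confined hip-peak delay, and an optional swing-confined
knee deficit:

* PD ROM scales default to the ratios of group medians to control medians
  (e.g. knee 54/62 ≈ 0.87 at preferred speed), so simulated group medians
  track the clinical pattern by construction.
* The hip-peak delay is a monotone piecewise-linear time warp acting only on
  the swing portion of the cycle, fixed at toe-off and 100%; it moves the
  swing-phase hip-flexion argmax by exactly the requested percent while
  leaving stance kinematics and the events untouched.  PD groups default to
  a 4% delay, reproducing the delayed peak hip flexion observed in PD.
* The knee swing deficit is a raised-cosine reduction supported on 60–90%
  of the cycle (peak at 75%).  It is off by default; the effect-recovery
  analyses use a 3° peak, a magnitude chosen once as clinically plausible
  (roughly 5% of the knee swing peak).

**Variability.**  Per cycle: log-normal duration jitter (3% SD),
multiplicative amplitude jitter per joint (6% SD), timing jitter (1.5% of
the cycle, SD), plus 0.1° additive measurement noise per sample.  These
four SDs were calibrated once so that default trials land inside the
clinically reported ranges of the regularity metrics (ACC medians
0.95–0.99, SSD medians ≈ 3–5°); no published per-cycle variability values
exist to match directly, so this is a realism calibration, not a
reproduction.  Between subjects, each subject carries log-normal hip and
knee ROM multipliers (7% SD) shared across speeds and across the paired
on/off sessions, which is what makes paired tests meaningful.

**Determinism.**  One root seed; per-subject and per-trial child seeds are
derived by hashing (group, subject, speed), so any subset of a cohort is
reproducible independently of generation order.  The off-medication group
reuses the subject identities and baseline multipliers of the first
`n_off` on-medication PD subjects.

**What the generator does not emulate.**  Marker-level artifacts, soft
tissue and filtering effects, asymmetry between body sides, freezing
episodes, dual-task effects, non-sagittal planes, and any correlation
between clinical severity and kinematics.  Passing the recovery analyses
therefore shows that the pipeline detects the modeled effect structure at
the study's sample sizes — not that it would detect every real-world
manifestation of PD gait.

## 1D SPM

Node-wise t statistics (pooled-variance two-sample, or paired one-sample on
differences) form a t continuum over the 101-node grid.  Smoothness is
estimated globally from the pooled residuals: per node, the ratio of
summed squared gradients to summed squares gives a local reciprocal FWHM;
the global FWHM is the reciprocal of the mean reciprocal.  A single global
scalar is standard 1D practice and is stable at the n ≤ 30 of typical gait
studies (the estimator recovers known smoothness within a few percent in
the package's own simulations).

The critical threshold solves the expected-Euler-characteristic equation
for a smooth t field with `(n_nodes − 1)/FWHM` resels:
`P(T > u) + resels · sqrt(4 ln 2)/(2π) · (1 + u²/ν)^{−(ν−1)/2} = α/2`
(two-tailed by default, matching common SPM practice; `tails = 1` is
available).  As FWHM → ∞ this reduces to the univariate critical t.  With
ν = 1 the EC density does not decay and no finite threshold exists; the
package raises an informative error (this is why paired SPM needs at least
3 pairs).

Supra-threshold cluster endpoints are interpolated between nodes and
reported in percent of the gait cycle.  Cluster p-values take the smaller
of (i) the 1D cluster-extent approximation (Poisson clumping with the
squared-extent tail) and (ii) the height-based probability of the cluster
peak; the minimum guarantees reported p ≤ α for any cluster that crosses
the threshold.  Under null simulations at the study's group sizes the
family-wise false-positive rate is within ±0.02 of the nominal 0.05, for
both the RFT and the permutation routes (the package's acceptance suite
recomputes this with 1000 replicates).

The permutation twin thresholds at the `1 − α` quantile of the permutation
distribution of the continuum maximum of |t| (group-label permutations, or
sign flips of paired differences), always including the observed labelling,
and derives cluster p-values from the permutation null of the maximum
cluster extent.  It serves both as a nonparametric alternative and as an
internal oracle for the RFT machinery.

**Temporally aligned vs spatially normalized.**  SPM on time-normalized
angle curves compares amplitudes ("spatial comparison").  To compare
*timing*, each joint's curve is first amplitude-normalized; the package
adopts per-cycle per-joint min–max scaling to [0, 1] because it removes
amplitude and offset differences exactly while leaving timing untouched,
which is what a temporal comparison requires.  A z-score variant is
available (`method = "zscore"`); the choice matters little for smooth
unimodal gait curves but is exposed because the normalization recipe is
not standardized across studies.

## Scalar statistics

All scalar tests are gated on Shapiro-Wilk normality at p < 0.05, applied
per sample; when samples disagree, the nonparametric branch wins
(conservative).  Outlier removal is single-pass, using the statistics of
the original sample: |z| > 3 for normal samples, Tukey fences
(type-7 quartiles, 1.5 × IQR) otherwise; whether removal is applied per
group-condition cell or globally is left to the caller (the pipeline works
per cell).  Three-condition comparisons use repeated-measures ANOVA with
Bonferroni-adjusted paired-t post hocs on the normal branch and Friedman
with Conover–Iman post hocs (rank-sum t statistics on within-subject
ranks, df (n−1)(k−1), Bonferroni-adjusted) otherwise; post hocs are
reported only when the omnibus test is significant.  Paired on/off
comparisons use the Wilcoxon signed-rank test with the exact null for
small samples (ties permitting), dropping zero differences; if all
differences are zero the report carries p = 1 by convention.  Chi-squared
tests are Pearson's without continuity correction.

## Numerical choices and degenerate inputs

* Interpolation is linear everywhere cycles are resampled; templates are
  refined through a periodic spline before per-cycle evaluation so that
  the zero-noise round trip (generate → segment → normalize) stays within
  0.1° at 200 Hz.
* Extremal-point ties break toward the earliest percent of the cycle.
* Degenerate inputs raise errors rather than returning arbitrary numbers:
  constant combined flexion (extremal points), all-zero segments (ACC),
  zero-ROM joints (amplitude normalization), zero-variance sample pairs
  (two-group tests).
* Undefined t nodes (zero variance at a node) never cross the threshold.
* Trial-level extremal locations are averaged on the circle (the gait
  cycle is periodic), though with the default timing jitter the locations
  never approach the wrap-around.

## Problem sizes used in the validation suite

The packaged analyses run at the emulated study's own scale: 29 subjects
per arm (8 in the paired off-medication subset), three speeds, five cycles
per trial at 200 Hz.  Calibration suites use 1000 null replicates for the
family-wise error of continuum inference and 100 replicates for the
effect-recovery analyses; these sizes give Monte-Carlo standard errors
comfortably inside the tolerance bands they are checked against.

## Known limitations

* RFT cluster p-values use the classical 1D extent approximation; they are
  accurate near the threshold but approximate for very wide clusters (the
  permutation route is exact up to Monte-Carlo error and is the
  recommended cross-check).
* ACC and SSD conventions vary across the literature; absolute values are
  only comparable across software when the aggregation (all-cycle
  resultant vs consecutive pairs) and normalization (RMS vs raw sum) match.
* The generator produces one leg's kinematics; asymmetry metrics are out
  of scope.
* Gait events are inputs, not outputs: the package starts at joint-angle
  time series with annotated initial contacts and does not detect events.
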