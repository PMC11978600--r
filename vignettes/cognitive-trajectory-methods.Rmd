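---
title: "Clustering cognitive aging trajectories: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering cognitive aging trajectories: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cogtraj implements a complete analysis pipeline for multi-wave longitudinal
cognitive-aging cohorts: a synthetic cohort generator, quality control,
autoencoder summarization of a large cognitive battery, temporal k-means
clustering of trajectories under multivariate dynamic time warping (DTW),
steady-state visual evoked potential (SSVEP) power extraction from EEG, and
statistical validation of the resulting groups. This vignette explains the
models behind each stage, the parameters that matter, and the choices made
where the design was genuinely open.

## The synthetic cohort

Real cohort data of this kind are governed by ethics restrictions, so the
package ships a generator that emulates the *statistical structure* such a
study assumes, making every downstream stage testable without any download.

**Waves and visits.** Three overlapping assessment waves of 211, 503, and
113 participants with overlaps 136 (waves 1∩2), 99 (wave 3 from wave 2),
and 10 (wave 3 from wave-1-only members) give 582 unique participants, each
with one to three visits at ages 57–68. `visit_index` is the wave number,
so the per-visit coverage filter (below) counts against wave sizes. Visit
ages are drawn uniformly inside per-wave windows (57–59, 61–67, 66–68),
with a small minimum gap enforcing strictly increasing ages; the windows
are treated as authoritative and may not overlap within a participant.

**Latent trajectories.** Each participant belongs to one of four
archetypes — low-stable, high-upper, low-declining, high-lower — drawn with
mixing weights proportional to 69/256/65/136. Cognition is a 2-dimensional
latent process, linear in age: a *composite level* axis (with archetype
baselines −1.4 / +1.7 / −1.6 / +1.3 z-units and slopes −0.010 / +0.005 /
−0.100 / −0.040 per year) and a *domain profile* axis (±3.0) capturing
which cognitive domains dominate the battery. The linear form is the
simplest consistent with "stable or declining" trajectories; curvature
would be a configuration extension.

The four means form a near-equidistant configuration on purpose: the level
axis separates the high pair from the low pair, the profile axis separates
the two archetypes within each pair. An earlier design with small
within-pair separations produced groups that a clustering algorithm could
recover perfectly yet a cluster-validity index would merge into two
super-groups; the equidistant geometry realizes four *detectable* groups,
which is the structure the analysis is premised on. Within-archetype
variation (random intercept SD 0.25, visit noise SD 0.10 per latent
dimension) stays small against every pairwise separation, and the
per-score observation noise (SD 0.3 on the z-scale, i.e. test reliability
near 0.9) is far below the between-archetype gaps — the regime in which
archetype recovery is a meaningful end-to-end check.

**Observed scores.** 77 score names follow a standard neuropsychological
battery (70 computerized subtests plus MMSE, ACE, SDMT, Trail-Making A/B,
word pairs, retention). Score *j* is `dir_j · (w_j · z) + ε`: every test
loads positively on the composite level (weights U(0.6, 1)) and with a
signed weight on the profile axis (U(−0.9, 0.9)); latency/error-type
scores are flagged `higher_is_worse` and enter with `dir_j = −1`, so a
declining participant's trail-making time *rises* across visits.

**MRI.** 35 regional volumes with order-of-magnitude realistic baselines
scale with a per-participant intracranial volume (ICV ~ N(1.5·10⁶,
1.2·10⁵ mm³), constant over visits). Ventricle/CSF regions expand with age
(+2%/yr), neocortical regions atrophy (−0.6%/yr, an extra −0.4%/yr in the
declining archetypes), subcortical and global regions shrink mildly. The
low-performing archetypes carry a 1.5% neocortical level deficit — the
signal available to the MRI classifier, sized so that the cross-validated
AUC lands near 0.9 rather than saturating.

**EEG.** Each available recording is 64 channels at 2 kHz: 1/f-shaped
background noise (unit-variance pink noise scaled to 6 µV) plus sinusoids
at the 8 Hz and 36 Hz stimulation frequencies. Parietal and temporal
channels carry the full archetype amplitude modulation (low-stable lowest
evoked power); other regions receive a damped group effect. Only ~66% of
participants have EEG, at most two visits each; ~36% have MRI — emulating
the participant counts of the motivating study design (526 cognitive / 190
MRI / 349 EEG out of 582). Participant counts are prioritized over scan
counts, which cannot be matched simultaneously with the cohort's visit
distribution.

**Risk factors.** Binary factors (alcohol, smoking, illness, familial
hypertension/diabetes/depression/dementia) and father's education use
per-archetype prevalences taken from the printed group tables of the
motivating study; school years and IQ use the printed means and SDs.
Father's occupation (20 categories) and BMI have no printed per-group
statistics and use synthetic defaults with a socioeconomic tilt; they are
documented as synthetic. Factors are independent given the archetype —
only marginals are reported, so no cross-factor correlation is modeled.

**What the generator does *not* emulate:** item-level response processes,
informative dropout (missingness is completely at random), practice
effects, scanner/batch effects, EEG artifacts, or nonlinear trajectories.
Passing tests therefore demonstrate correctness of the *methods* under the
assumed structure, not performance on real cohort data.

## Quality control

Rules are applied in a fixed order, with one report per rule:

1. **Coverage** — a test is kept only if every visit at which it was
   administered has ≥ 75 non-missing participants.
2. **Constancy** — pooling visits, a test is removed if the values between
   its 5th and 95th percentiles are all equal. "Constant within the band"
   is operationalized as a single distinct value among the in-band
   observations.
3. **IQR outliers** — values outside [Q1 − 5·IQR, Q3 + 5·IQR] are removed,
   per variable, pooling visits (a per-visit variant is available by
   flag). Quantiles use linear interpolation (R type 7). With fewer than
   four finite values no flagging occurs, with a warning.
4. **Participant drop** — participants without a single usable cognitive
   observation are excluded.

Nothing is imputed during preprocessing; missingness is carried forward
explicitly. MRI volumes are divided by the participant's ICV (dimensionless
proportions; participants with missing or non-positive ICV are excluded
and logged), and MRI/EEG tables are then restricted to the cognitive
analysis set.

## Cognitive summary: a masked autoencoder

The 77 standardized scores per participant-visit are reduced with an
autoencoder of two fully connected layers per side: input → 0.8·input →
latent, mirrored decoder, tanh on the hidden layers, linear latent and
output. The loss is mean squared reconstruction error **over observed
entries only**; missing inputs enter the forward pass as zeros (the
variable mean on the standardized scale) but contribute neither loss nor
gradient, which avoids biasing reconstruction toward imputed values.
Training is full-batch Adam (learning rate 0.01, 300 epochs by default),
deterministic given the seed. Visits are pooled as independent rows.

Two oracles pin the optimizer down: with linear activations the final
reconstruction error must match the truncated-SVD optimum within 5% on
random low-rank matrices, and training error must be non-increasing in the
latent size.

The latent fraction is chosen by k-fold cross-validation with a
one-standard-error rule (smallest fraction within one SE of the minimum
mean held-out error). On the default synthetic cohort the curve is
essentially flat from small fractions on — unsurprising, since the
generative latent space is 2-dimensional — so the one-SE rule picks a
small fraction; the pipeline nevertheless runs at the conventional 65%
(50 latent features for 77 inputs), which the curve shows to be no worse,
and which exercises the same latent budget a richer battery would need.

## Trajectory clustering

**Distance.** Dependent multivariate DTW: one monotone, boundary-anchored,
continuity-constrained alignment path shared by all feature dimensions;
local cost is the squared Euclidean distance between aligned latent
vectors; the distance is the square root of the accumulated cost. With at
most three visits no Sakoe-Chiba band is needed. Ages are not used inside
the distance — alignment is ordinal over visits, so trajectories of
different lengths are compared without imputation. Symmetry and
non-negativity hold; the triangle inequality is not guaranteed (standard
for DTW) and is not relied upon. An exhaustive path-enumeration oracle
verifies the dynamic program on all short sequences.

**Centroids.** DTW barycenter averaging (DBA) with centroid length L = 3
(the maximum visit count): align all members to the current centroid,
replace each centroid point by the mean of member points mapped to it; the
sum of squared DTW distances is non-increasing across sweeps.
Initialization is the member closest to the medoid, linearly resampled to
length 3; backtracking ties prefer the diagonal step, deterministically.

**k-means.** Distance-weighted (k-means++-style) seeding on DTW distances,
alternating nearest-centroid assignment (ties to the lowest index) and DBA
updates until assignments stabilize; empty clusters are repaired by
reassigning the farthest point; 10 restarts, best inertia kept; fully
deterministic given the seed. The inner loops (accumulated-cost matrix,
path backtracking, barycenter sweep) are implemented in C++, as the
field's time-series clustering packages do.

**Model selection.** k is chosen from 2–8 by minimizing the
Davies-Bouldin index `DB = (1/k) Σᵢ maxⱼ≠ᵢ (Sᵢ+Sⱼ)/Mᵢⱼ`, with Sᵢ the mean
member-to-centroid DTW distance and Mᵢⱼ the centroid separation; ties go
to the smaller k.

**Naming.** With k = 4, clusters are split into low/high pairs by mean
composite cognitive score (direction-corrected mean of standardized
scores); within each pair the cluster with the more negative mean
within-participant slope is "declining" (low pair) or "lower" (high pair).
For k ≠ 4, rank-based names are emitted instead.

## EEG power

Welch's method with 2-second periodic-Hann segments and 50% overlap (0.5 Hz
resolution, so 8 and 36 Hz fall exactly on bins), one-sided
Parseval-consistent scaling — the integral of the density equals the
signal variance, checked to 5% on stationary noise. Spectra are multiplied
by frequency to compensate the 1/f background, the peak within ±0.5 Hz of
each stimulation frequency is read off per channel, channels are averaged
within five scalp regions (temporal, frontal, central, parietal,
occipital; a fixed disjoint map over the 64-channel montage with midline
and fronto-central rows assigned to central), and each region×band is
log-transformed and z-scored across all participant-visits (pooled across
visits; a per-visit flag exists). Every usable recording yields exactly
10 features. Artifact rejection, re-referencing, and source analysis are
out of scope; recordings are assumed clean.

## Group statistics

Continuous variables: Wilcoxon rank-sum (two groups; exact enumeration for
combined n ≤ 10 without ties, otherwise the tie-corrected normal
approximation without continuity correction, which makes the two-group
Kruskal-Wallis test agree exactly) or Kruskal-Wallis (four groups).
Categorical variables: chi-square without continuity correction (four
groups, or merged multi-category), Fisher's exact test
(probability-mass two-sided rule) for merged binary factors. All tests are
two-sided at p < 0.05 with no multiple-testing correction by default
(Benjamini-Hochberg by flag) — matching a significance-threshold-only
analysis convention. Each test's type-I error is calibrated to 0.05 ±
0.015 over 1000 null simulations.

Group trajectory summaries report mean, SD, n, and 1.96·SD/√n per
(group, visit) — the 95% CI of the mean. The figure-caption phrase that
motivated this ("confidence interval for the population standard
deviation") is internally inconsistent; the CI-of-the-mean reading is
implemented, with mean ± SD available by computing it from the same
payload.

## Classification

The four clusters merge into high ({high_upper, high_lower}) and low
({low_stable, low_declining}) classes. Per modality, the earliest visit
with any data supplies the features (missing features mean-imputed with a
logged count), and a ridge-penalized logistic regression (λ = 10⁻⁴ on
standardized features, handling separable data; zero-variance features
guarded out) is scored by ROC/AUC. AUC is computed by the Mann-Whitney
rank statistic with half credit for ties and equals the trapezoidal area
under the stored curve to 10⁻¹².

In-sample AUC is the default — a choice consistent with reporting nearly
perfect cognitive-battery AUCs on the very features that defined the
groups — but it saturates for strong modalities, so the k-fold
cross-validated variant is provided and is what the acceptance checks use
to resolve the modality *ordering* (cognitive > MRI > EEG under the
generator's configured effect sizes). A univariate scan fits one
single-feature logistic model per cognitive score, direction-corrects AUC
to ≥ 0.5, and ranks the scores.

The printed real-data AUCs of the motivating study (0.98 cognitive, 0.89
MRI) require the restricted cohort and are not reproduction targets; the
synthetic defaults were sized to land in the same regime.

## Problem sizes and numerical choices

The default cohort (582 participants, ~830 visits) runs the full pipeline
in a few minutes on one CPU; the multi-seed stability analyses use 20
seeds with 5 k-means restarts and 200 training epochs, which leaves the
selected k and recovery ARI unchanged relative to the full settings.
Davies-Bouldin with coincident centroids returns infinity with a warning;
all-identical trajectories collapse to a single effective cluster with a
warning; degenerate QC inputs (IQR on < 4 values, zero-SD variables
reaching standardization) error or warn explicitly rather than silently
proceeding.

## Known limitations

Missingness is MCAR only; trajectories are linear in age; risk factors are
conditionally independent; the autoencoder is a fixed two-layer family
(no denoising/variational variants); DTW uses the squared-Euclidean local
cost with the symmetric step pattern only; no artifact model for EEG.
These bounds are deliberate: each matches an explicit scope decision of
the analysis design.
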