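# cogtraj

Cognitive aging unfolds along distinct trajectories: some people hold a
stable high level into late midlife, others start lower or decline early.
Detecting those phenotypes from longitudinal data — and asking which brain
measures and life-course risk factors travel with them — requires methods
that tolerate variable visit counts, heavy multivariate batteries, and
missing modalities. **cogtraj** is an R package plus analysis workflow for
exactly that setting, built for biostatisticians and cognitive-aging
researchers who want a tested, fully reproducible pipeline they can run on
synthetic data today and adapt to a real multi-wave cohort.

The pipeline:

1. **Simulate** a three-wave cohort (582 unique participants, ages 57–68,
   1–3 visits) with four latent trajectory archetypes — low-stable,
   high-upper, low-declining, high-lower — driving 77 cognitive scores,
   35 ICV-corrected regional brain volumes, 64-channel 2 kHz EEG with
   8/36 Hz steady-state visual evoked potential (SSVEP) responses, and
   per-participant risk factors.
2. **Preprocess**: per-visit coverage filter (≥ 75 participants),
   constancy filter on the [5, 95] percentile band, 5×IQR outlier removal,
   empty-participant drop; ICV normalization; modality matching.
3. **Summarize** the battery with a masked two-layer autoencoder
   (65% latent fraction → 50 features), tuned by ten-fold CV.
4. **Cluster** latent trajectories with temporal k-means under dependent
   multivariate dynamic time warping (DTW) with DBA centroids, choosing k
   by minimizing the Davies-Bouldin index
   `DB = (1/k) Σᵢ maxⱼ≠ᵢ (Sᵢ+Sⱼ)/Mᵢⱼ`.
5. **Extract EEG power**: Welch spectra (2 s Hann, 50% overlap), ×f
   compensation of the 1/f background, peak power at 8/36 Hz, five scalp
   regions, log + z-scoring — 10 features per recording.
6. **Compare groups** with Wilcoxon / Kruskal-Wallis / Fisher / chi-square
   at p < 0.05, plus per-visit trajectory summaries with 95% CIs.
7. **Validate labels** by merging into high/low performers and classifying
   per modality with ridge logistic regression and ROC/AUC, plus a
   univariate AUC scan over the individual scores.

The DTW dynamic program, path backtracking, and DBA update are implemented
in C++ (Rcpp); an exhaustive path-enumeration oracle and a truncated-SVD
oracle pin down the DTW and autoencoder implementations in the tests.

## Worked example

```r
library(cogtraj)

config <- cohort_config()          # 582 participants, fixed seed
res <- run_pipeline(config)
res$clustering$curve
res$manifest$auc
```

The Davies-Bouldin curve printed by the clustering stage (default seed):

```
      k    db inertia
  <int> <dbl>   <dbl>
1     2 0.974   3150.
2     3 0.614   1953.
3     4 0.446   1469.
4     5 1.12    1409.
5     6 1.54    1374.
6     7 1.80    1353.
7     8 1.98    1336.
```

The minimum at k = 4 selects four trajectory groups; with the default
cohort the recovered labels match the generative archetypes exactly
(adjusted Rand index 1.000, cluster sizes 66/67/140/264), and the
level/slope naming rule maps them to
`low_stable / low_declining / high_lower / high_upper`. The per-modality
classification of low- vs high-performing participants then reports, e.g.:

```
  modality  auc_insample auc_cv5     n
  cognitive        1.000   1.000   537
  mri              0.958   0.811   188
  eeg              0.798   0.763   354
```

i.e. the cognitive battery separates the merged classes essentially
perfectly (it defined them), structural MRI is a strong predictor, and
regional SSVEP power a moderate one — the ordering implied by the
generator's configured effect sizes.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_classify.R` are thin numbered
drivers over the package functions; each reads its inputs from `results/`,
prints what it found, and writes its tables back to `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Package layout

- `R/` — cohort generator, preprocessing, autoencoder, DTW/k-means/DBA,
  EEG power, group statistics, classifier, I/O and pipeline orchestration
- `src/` — C++ DTW core
- `tests/testthat/` — unit, property, and acceptance suites
- `vignettes/cognitive-trajectory-methods.Rmd` — the methods vignette:
  models, parameter choices, and limitations
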