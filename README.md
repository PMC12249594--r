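# escbio

Eye-selection-criteria analysis for paired-eye ophthalmic biomarkers.

## What this package is for

In ophthalmology the unit of analysis is usually the eye, and subjects have
two of them. Whether a study uses the right eye, the left eye, a randomly
selected eye, both eyes as independent rows, or the structurally best or
worst eye changes the apparent value of any biomarker — and inter-eye
correlation decides whether pooling eyes double-counts information. `escbio`
implements this eye-selection-criteria (ESC) analysis end to end for the
biomarkers used in pituitary macroadenoma (PMA) management: the pattern
visual evoked potential P100 amplitude at 12-arcmin checks (`AOz12`, µV,
cutoff 15.5) and the bi-nasal ganglion cell complex + inner plexiform layer
thickness (`BiNS`, µm, cutoff 65). Both fall under chiasmal compression, so a
value at or below its cutoff calls disease.

The pipeline:

* **Synthetic paired-eye cohort generator** — truncated-normal marginals at
  the published group moments, family-level inter-eye correlations (0.7–0.9
  in controls, ~0.45 in patients), a linear 12-month recovery model with
  population R² = 0.75, MCAR missingness injection. It defines the study
  conditions every claim is tested under, since no patient data are
  distributed.
* **ESC datasets** — `RE`, `LE`, `RSE`, `BoE`, `BeE`, `WE` construction with
  a per-subject selection audit (the worst eye is the one with lower global
  RNFL thickness).
* **Reliability** — intraclass correlation on right/left pairs (consistency
  ICC(3,1) default, agreement ICC(2,1) optional), Koo–Li classes, and the
  pooling decision rule (all ICCs > 0.7 → one random eye per subject).
* **Imputation** — perturbed-regression and 5-nearest-neighbour single
  imputation.
* **Univariate battery** — Kruskal–Wallis + Holm-adjusted pairwise rank-sum
  across ESC datasets; Mann–Whitney patients vs controls.
* **Diagnostics** — Se/Sp at the fixed cutoffs, trapezoidal ROC/AUC
  (identically U/(n₊·n₋)), stratified bootstrap AUC intervals, permutation
  comparison of AUCs across criteria.
* **Stable Sparse Biomarkers Detection (SSBD)** — the core multivariate
  method: 500–1000 subject-level subsamples, an elastic-net GLM per
  subsample with cross-validated penalty, a per-variable *stability index*
  (exact fraction of subsamples in which the variable has a nonzero
  coefficient) and aggregated standardized β, for PMA diagnosis and
  12-month visual-recovery prediction.

## Worked example

```r
library(escbio)

cohort   <- generate_cohort(generator_config(seed = 7))   # 42 patients + 42 controls
patients <- eye_cohort(as.data.frame(cohort[cohort$group == "patient", ]))
controls <- eye_cohort(as.data.frame(cohort[cohort$group == "control", ]))

we   <- build_esc_dataset(patients, "WE",  family = "all", seed = 7)
ctrl <- build_esc_dataset(controls, "RSE", family = "all", seed = 7)

evaluate_biomarker(we, ctrl, "BiNS", ci_iterations = 2000, seed = 1)
#> BiNS under WE @ cutoff 65: Se = 0.643, Sp = 1.000, AUC = 1.000 [1.000, 1.000] (n = 42/42)

icc_pairs(interocular_pairs(controls, "AOz12"))
#> ICC(consistency) = 0.844  [0.728, 0.913] (95% CI), n = 42 pairs, good

predictors <- c("AOz60", "AOz20", "AOz12", "gRNFL", "TS", "gGCCIPL", "BiNS")
tab <- rbind(as.data.frame(we)[,   c("subject_id", "group", predictors)],
             as.data.frame(ctrl)[, c("subject_id", "group", predictors)])
fit_ssbd(tab, predictors, "group", mode = "diagnosis",
         config = ssbd_config(n_subsamples = 500, seed = 7))
#> <ssbd_result> mode = diagnosis, 500 subsamples (0 redrawn)
#>  variable stability_index beta_aggregate
#>     AOz60           1.000         -1.519
#>     AOz20           1.000         -1.615
#>     gRNFL           1.000         -1.632
#>   gGCCIPL           1.000         -1.458
#>      BiNS           1.000         -2.945
#>     AOz12           0.998         -1.535
#>        TS           0.938          0.189
#> model AUC = 1.000
```

Reading the output: under the worst-eye criterion the structural biomarker is
a near-perfect classifier by rank (AUC 1.0) and perfectly specific at its
65 µm cutoff, while its sensitivity at that fixed cutoff depends on where the
patient distribution sits relative to 65 µm. Healthy controls show high
inter-eye agreement for the amplitude (ICC 0.84 here, "good"), which is what
licenses analysing one random eye per control. In the multivariate model the
negative β for the amplitudes and thicknesses says lower values vote for
disease; the stability indices say those votes are cast in essentially every
subsample.

`run_study("study.yaml")` (or `run_study()` for the shipped defaults) chains
all stages — generation, age matching, missingness + imputation, ESC
construction, ICC/pooling, univariate tables, 12 diagnostic results, and
SSBD in both modes — into one seeded, bit-reproducible report.

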