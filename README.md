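# blastprs

Quantitative myeloblast morphology for post-transplant AML/MDS relapse
risk. `blastprs` is an R package that reimplements, end to end, a
tile-based bone-marrow-aspirate image analysis: segment myeloblast nuclei
on Wright-Giemsa-stained tiles, extract a 214-element per-patient vector
of chromatin-texture and shape descriptors, select prognostic features by
LASSO-penalized Cox regression to form a **pathological risk score
(PRS)** for relapse-free survival (RFS), and train a linear-discriminant
relapse classifier benchmarked against the machine-counted blast
percentage.

It is aimed at computational-pathology and biostatistics users who want a
tested, reproducible reference pipeline: every stage — including a
synthetic cohort generator with ground-truth masks and survival outcomes
— is exercised by oracle-backed unit tests and an acceptance suite.

## The model in brief

For each cell nucleus with gray-level co-occurrence matrix
p(i,j) (16 levels, four distance-1 directions, symmetric), the two
headline texture descriptors are Haralick's

- contrast: `f_con = Σ_{i,j} (i-j)^2 p(i,j)`
- correlation: `f_cor = (Σ_{i,j} ij p(i,j) − μx μy) / (σx σy)`

These are summarized across the myeloblasts of each tile by mean, median,
standard deviation and skewness, averaged across a patient's six tiles,
and pooled with first-order intensity, morphometric, Hu-moment, elliptic
Fourier and irregularity descriptors into the 214-vector
(53 descriptors × 4 statistics + blast count + blast percentage). A
LASSO-Cox model on the training split selects the prognostic subset — in
the emulated cohorts, the *average of contrast variance* (across-cell
heterogeneity of chromatin contrast) and the *average of correlation
skewness* — whose Cox linear predictor is the PRS:

```
PRS_i = Σ_j β_j · z_ij ,   z_ij = (x_ij − mean_train) / sd_train
h_i(t) = h_0(t) · exp(PRS_i)          (proportional hazards)
```

Patients are dichotomized at the training-mean PRS (Kaplan-Meier,
log-rank, hazard ratio, Harrell's C), and a pooled-covariance LDA on the
selected features predicts one-year relapse (ROC/AUC, operating point
maximizing accuracy).

## Worked example

Simulate a 200-patient cohort whose relapse hazard is driven by latent
chromatin heterogeneity, run the full pipeline, and print the comparison
report:

```r
library(blastprs)
cfg <- run_config(
  out_dir = file.path(tempdir(), "demo_run"), seed = 11, mode = "features",
  sim = sim_params(n_patients = 200, tiles_per_patient = 6,
                   beta_texture = 1.2, train_frac = 0.6))
res <- run_pipeline(cfg)
cat(readLines(file.path(cfg$out_dir, "report.md")), sep = "\n")
```

which prints (seed 11):

```
# Pipeline comparison report

- patients: 200 (train 120 / val 80)
- selected features: har_contrast_sd

| method | split | AUC | accuracy | sensitivity | precision | HR | C-index | log-rank p |
|---|---|---|---|---|---|---|---|---|
| texture_prs | train | 0.793 | 0.775 | 0.81 | 0.842 | 2.72 | 0.678 | 4.1e-08 |
| texture_prs | val | 0.862 | 0.838 | 0.857 | 0.875 | 5.58 | 0.782 | 5.99e-09 |
| blast_percentage | train | 0.601 | 0.692 |    1 | 0.681 | 2.72 | 0.544 | 0.27 |
| blast_percentage | val | 0.591 | 0.65 | 0.918 | 0.652 |  4.2 | 0.606 | 0.0899 |
```

Reading it: LASSO recovered the causal heterogeneity feature
(`har_contrast_sd`, the across-cell contrast variance averaged over
tiles); on the held-out validation split the texture PRS separates
relapse from non-relapse patients (AUC 0.862, log-rank p ≈ 6e-9,
C-index 0.78) while the blast-percentage baseline — independent of the
simulated hazard by design — hovers near chance (AUC 0.59). The
training-split HR of a Cox-derived PRS is e ≈ 2.72 by construction
(see the methods vignette); the validation HR (5.58 per unit PRS) is the
informative one.

`mode = "image"` runs the same pipeline from rendered tiles through the
classical segmenter (Otsu on the blue-excess channel, opening, watershed)
and the feature extractor; see `?run_config`, `?segment_tile`,
`?render_tile`. A command-line interface wraps the same stages:

```sh
Rscript inst/cli/blastprs.R all --out run1 --seed 7 --n 40 --mode image
```

## Layout

- `R/` — simulator (`sim_params`, `render_tile`, `simulate_cohort`),
  segmentation (`segment_tile`, `evaluate_segmentation`), features
  (`compute_glcm`, `haralick_features`, `first_order_features`,
  `shape_features`, `aggregate_tile`, `aggregate_patient`), survival
  models (`lasso_cox_select`, `prs_score`, `dichotomize`, `fit_cox`,
  `km_logrank`, `harrell_c`), classifier (`fit_lda`, `roc_curve`),
  pipeline (`run_config`, `run_pipeline`, `blast_percentage_baseline`).
- `src/` — Rcpp morphology kernels (connected components, hole filling,
  chamfer distance, peak finding, seeded watershed).
- `vignettes/methods.Rmd` — model, assumptions, parameter rationale, and
  what the synthetic world does and does not establish.
- `tests/testthat/` — oracle-backed unit tests plus
  `test-acceptance.R`, one test per acceptance criterion.

Tiles are written as binary PPM and label masks as 16-bit PGM (NetPBM):
self-describing raster formats readable by any imaging stack.
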