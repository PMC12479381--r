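# nmbench

Synthetic phantoms and evaluation tools for neuromelanin-MRI substantia
nigra segmentation.

## The problem

Neuromelanin-sensitive MRI (NM-MRI) shows the substantia nigra pars
compacta — the dopaminergic midbrain nucleus that degenerates in
Parkinson's disease (PD) — as a bilateral hyperintensity. Segmenting that
hyperintensity yields imaging biomarkers: its volume (raw, normalized by
total brain volume, or intensity-thresholded) and its contrast relative to
a crus cerebri reference region,

```
CNR = (I_SN - I_CC) / SD_CC        CR = (I_SN - I_CC) / I_CC
```

Evaluating a segmentation method for this task needs several interacting
pieces: surface-aware quality metrics under anisotropic voxels (Dice, mean
surface distance, 95th-percentile Hausdorff distance in mm), combinatorial
screening of which MRI contrasts help, clinical discrimination statistics
(Mann-Whitney tests, common-language effect size, seed-averaged
cross-validated logistic ROC, symptom-laterality analysis), and — because
models trained on one scanner routinely collapse on another — a controlled
way to study domain shift.

Clinical NM-MRI cohorts are access-restricted, so `nmbench` ships a
synthetic-data module: multi-contrast midbrain phantoms with known ground
truth (crescent-shaped bilateral SN over 5–8 axial slices, a crus cerebri
reference, configurable PD effects, simulated raters at a target
inter-rater Dice, and acquisition-artifact operators — bias field, gamma,
noise, motion ghosting, affine/elastic — that move phantoms between
simulated scanners). Every stage of the analysis is exercised and tested
end to end on these phantoms; no image download is needed. The package is
aimed at methodologists building or validating SN segmentation and
biomarker pipelines.

## Worked example

```r
library(nmbench)

params <- phantom_params()                 # 64 x 64 x 24 voxels, 0.67 x 1.0 x 1.34 mm
effect <- disease_effect(cnr_reduction = 0.13)
cohort <- make_cohort(params, effect, n_pd = 12, n_hc = 8, seed = 1)
cohort
#> <nm_cohort> 20 subjects (HC=8, PD=12), site A, seed 1

# calibrate the reference segmenter on half the cohort, evaluate on the rest
train <- cohort; train$subjects <- cohort$subjects[1:12]
test  <- cohort; test$subjects  <- cohort$subjects[13:20]
model <- calibrate(train, contrasts = "NM", folds = make_folds(train, 3))
cat(sprintf("calibrated: k = %.2f, normalization = %s, CV DSC = %.3f\n",
            model$k, model$normalization, attr(model, "cv_dsc")))
#> calibrated: k = 1.75, normalization = reference, CV DSC = 0.841

metrics <- evaluate_cohort(segment_cohort(test, model), test)
round(colMeans(metrics[, c("dsc", "msd_mm", "hd95_mm")]), 3)
#>     dsc  msd_mm hd95_mm
#>   0.894   0.287   1.693

# imaging biomarkers on truth masks, and the PD-vs-HC CNR contrast
bm <- biomarker_table(cohort)
mw <- mann_whitney(bm$cnr[bm$group == "PD"], bm$cnr[bm$group == "HC"])
cat(sprintf("mean CNR: PD %.2f vs HC %.2f (Mann-Whitney p = %.3g)\n",
            mean(bm$cnr[bm$group == "PD"]), mean(bm$cnr[bm$group == "HC"]), mw$p))
#> mean CNR: PD 2.66 vs HC 2.95 (Mann-Whitney p = 0.0691)
```

Reading the output: the calibrated threshold (1.75 reference SDs) recovers
the SN on held-out phantoms at Dice 0.89 with sub-voxel mean surface error
(0.29 mm) and HD95 of 1.7 mm; the 13% generative CNR reduction shows as
PD 2.66 vs HC 2.95, not yet significant at this toy sample size of 20 (at
the default 58/22 cohort the same contrast reaches p < 0.01 — that check
is part of the acceptance suite).

The domain-shift experiment runs the same way:

```r
ds <- domain_shift_experiment(seed = 0)   # ~30 s, one CPU
ds[c("dsc_clean", "dsc_shifted", "dsc_aug_shifted", "recovery")]
```

A segmenter calibrated on clean "site A" phantoms holds its clean-test
DSC, collapses on "site B" images (strong inhomogeneity, gamma shift,
motion, noise), and recovers most of the loss when calibration is
augmented with site-transformed copies — the cross-scanner failure mode and
its augmentation remedy, reproduced at desk scale.

Other entry points: `simulate_rater()` (boundary-coherent rater noise at a
target Dice), `build_matrix()` / `delta_vs_single()` / `rank_models()`
(contrast-pair screening), `threshold_mask()` / `collinearity_report()`
(the volume–CNR confound introduced by intensity thresholding),
`cv_roc_auc()` / `laterality_analysis()` (clinical statistics),
`run_pipeline()` (the whole chain with CSV/JSON outputs), and
`write_cohort()` / `read_volume()` / `write_volume()` (NIfTI-1 I/O).

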