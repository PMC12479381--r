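---
title: "Methods: synthetic neuromelanin-MRI phantoms and segmentation evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic neuromelanin-MRI phantoms and segmentation evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Neuromelanin-sensitive MRI (NM-MRI) renders the substantia nigra pars
compacta (SNc) as a bilateral hyperintensity in the midbrain. Two families
of imaging biomarkers are derived from a segmentation of that
hyperintensity: its volume (raw, brain-volume-normalized, or
intensity-thresholded) and its contrast relative to a crus cerebri (CC)
reference region,

* CNR = (I_SN − I_CC) / SD_CC,
* CR  = (I_SN − I_CC) / I_CC,

where I denotes a mean intensity over a region and SD_CC the reference
standard deviation. In Parkinson's disease (PD) the SNc degenerates, which
lowers both the CNR and, more weakly, the volume.

`nmbench` implements the full evaluation chain around these quantities —
segmentation-quality metrics, biomarker extraction, combinatorial contrast
screening, clinical discrimination statistics, and a cross-scanner
(domain-shift) experiment — and, because clinical NM-MRI cohorts are not
freely redistributable, a synthetic-data module that generates midbrain
phantoms with known ground truth on which every stage can be exercised and
tested end to end.

## The phantom generator

`make_subject()` builds one multi-contrast phantom on a grid of
64 × 64 × 24 voxels at 0.67 × 1.0 × 1.34 mm spacing (the in-plane and
through-plane resolution typical of NM-sensitive GRE protocols; all
geometry is computed in millimetres so the anisotropy is honored
everywhere). It contains:

* two mirrored crescent-shaped SN regions, each the per-slice difference of
  two offset ellipses, mildly randomized per subject, spanning 5–8
  contiguous axial slices (the slice count is drawn per subject); the
  in-plane scale is bisected so each side hits its voxel-count target
  (default 600 voxels ≈ 540 mm³, log-normally jittered per subject with SD
  0.10);
* a bilateral crus cerebri reference region anterolateral to the SN
  (default 2400 voxels total);
* a uniform background.

Intensities per named contrast are `(structure level) + sn_coefficient ×
CNR × noise_sd + Gaussian noise`. The generative contract is that on the
clean `"NM"` image, `mean(SN) = mean(CC) + CNR × noise_sd` per side, so the
measured CNR on truth masks recovers the generative target (the acceptance
suite verifies a mean absolute error below 0.1 at targets 1, 2 and 3). The
default contrast set is `NM` (SN coefficient 1), `SWI` (−0.9, noisier),
`T2` (0.5) and `T1` (0 — no SN signal), which spans the qualitative range
needed by the screening experiments: synergistic informative contrasts, a
hypointense contrast, and a pure-noise control.

Simplifications worth keeping in mind when interpreting green tests: the
background is flat and matches the CC level within each contrast (no other
anatomy is rendered as intensity; non-SN structures exist only as labelled
masks), edges are hard (no partial-volume ramp), and the noise is additive
Gaussian rather than Rician — the CNR definition divides by a reference SD,
so only a well-defined SD is required of the noise family. Nothing here
models nigrosome substructure, DTI tensors or QSM reconstruction. Passing
tests demonstrate that the *evaluation machinery* behaves correctly under
the stated statistical structure, not that any particular segmenter will
reach a particular DSC on real scans.

### Disease effects

`disease_effect()` holds the group-level generative parameters:

* `cnr_reduction` (default 0.13): fractional CNR decrease in PD. 0.13
  mirrors an average reduction over a whole mixed cohort; 0.22 is a typical
  test-set-sized effect. Applied as a multiplier after the per-subject and
  per-side draws so that a zero effect makes PD and HC generation
  bit-identical under the same seed.
* `volume_reduction` (default 0.05): the volume effect is deliberately much
  weaker than the CNR effect.
* `between_subject_sd` (default 0.35, CNR units): chosen so that at 58 PD /
  22 HC the CNR group difference is detectable at p < 0.01 but the groups
  overlap substantially — the regime the clinical statistics are designed
  for.
* `laterality_coupling` (default 0): the probability excess that the
  clinically dominant side is contralateral to the side with the larger CNR
  deficit. The default 0 is an exact built-in null (imaging asymmetry
  carries no information about symptom laterality); 1 is a positive
  control in which the CNR left/right ratio separates the dominance groups
  almost completely.

### Clinical scores

`assign_clinical()` gives PD subjects per-side UPDRS-III brady-rigidity +
tremor sums with one strictly dominant side, and SBR values whose
log left/right ratio is shifted by ±0.179 (SD 0.18) depending on the
dominant side. Those two constants were set once, analytically, from
CLES = pnorm(2m / (sd · sqrt(2))) = 0.92, the separation typical of
dopamine-transporter SPECT; the acceptance suite checks the realized CLES
lies in [0.87, 0.97]. Healthy controls get zero UPDRS sums and SBR drawn
from a normal range.

### Simulated raters

`simulate_rater()` perturbs a mask by adding a smooth random field to a
layered signed-depth map of the mask and re-thresholding, which produces
spatially coherent boundary errors (over- and under-inclusion) rather than
voxelwise salt-and-pepper. The field magnitude is searched per draw so the
Dice agreement with the input matches the target (default 0.70, the level
of real inter-rater agreement on this structure). Only the mean agreement
is matched; the between-rater spread of real raters is not modelled, since
the underlying error process is unobservable.

## Site effects

The acquisition-artifact operators double as training augmentations and as
the source of simulated cross-scanner shift: multiplicative polynomial bias
fields (`exp(f)` with `max|f|` = amplitude, zero-mean log-field), gamma
remaps on the image's own range, additive noise, k-space line-replacement
motion ghosting, and joint affine / elastic geometric transforms (images
interpolated linearly, masks nearest-neighbour, one sampled transform for
all inputs). Every operator is deterministic under a seed, intensity
operators never touch masks, and null parameters are identities.

The bundled `site_b` profile (intensity remap 1.4x − 20, bias amplitude
0.5 at order 3, gamma 0.65–0.8, 8% corrupted k-space lines, extra noise
2.5) is a set of calibration constants, not measured values: it was tuned
once so that a segmenter calibrated on clean phantoms loses a large
fraction of its DSC on `site_b` images while augmented calibration recovers
most of the loss — the qualitative pattern observed when single-site models
meet other scanners. The dominant driver in the phantom, as in practice, is
the bias field interacting with gamma compression. The package exposes
per-operator magnitudes but makes no claim about which artifact drives the
gap in any real dataset.

Elastic deformation defaults (8 mm control grid, 1.5 mm maximum
displacement) keep the volume change of SN-sized masks within about 15%
and respect a fold-free heuristic (`max displacement < control spacing /
2`).

## The reference segmenter

The deep networks that motivate this evaluation pipeline are out of scope;
in their place stands a transparent, deterministic reference-region
segmenter so that screening and domain-shift experiments are about
*evaluation behaviour*, not network internals. `segment()`:

1. optionally removes inhomogeneity (`normalization = "polyfit"`: an
   order-3 polynomial is least-squares fitted to the log-intensities with
   the brightest 2% of voxels excluded, and divided out — classical
   parametric bias-field correction);
2. z-scores each requested contrast by the subject's CC statistics;
3. averages the z-maps with weights proportional to each contrast's mean
   truth-SN z-score estimated from the training folds (sign orients
   hypointense contrasts, magnitude down-weights uninformative ones —
   uniform weights would dilute a pair by sqrt(2) when one member carries
   no SN signal);
4. thresholds at `k` reference SDs inside a central search box
   (±14 mm in-plane), labels 26-connected components, keeps components
   within size bounds (40–4000 voxels), and selects up to two ranked by
   excess z-mass `sum(z − k)` with a one-per-hemisphere preference. Excess
   mass is used instead of raw size because under heavy artifacts large,
   barely-supra-threshold noise clusters otherwise outrank the fragmented
   SN.

`calibrate()` selects `(normalization, k)` by maximizing mean out-of-fold
DSC on subject-level folds (default 3), with ties resolved toward the plain
reference mode and then toward smaller `k`; `augmented_calibrate()` runs
the same selection with site-transformed copies of every training subject
added to the out-of-fold evaluation, which is how robustness enters: on
clean data both normalizations tie and the simple one wins, on corrupted
copies only the bias-corrected mode scores, so the augmented model learns
the invariance — a faithful, inspectable analogue of what aggressive
augmentation does to a network.

## Metric conventions

* DSC = 2|X∩Y| / (|X|+|Y|); both masks empty → 1, exactly one empty → 0,
  so catastrophic failures surface as near-zero DSC rather than NaN.
* The surface of a voxel mask is the set of centres of foreground voxels
  with at least one face-adjacent (6-connectivity) background neighbour;
  out-of-grid counts as background; coordinates are `(index − 1) × spacing`
  mm.
* MSD is the mean of the two one-sided distance vectors *concatenated*
  (each surface point weighted equally). The alternative reading — the mean
  of two per-direction means — coincides when |A| = |B| and differs
  negligibly for similar-sized surfaces; the choice is fixed and stated
  here because the defining phrase is ambiguous.
* HD95 takes the 95th percentile of each one-sided vector with linear
  interpolation between order statistics (`quantile` type 7 — no standard
  convention exists, so the implementation's one is pinned and the test
  oracle uses the same rule), then the maximum of the two directions.
* Surface metrics raise an error on empty masks (undefined) rather than
  returning a sentinel.
* Distances are computed from per-coordinate differences; the usual
  `|a|² + |b|² − 2ab` expansion was rejected because cancellation broke
  nanometre-level agreement with the brute-force oracle.

## Biomarkers

`roi_stats()` uses the population SD (divisor N) for the reference region;
the convention is recorded in the table attributes so results are labelled.
CNR and CR are computed on the bilateral SN union by default (one value per
subject), with per-side values available for laterality analyses.
`threshold_mask()` implements the 1.5-SD-above-reference rule; the
collinearity report exists because that rule mechanically couples the
surviving volume to the signal level: on cohorts where volume and CNR are
generated independently, the raw correlation is near zero while the
thresholded-volume correlation is strongly positive — a confound worth
demonstrating before interpreting thresholded volumes as an independent
biomarker.

## Screening

`build_matrix()` fills the K × K matrix A with the cross-validated DSC of
the segmenter calibrated per contrast pair (singles on the diagonal); one
calibration per unordered pair, stored mirrored, so symmetry holds by
construction. Derived quantities are pure functions of A: `delta_vs_single`
(B[i,j] = A[i,j] − A[j,j]), `delta_vs_best` (pair minus best constituent),
the per-contrast improvement potential (column means of B excluding the
diagonal — "mean" chosen and labelled since the aggregate is not otherwise
pinned down), and a ranking of all K singles and K(K−1)/2 pairs. With the
informativeness-weighted combination, adding a pure-noise contrast is
neutral rather than harmful, so its delta row hovers at zero (the unit test
allows +0.02 of Monte-Carlo slack around the expected non-positive trend).

## Clinical statistics

* `mann_whitney()`: midrank U; exact p via the null U distribution for
  tie-free samples (both n ≤ 50), full enumeration of rank assignments when
  `choose(n, nx)` ≤ 2e5 (valid with ties), otherwise the normal
  approximation with tie and continuity correction. Exact enumeration at
  20-per-group with ties is combinatorially impossible (~1.4e11
  assignments), so the enumeration cutoff is explicit rather than
  per-group-size.
* `cles()` counts ties as one half, which makes `cles(x,y) =
  U(x)/(n_x n_y)` and `cles(x,y) + cles(y,x) = 1` exact identities (both
  are tested on random tied data).
* `auc()` is the rank form (probability a positive outranks a negative),
  cross-checked in the tests against trapezoidal ROC integration from an
  independent package.
* `cv_roc_auc()` uses stratified random 2-fold splits (the 58/22 imbalance
  would otherwise occasionally produce single-class folds), standardizes
  features on the training fold only, fits a lightly ridge-penalized
  logistic model (fixed lambda 0.01, penalty excluding the intercept,
  IRLS) so separable folds converge, pools the out-of-fold scores into one
  ROC per seed, and averages over 100 seeds. Pooled scoring was chosen over
  averaging per-fold AUCs because at two folds the per-fold ROC is built
  from half the subjects and is markedly noisier.
* `laterality_analysis()` compares left- versus right-dominant PD subjects
  on the SBR ratio and the truth per-side CNR and volume ratios
  (Mann-Whitney p and CLES each); subjects with tied UPDRS sums are
  `undetermined` and excluded.

## Determinism and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
per-subject and per-stage seeds are derived from master seeds with a
counter-based scheme, so cohorts are bit-reproducible and extensible
without reshuffling earlier subjects. The bundled experiments run on one
CPU: the test suite uses reduced grids (56 × 44 × 14) for unit tests and
the full 64 × 64 × 24 grid with 100-subject-per-level recovery runs, an
80-subject default cohort, and a 16-train / 10-test domain-shift experiment
in the acceptance checks; `scripts/acceptance.R` regenerates everything
from scratch in a few minutes. These sizes are the package's chosen study
conditions for desk-scale verification, stated here so results are read at
the scale they were computed.

## Known limitations

* The phantom's flat background understates the difficulty of real
  midbrain segmentation; DSC values obtained on phantoms are upper bounds
  of a rather easy task and should never be quoted as expected clinical
  performance.
* The reference segmenter is a stand-in: conclusions about *which* network
  architecture or loss would win on real data are explicitly out of scope.
* The rater simulator matches mean agreement only.
* The site profiles are synthetic calibration constants; no claim is made
  that any specific artifact magnitude corresponds to a particular scanner.
* CR's sensitivity to intensity offsets (unlike CNR) is preserved by
  design; pipelines that apply offset remaps before computing CR will see
  that dependence.
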