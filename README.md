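# atriashape

Statistical shape analysis of the left atrium (LA) for predicting atrial-
fibrillation recurrence after catheter ablation.

The LA remodels under atrial fibrillation: it dilates and becomes more
spherical, and remodelled atria respond less well to ablation. `atriashape`
implements the full computational-anatomy pipeline that turns endocardial
segmentations into recurrence predictors:

* **Smooth shape encoding** — a closed bicubic Hermite surface template
  (134 nodes x 12 DOF = 1,608 parameters; C1-continuous patches) is
  personalized to each subject's segmentation point cloud by regularized
  ICP, suppressing segmentation artifacts by construction.
* **Shape atlas** — PCA over cohort shape vectors; the retained mode count
  is the smallest k whose mean node reconstruction error drops below 1 mm.
* **Discriminant modes** — Fisher LDA in the PCA score space: an inclusive
  mode (iLDA) over all retained modes, and an optimized mode (oLDA) from an
  exhaustive subset search (247 combinations for 8 modes) ranked by
  leave-one-out AUC.
* **Shape markers** — volume, surface area, three AP-radius variants
  (mesh caliper, segmentation slab, imported echo), axis radii/ratios,
  sphericity `(1 - mean|r_i - R| / R) * 100` from a least-squares sphere
  fit, and **vertical asymmetry**: the signed sum over 50 mirrored slice
  pairs of the superior-minus-inferior difference in anterior-posterior
  extent (positive = superior hemisphere AP-larger).
* **Classification** — Mann-Whitney ROC/AUC, leave-one-out CV with exact
  rank-one LDA downdates, exhaustive LDA search over marker combinations,
  Gaussian score fits with Bhattacharyya overlap, and per-node Hotelling
  T² tests after rigid Procrustes alignment.
* **Synthetic cohorts** — a seeded generator of LA-like surfaces
  (AP-flattened ellipsoids with a superior-posterior prominence and a
  superior/inferior AP imbalance) with a logistic recurrence model on the
  true markers, so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(atriashape)

co  <- generate_cohort(cohort_config(n_subjects = 144, seed = 7))
tpl <- make_sphere_template()          # 134 nodes, 144 faces, r = 20 mm

# personalize the template to one subject's segmentation cloud
fit <- fit_template(co$clouds[[1]], tpl)
fit$report
#> Fit error: 0.810 +/- 0.601 mm over 2000 points

# cohort atlas and markers
pca <- build_pca(lapply(co$meshes, mesh_to_vector))
round(head(pca$explained_fraction, 3), 3)
#> [1] 0.884 0.054 0.036
mode_marker_correlation(pca, co$latent$volume)[1]
#>      mode1
#> -0.9693921                       # mode 1 is a size mode

sph <- sapply(co$meshes, function(m) sphericity(sample_surface(m, 8)))
va  <- sapply(co$meshes, vertical_asymmetry)
cv  <- loo_cv(cbind(scale(sph), scale(va)), co$labels$recurrence_12m)
c(loo = cv$loo_auc, bayes = co$bayes_auc_12m)
#>       loo     bayes
#> 0.7504437 0.7636483
```

The sphericity + vertical-asymmetry combination recovers almost all of the
separability the label model planted (`bayes` is the expected AUC of the
Bayes-optimal score for this cohort); the small gap is the measurement noise
introduced by the pipeline itself.

`pipeline_run(cohort, la_run_config(), out_dir)` chains every stage
(fit → PCA → mode selection → iLDA/oLDA → markers → classification) and
writes CSV/JSON artifacts plus the exact configuration used.

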