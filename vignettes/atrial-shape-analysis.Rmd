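---
title: "Statistical shape analysis of the left atrium: models, markers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of the left atrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriashape)
```

## The problem

Atrial fibrillation remodels the left atrium (LA) at the organ level: the
chamber dilates and its shape drifts towards a sphere. Because remodelled
atria respond less well to catheter ablation, scalar descriptors of LA
anatomy — volume, anterior–posterior (AP) radius, sphericity — are candidate
predictors of post-ablation recurrence. `atriashape` implements a complete
computational-anatomy pipeline for this question: it encodes each patient's
LA body as a smooth parametric surface, builds a statistical shape atlas over
a cohort, derives discriminant shape modes, computes scalar remodelling
markers (including the vertical-asymmetry marker, which quantifies the
AP-size imbalance between the superior and inferior hemispheres), and
evaluates marker combinations as recurrence classifiers under leave-one-out
cross-validation.

All geometry uses patient-oriented axes *x* = right→left (LR), *y* =
posterior→anterior (AP), *z* = foot→head (FH), in millimetres.

## Shape representation

Surfaces are closed bicubic Hermite meshes. Each node carries 12 degrees of
freedom — position plus the parametric derivatives $\partial_u$,
$\partial_v$ and $\partial_{uv}$ of the surface map, three components each —
and every quadrilateral patch interpolates its four corner nodes with the
cubic Hermite basis

$$ h_{00}(t) = 2t^3 - 3t^2 + 1,\quad h_{01}(t) = -2t^3 + 3t^2,\quad
   h_{10}(t) = t^3 - 2t^2 + t,\quad h_{11}(t) = t^3 - t^2 . $$

Because adjacent patches share corner data, the surface is $C^1$: positions
along shared edges agree to machine precision (the suite checks $<10^{-9}$
mm). The standard template is a UV sphere of radius 20 mm with 12
longitudinal segments and 11 latitude rings plus two poles — 134 nodes and
144 faces (120 quads and 24 pole triangles), hence $134 \times 12 = 1{,}608$
parameters per subject.

Two representation choices were genuinely open and are worth stating:

* **Pole caps.** Pole triangles are quads with one collapsed edge, so a
  single patch code path serves every face. A pole node stores two
  orthogonal surface tangents in its du/dv slots; the meridional derivative
  of a cap patch at column angle $\theta$ is the blend
  $\cos\theta \, D_1 + \sin\theta \, D_2$. This keeps evaluation *linear* in
  the node DOF (essential for least-squares fitting) and is exact for
  axis-scaled or radially-bumped spheres, the family the synthetic generator
  produces.
* **Derivative scaling.** Stored derivatives are per unit of the local patch
  coordinate on the uniform template grid, so patch corner data are the
  stored values without per-subject rescaling; the scaling convention is
  fixed once at template construction.

Area, volume and centroid use tensor Gauss–Legendre quadrature per patch
(order 4 by default; order 8 changes the template volume by $<10^{-4}$\%)
with the divergence theorem $V = \tfrac13 \oint \mathbf{x}\cdot\mathbf{n}\,
dA$; a non-positive volume signals inward orientation and is an error.

## Template personalization

A subject is represented by warping the spherical template onto their
endocardial segmentation point cloud. Alignment estimates translation (cloud
centroid) and isotropic scale (RMS radius) only — no rotation, because the
patient axes are trusted and a free rotation would destroy the
node-correspondence convention (node 1 is always the most inferior point).
The fit then alternates

1. *correspondence*: each cloud point is matched to its closest point on a
   dense surface sample grid (6×6 per patch), and
2. *update*: a linear least-squares solve over all node DOF minimizing
   $\sum_i \lVert S(q)_i - x_i \rVert^2 + \lambda \,
   \lVert \mathcal{D}^2 (q - q_0) \rVert^2$,

where $\mathcal{D}^2$ collects the second parametric derivatives
$(\partial_{uu}, \partial_{vv}, \sqrt{2}\,\partial_{uv})$ of the
*displacement* from the aligned template at quadrature points. The penalty
suppresses segmentation spikes while leaving a uniform translation or
scaling of the surface unpenalized. Both steps decrease the objective, so
the iteration is monotone (asserted by a test against the logged trace).

The stiffness default $\lambda = 0.2$ was fixed by a one-off synthetic
calibration: it keeps the fit bias on a noise-free cloud of a representable
surface below 0.1 mm while returning residuals of roughly 0.8–1 mm on clouds
with 1 mm isotropic noise — the residual scale expected when the cloud noise
dominates. Larger $\lambda$ trades residual for smoothness; the
regularization path is monotone (a test checks the data misfit never
decreases with $\lambda$).

Point-to-surface distances are computed against an 8×8 per-patch sample grid
followed by local parametric refinement (nine halvings of a 3×3 stencil),
giving self-distances below 0.05 mm; exact closest-point projection is
deliberately out of scope.

## Shape atlas and discriminant modes

Cohort shape vectors are analysed by PCA (SVD of the row-centered matrix).
Modes are unit directions; the per-mode score standard deviations carry the
variance, matching the convention "mean shape ± 2 SD along a mode" used for
visualisation. The number of retained modes is the smallest $k$ whose
cohort-mean node-position reconstruction error falls below 1 mm (about half
a typical MR voxel); error averaging is per subject, then across the cohort,
using node positions only.

Fisher LDA operates in the retained PCA score space, where it is well posed
($n \gg d$), with direction $w \propto S_w^{-1}(\mu_1 - \mu_0)$ and a ridge
added only when $S_w$ is numerically singular. Two discriminant modes are
built:

* **iLDA** uses all retained modes;
* **oLDA** exhaustively searches mode subsets of sizes `min_subset`..$k$ and
  keeps the subset with the best leave-one-out AUC. With $k = 8$ and the
  default `min_subset = 2` this is 247 combinations
  ($\sum_{j=2}^{8}\binom{8}{j}$); `min_subset = 1` gives all 255 non-empty
  subsets. Both are exposed because the two counts circulate in the
  literature for the same search; the default reproduces 247. Ties are broken
  towards fewer modes, then lexicographically.

Out-of-fold LDA scores are the canonical decision values
$(x - \tfrac{\mu_1+\mu_0}{2})^{\top} \widehat\Sigma^{-1} (\mu_1 - \mu_0)$,
whose log-odds-like units make scores comparable across leave-one-out folds
when pooled into a single AUC (pooling is the only well-defined option for
LOO; per-fold AUC does not exist at fold size one). The LOO loop uses exact
rank-one downdates of the class statistics, so the 247-subset search is
cheap even at $n = 500$.

## Shape markers

* **Sphericity**: $(1 - \overline{|r_i - R|}/R)\times 100$ from the
  least-squares sphere fit (algebraic initialisation, Gauss–Newton
  refinement of the geometric residuals with the radius profiled out). The
  mean-absolute-residual normalisation is one of several "normalized
  residual" conventions; it is scale-invariant and equals 100 exactly on a
  sphere, and the choice is isolated in one function.
* **AP radius, three ways**: from the smooth mesh (half the minimal caliper
  width of the equatorial cross-section — the shortest equatorial radius,
  invariant to in-plane rotation), from the segmentation cloud (half the
  y-extent of a ±2 mm slab at the centre-of-mass height, which reads the
  noise envelope and is therefore biased upward on noisy clouds — the
  modality effect the pipeline is designed to expose), and from
  echocardiography (an imported number, never computed here).
* **Axis radii and ratios**: half-extents along LR/AP/FH and their ratios.
* **Vertical asymmetry (VA)**: with $z_0$ the centroid height and $H$ the
  smaller pole distance, mirrored slice pairs at $z_0 \pm h_j$,
  $h_j = (j - \tfrac12) H / n$, $j = 1..50$, each contribute the difference
  in AP extent (max $y$ − min $y$) of the cross-section; VA is the sum over
  pairs, in mm. Positive VA means the superior hemisphere is AP-larger. The
  slice-pair sum was chosen because it directly measures the
  superior/inferior AP imbalance, its sign convention matches the clinical
  description, and summation over ~50 pairs produces cohort magnitudes of
  order $10^2$–$10^3$ mm. VA is exactly zero for any shape mirror-symmetric
  about $z_0$ and flips sign under z-reflection, for *any* slice count —
  these are the properties the tests pin down. The hemisphere split uses the
  centroid height rather than the bounding-box midpoint for noise
  robustness.

Cross-sections are extracted by evaluating a fixed parametric grid once per
mesh and interpolating the $z$-crossings along the $v$ direction of every
grid column; doubling the grid moves VA by well under 1% and the suite
checks agreement with an independent analytic slice oracle to 1% on an egg
shape.

## Recurrence classification

ROC analysis uses the rank (Mann–Whitney) AUC with half-credit for ties.
`marker_combination_search()` evaluates every subset of the configured
markers (63 subsets for six markers) as an LDA combination under LOO-CV,
using for each subset the subjects with complete data for that subset —
mirroring clinical tables whose $n$ varies by marker availability. Gaussian
per-class score fits are summarised by the Bhattacharyya overlap
coefficient. Localized shape differences are tested per node with two-sample
Hotelling $T^2$ on 3D node positions after rigid (rotation + translation,
no scaling) generalized-Procrustes alignment to an iterated mean (3
iterations); no multiple-testing correction is applied by default, matching
the clinical procedure this reproduces, and a Bonferroni option exists. The
per-node null rate is slightly conservative (≈0.008–0.01 at $\alpha=0.01$ in
simulation) because the alignment consumes rigid degrees of freedom.

## The synthetic cohort

The generator replaces image acquisition and segmentation so that every
stage is testable without patient data. A subject is an AP-flattened
ellipsoid (median semi-axes 32/22/30 mm LR/AP/FH) deformed by

* a shared log-normal **size** factor (log-SD 0.18) and per-axis log-normal
  **ratio** factors (log-SD 0.07), so the first atlas mode is a size mode
  (the suite checks $|\rho|$ between mode-1 scores and volume exceeds 0.9);
* a smooth superior-posterior radial **prominence** (median 4 mm), emulating
  the left pulmonary-vein region;
* a superior/inferior AP-width ratio $\gamma$ (median 0.92, log-SD 0.08)
  applied through a smooth tanh ramp — the source of vertical asymmetry;
* per-node Gaussian position noise (0.5 mm) for individual local variation.

The segmentation cloud is 2,000 area-weighted surface samples with 1 mm
isotropic noise, the scale of typical segmentation-to-mesh residuals.
Recurrence labels follow a logistic model on the z-scored *true*
(noise-free) sphericity and VA with unit log-odds per SD
(+1 for sphericity, −1 for VA — sphere-like, inferior-dominant atria recur),
a clear planted effect at the upper end of the clinically plausible range;
the intercept is solved numerically for a 31% 12-month prevalence, and the
24-month horizon adds conversions to 40% cumulative with 20% lost to
follow-up. Because labels derive from noise-free markers, any classifier
degradation is attributable to pipeline noise; the expected AUC of the
Bayes-optimal score for the generated cohort is stored alongside
(`bayes_auc_12m`, computed as the exact conditional pairwise expectation
over label draws rather than by Monte-Carlo — same estimand, no sampling
error).

What the generator does **not** emulate: pulmonary veins and appendage
(excluded at their ostia in the clinical meshes too), wall thickness and
fibrosis, segmentation artifacts with spatial structure, and clinical
covariates. Synthetic VA magnitudes (tens of mm) are smaller than clinical
cohort values (hundreds of mm) because the deformation family is smoother
and more symmetric than real atria; passing the recovery tests therefore
demonstrates correctness of the machinery, not clinical performance.

## Problem sizes and determinism

The shipped experiments use cohorts of 144 (the clinical cohort scale) for
the marker-search recovery replicates and 500 for the LOO-vs-Bayes and
planted-direction checks; template fits use 1,500–5,000-point clouds. All
stochastic stages are driven by explicit seeds; `generate_cohort()` is
bit-reproducible given its seed and `loo_cv()` has no internal randomness.

One recovery criterion deserves a note: the top-ranked marker subset is
required to *contain* the planted {sphericity, VA} pair rather than equal it
exactly. Exact-subset selection by cross-validation is inconsistent — a
superset carrying a near-harmless extra marker wins with non-vanishing
probability on any finite cohort, and several remaining markers are partial
information proxies of sphericity (the axis radii jointly encode the axis
ratios that drive it). The companion check that the pair's LOO AUC is within
0.02 of the winner's confirms no other marker adds real predictive value.

## Known limitations

* Closest-point correspondences are grid-based; sliver-thin or strongly
  non-star-shaped surfaces could mis-associate points. LA bodies and the
  synthetic family are star-shaped in practice.
* Node correspondence after fitting is approximate (ICP allows tangential
  sliding); markers and the atlas are surface-based and insensitive to this,
  but per-node tests on fitted meshes inherit it as alignment noise.
* The sphericity normalisation and the VA slice recipe are single published
  conventions among several; both are isolated behind one function each and
  documented above.
* Reading binary VTK/PLY is not supported; all formats are ASCII.
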