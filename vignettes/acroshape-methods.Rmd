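---
title: "Shape morphometry and classification of acrosome surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape morphometry and classification of acrosome surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acroshape)
```

## The problem

During spermiogenesis the acrosome — the exocytotic vesicle capping the
sperm head — remodels from a roughly spherical vesicle (round spermatids)
into a flattened, hooked cap (mature spermatozoa, in mouse).  Given a
closed triangular surface mesh of one acrosome, reconstructed from
confocal microscopy, `acroshape` quantifies its morphology with seven
parameters and classifies cells between the two developmental stages with
a repeated cross-validated linear SVM, scored with a per-cell accuracy
framework.  The package consumes meshes (PLY, OBJ, legacy VTK polydata);
image segmentation and surface reconstruction are out of scope.

## The 7-parameter feature vector

For a mesh with vertices ("nodes") indexed $i = 1 \dots N$:

* **Volume** $V$: the absolute signed sum of origin tetrahedra
  (divergence theorem).  The sign of the raw sum flags inward orientation
  in `validate_mesh()`; the reported volume is always $|V|$.
* **Surface area** $\Sigma$: the sum of triangle areas.
* **Sphericity** $\Psi = \pi^{1/3}(6V)^{2/3}/\Sigma$, which is 1 for a
  perfect sphere and decreases with eccentricity or asymmetry; it is
  dimensionless and scale-invariant.
* **Average curvatures** $\bar M = \sum_i M_i / N$ and
  $\bar G = \sum_i G_i / N$, with $M_i = (k_1^i + k_2^i)/2$ (units
  length$^{-1}$) and $G_i = k_1^i k_2^i$ (length$^{-2}$), where
  $k_1 \le k_2$ are the principal curvatures.  Note these are plain
  node averages, not area-weighted surface integrals: every mesh node
  counts equally.  An area-weighted alternative exists behind the
  `weights` argument of `surface_average()` but is never the default.
* **Relative fluctuations**
  $\Delta M/\bar M = \sqrt{\sum_i (M_i - \bar M)^2 / ((N-1)\bar M^2)}$
  and analogously $\Delta G/\bar G$: the sample standard deviation over
  nodes divided by the absolute mean — dimensionless curvature
  heterogeneity.

Units are whatever the mesh carries (microns for confocal
reconstructions); the engine is dimensionless and nothing is enforced.

## Discrete curvature estimation

The default estimator (`method = "deficit"`) uses the classical discrete
operators:

* Gaussian curvature from the angle deficit,
  $G_i = (2\pi - \sum_f \theta_{if}) / A_i$, with $A_i$ the barycentric
  vertex area (one third of the incident triangle areas).  By the
  discrete Gauss–Bonnet/Descartes theorem the area-weighted total
  $\sum_i G_i A_i$ equals $2\pi\chi$ *exactly* (to rounding), which the
  test suite asserts at $10^{-8}$ on genus-0 and toroidal meshes.
* Mean curvature from the cotangent-Laplacian mean-curvature normal,
  $\mathbf{K}_i = \frac{1}{2A_i}\sum_{j}(\cot\alpha_{ij} +
  \cot\beta_{ij})(\mathbf{x}_i - \mathbf{x}_j)$, with
  $M_i = \pm\frac{1}{2}\lVert\mathbf{K}_i\rVert$ signed by the outward
  vertex normal.  The sign convention is positive where the surface is
  convex with respect to the outward normal, so a sphere of radius $R$
  has $k_1 = k_2 = 1/R > 0$.
* Principal curvatures recovered as $M \pm \sqrt{\max(M^2 - G, 0)}$.
  Where rounding noise makes $M^2 < G$ (common on near-umbilic surfaces
  such as spheres) the square root is clamped at zero and the vertex
  counted in the field's `n_clamped` attribute; at clamped vertices
  $k_1 k_2 = M^2$ rather than $G$, so the consistency identity
  $G = k_1 k_2$ is asserted only at unclamped vertices while
  Gauss–Bonnet always uses the raw deficit values.

A second estimator (`method = "quadric"`) fits a quadratic height
function over each vertex's neighborhood in its tangent frame and takes
the eigenvalues of the Weingarten map, emulating patch-fitting toolkits.
The two estimators have complementary strengths, and this drives which
one each validation uses: the angle deficit satisfies Gauss–Bonnet
exactly but its *pointwise* values at irregular vertices (the 12
valence-5 vertices of an icosphere) do not converge under subdivision —
the maximum vertex error plateaus near 0.15 — whereas the quadric
estimator converges pointwise (maximum errors fall from $5\times10^{-2}$
to $9\times10^{-4}$ over subdivision levels 2–5) but has no exact
integral invariant.  Node *averages* of the deficit estimator converge
fine, which is what the feature vector uses.  The monotone-convergence
test therefore exercises the quadric estimator and the integral-invariant
test the deficit estimator.

Open patches (plane, cylinder wall fixtures) are accepted with
`allow_open = TRUE`; boundary vertices get `NA` and analytic limits are
checked on interior vertices only.  Degenerate (zero-area) faces are
dropped at construction with a warning rather than failing the mesh.

## The synthetic population generator

The original confocal dataset (158 spermatids, 51 spermatozoa) is not
distributable, so `simulate_population()` provides a synthetic stand-in
that reproduces its *qualitative* contrasts, with class sizes 158/51 by
default:

* class A ("spermatid", label $-1$): mildly elongated ellipsoids
  (long-axis ratio uniform in 1–1.4) with smooth radial bump noise;
* class B ("spermatozoon", label $+1$): "hooked caps" — flattened
  capsules (elliptical cross-section, default in-plane semi-axis 1.3 and
  flattening 0.7 before volume rescaling) swept along a circular arc
  (sweep angle uniform in 3.4–4.6 rad) with rounded closed ends.  This
  is a closed genus-0 hairpin-shaped shell with tunable curvature
  heterogeneity, the same geometric family as a cap swept along an arc.

Per-cell volumes are drawn log-normally (class A mean 60 µm³, log-SD
0.25 — a realistic acrosome scale and spread) and each mesh is rescaled
to its drawn volume, so the class-B/class-A mean-volume ratio is exactly
the configured `volume_factor` (default 1.5) in expectation.  With these
defaults class B also has lower sphericity, lower average mean and
Gaussian curvature, and larger curvature fluctuations — the observed
spermatozoon pattern; the hook cross-section was deliberately made wide
enough (in-plane semi-axis 1.3) that its intrinsic mean curvature stays
below the spermatid ellipsoids' after the 1.5× volume rescale.  All
seven features are strictly positive for the default generator, so the
log transform applies cleanly.

Bump noise is a low-order (degree ≤ 3) real-spherical-harmonic random
radial field, rescaled to the requested maximum relative amplitude
(default 0.08, capped at 0.3): smooth by construction, so perturbed
meshes remain valid and their curvature fields finite — unlike
per-vertex white noise, which the generator deliberately avoids.
Seeding is hierarchical: the master seed spawns per-mesh child seeds by
counter, making any subset reproducible.

What the generator does **not** emulate: segmentation artifacts, mesh
irregularity from marching surfaces, spatially correlated measurement
error, or the real (unknown) per-class feature distributions — only
their qualitative ordering.  Passing tests on synthetic populations
therefore validate the machinery, not the biological effect sizes.

## Population statistics

`class_means()`, `ks_compare()` (two-sided two-sample Kolmogorov–Smirnov,
asymptotic p-values by default, exact behind a flag; the tie warning is
suppressed since mesh-derived features are effectively continuous),
`log_transform()` (natural log, column-wise; non-positive values are an
explicit error naming the cells, with an `asinh(x/2)` signed fallback
that must be requested), and `fit_scaling_exponent()` (OLS slope of
$\log\Sigma$ on $\log V$ across individual cells, not class means, since
per-cell scatter is the object of interest).  Geometrically similar
shapes of any family recover the dimensional law
$\Sigma \sim V^{2/3}$ to within 0.02.  Raw KS p-values are reported for
the 7 features (Bonferroni available behind a flag, never default).

## Classification

`classify_cv()` is the package's central fit.  Per run, the data are
split into $k = 10$ stratified folds (stratification is a deliberate
choice: with 51 cells in the minority class, plain random folds — still
available via `stratified = FALSE` — can end up minority-free); each
fold is predicted once by a soft-margin linear SVM (minimize
$\tfrac12\lVert w\rVert^2 + C\sum_i\xi_i$ subject to
$y_i(w\cdot x_i + b) \ge 1 - \xi_i$) trained on the rest.  Defaults and
why:

* **balanced class weights**: per-class penalties inversely proportional
  to class frequency ($n / (2 n_c)$), guarding the 158-vs-51 imbalance;
* **$C = 1$**: the common library default; no hyperparameter search;
* **log space**: feature densities are closer to uniform there;
* **in-fold standardization** (fit on the training folds only): linear
  SVMs are scale-sensitive and the 7 features span different units;
* **prediction** $\hat y = \mathrm{sign}(w\cdot x + b)$ with the tie
  $\mathrm{sign}(0)$ assigned to the positive class (implemented
  directly on the decision values, not via the library's label output);
* **runs**: the headline protocol repeats the random split 1000 times;
  tests use 10–50 runs, which is ample for the contrasts asserted.

Correctness indicators over cells × runs form the binary matrix $B_{ij}$,
from which the framework derives per-cell accuracy
$a_i = \frac{1}{N_r}\sum_j B_{ij}$, class accuracy
$A_C = \frac{1}{|C|}\sum_{i\in C} a_i$ (identical whether cells or runs
are averaged first — asserted to $10^{-12}$), and the threshold ratio
$r_a = |\{i \in C: a_i \ge a\}| / |C|$.  The inclusive $\ge$ is used (a
strict $>$ appears in one formulation, but "equal to or greater" is the
stated meaning); with continuous-valued $a_i$ the difference is
immaterial except exactly at $a_i = a$.  ROC AUC is computed per run on
the pooled held-out decision scores as the Mann–Whitney probability
(ties count ½) and averaged over runs; an alternative — the AUC of the
$a_i$ vector itself — can be computed directly with
`roc_auc(fit$report$a, fit$labels)` for sensitivity analysis.  How a
single AUC should be aggregated across repeated runs is genuinely open;
per-run-then-average was chosen because it matches the run-averaging of
every other quantity in the framework.

`pca_project()` gives the standardized 2-component PCA view (linear or
log space) used to rule out obvious clustering; component signs are
fixed by making the largest-magnitude loading positive.

### Random-forest imbalance comparison

`classify_cv(..., learner = "rf")` runs a random forest under the
*identical* split protocol (same master seed ⇒ same fold assignments, so
differences are learner-only), either with balanced class weights or
with in-fold downsampling of the majority class to minority size.  On a
weak-signal imbalanced population the weighted forest collapses the
minority class (it drifts toward majority voting) while the balanced SVM
and the downsampled forest keep both classes comparable — the
qualitative failure mode that motivates the balanced linear SVM as the
default learner.

## Numerical choices and degenerate inputs

* Validation never throws; it reports closedness, manifoldness,
  orientation consistency, outwardness and the Euler characteristic
  $V - E + F$.  Measures that require closedness (`mesh_volume`,
  `curvature_field`) refuse open meshes with a pointer to
  `validate_mesh()`.
* Quad and general polygon faces are fan-triangulated on load (all
  formulas assume triangles).
* Zero-mean curvature fields make the relative fluctuation undefined;
  this is an explicit error, not an `NaN`.
* `ks_compare` requires ≥ 2 values per class; `classify_cv` requires
  each class to have at least `folds` members (stratification needs one
  per fold) and suggests a smaller `folds` otherwise.

## Problem sizes

The test suite and the acceptance script run entirely on generated
geometry: icospheres at subdivision levels 1–5 (42–10242 vertices),
gridded tori/patches around 10³ vertices, and synthetic populations of
209 meshes at subdivision 2–3 with 10–50 CV repeats — sizes chosen so a
full run takes about a minute on a laptop core while leaving every
asserted contrast far from its decision boundary.

## Known limitations

* Absolute curvature magnitudes of third-party pipelines cannot be
  matched in general — estimator and parameters vary between toolkits —
  so validation rests on analytic limits (sphere, plane, cylinder,
  saddle, Gauss–Bonnet) rather than cross-toolkit agreement.
* The angle-deficit estimator's pointwise values at irregular vertices
  are biased (see above); features built on node averages are
  unaffected, but per-vertex maps exported for rendering will show it.
* The synthetic generator controls qualitative contrasts only; headline
  accuracies measured on it (at or near 100% for the default, clearly
  separated classes) say nothing about accuracy on real acrosomes.
* PLY binary support covers little-endian files; big-endian PLY is not
  read.
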