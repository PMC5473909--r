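# acroshape

3D surface-mesh morphometry and two-class shape classification for sperm
acrosomes (and closed organelle surfaces generally).

During spermiogenesis the acrosome — the vesicle capping the sperm head —
remodels from a near-spherical shape (round spermatids) into a flattened,
hooked cap (mature spermatozoa).  Given closed triangular surface meshes
reconstructed from confocal stacks, `acroshape` provides the downstream
analysis for a semi-automatic classification of that remodeling:

* **Mesh handling**: PLY (ascii + binary little-endian), OBJ and legacy
  VTK polydata readers/writers; topology validation (closedness,
  manifoldness, orientation, Euler characteristic).
* **Morphometry**: the 7-parameter feature vector per cell — volume *V*,
  surface area *Σ*, sphericity *Ψ = π^{1/3}(6V)^{2/3}/Σ*, node-averaged
  mean and Gaussian curvature *M̄*, *Ḡ* (from angle-deficit /
  cotangent-Laplacian discrete operators, with a quadric-fitting
  alternative), and their relative fluctuations *ΔM/M̄*, *ΔG/Ḡ*.
* **Population statistics**: per-class means, two-sample
  Kolmogorov–Smirnov tests per feature, log-space transform, and the
  *Σ ~ V^{2/3}* surface–volume scaling fit.
* **Classification**: repeated stratified 10-fold cross-validated linear
  SVM with balanced class weights (prediction *ŷ = sign(w·x + b)*),
  scored by the per-cell accuracy framework — *a_i* (fraction of runs a
  cell is classified correctly), class accuracy *A_C*, threshold ratios
  *r_a*, run-averaged ROC AUC — plus a random-forest comparison
  (class-weighted or in-fold downsampled) under identical splits.
* **Synthetic populations**: a generator of two-class shape ensembles
  (noisy ellipsoids vs hooked caps, 158/51 cells, 1.5× volume contrast
  by default) so the whole pipeline is testable without microscopy data.

## Worked example

```r
library(acroshape)

# one synthetic spermatozoon-like shape and its feature vector
m <- make_shape("hooked_cap", noise = 0.08, seed = 42)
round(extract_features(m), 4)
#>       V   Sigma     Psi    Mbar    Gbar   dMrel   dGrel
#> 20.2103 46.0629  0.7790  0.6649  0.2245  0.6902  4.7185
```

The hooked cap encloses 20.2 µm³ behind 46.1 µm² of membrane; its
sphericity 0.78 is well below the spherical limit 1, its node-averaged
mean curvature is 0.66 µm⁻¹, and the large relative fluctuations (0.69
and 4.7) reflect the strong curvature heterogeneity of the hook.

```r
# a small two-class population, statistics, and the classifier
pop <- simulate_population(population_spec(n_a = 40, n_b = 20,
                                           subdivisions = 2, seed = 7))
tab <- build_feature_table(pop)

ks_compare(tab, "Psi")
#> KS Psi    D = 1.0000  p = 5.25e-12  (n = 40 / 20)

fit_scaling_exponent(tab)
#> log-log surface-volume scaling: slope 0.9132 (se 0.0364, n 60)

fit <- classify_cv(tab, runs = 50, seed = 1)
fit
#> repeated 10-fold CV SVM (log space, balanced weights, 50 runs)
#> accuracy over 50 repeated-CV runs
#>                A_C r_0.85 r_0.99
#> class A (n=40)   1      1      1
#> class B (n=20)   1      1      1
#> all cells        1      1      1
#> ROC AUC: 1.00
```

The sphericity distributions of the two synthetic classes do not overlap
(KS *D* = 1), so the repeated-CV SVM classifies every cell correctly in
every run — the default synthetic contrast is deliberately clear; real
acrosome populations overlap far more.  The scaling slope over a *mixed*
population (0.91) exceeds 2/3 because the two classes are not
geometrically similar; on similar shapes of varying scale the fit
recovers 2/3 within 0.02 (see the test suite).  `summary()`, `coef()`
(the separating hyperplane), `predict()` and `plot()` methods are
available on the fit.

A command-line wrapper (`inst/exec/acroshape.R`) exposes the pipeline as
`simulate`, `features`, `stats` and `classify` subcommands.

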