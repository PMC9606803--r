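---
title: "Association mapping: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the statistic it
implements, the preprocessing model around it, the synthetic cohort used to
validate it, and the numerical and design choices that were genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The association index

For every in-mask voxel the package builds the whole-brain functional graph:
an undirected edge joins two voxels when the Pearson correlation of their
preprocessed series exceeds a threshold, 0.25 by default. With `N` the
voxel's degree and `K` the number of edges among its neighbors,

$$\mathrm{Asso} = \frac{N(N-1) - 2K}{2} = \binom{N}{2} - K ,$$

the count of neighbor pairs *not* directly interconnected — pairs for which
the voxel is a potential mediator. Degree centrality (`compute_fcs_map()`)
is `N` alone; the association index penalizes it by the local clustering of
the neighborhood. Both are exact integer counts; `compute_asso_map()` is
tested against an explicit brute-force neighbor-pair counter for exact
equality on random graphs.

Choices made here:

* **Signed threshold.** The edge test is `r > 0.25` on signed correlation,
  not `|r|`; anti-correlations do not create edges. A config switch
  (`use_absolute`) provides the absolute variant.
* **Self-exclusion.** A voxel never counts in its own neighborhood.
* **Constant series** (zero variance, e.g. zero-padded mask edges) have
  undefined correlation and are treated as never connected (`N = 0`,
  `Asso = 0`), with a message reporting how many were seen.
* **Threshold is a parameter**, not a claim: the index depends on the 0.25
  default and no threshold-freeness is asserted anywhere.
* `K` is computed from blockwise Boolean matrix products
  (`asso_counts_from_adjacency(block_size = ...)`) so memory stays bounded
  on large masks.

After the per-subject map: z-transformation over the in-mask distribution
(improves normality for the group model), then 6 mm FWHM Gaussian
smoothing of the *map* — the BOLD series itself is not smoothed on this
branch. The seed-FC branch deliberately differs: there the volumes are
smoothed *before* the temporal preprocessing, and the Fisher-z FC map is
not smoothed afterwards. `run_all()` materializes both branches from the
shared volume-dropped input.

## 2. Temporal preprocessing

Order of operations (`preprocess_subject()`): drop the first 10 volumes
(magnetization equilibrium), compute framewise displacement and the scrub
plan on the cropped motion table, detrend, regress nuisance signals,
band-pass, then replace flagged frames by linear interpolation.

* **FD** uses the Power convention: summed absolute translation deltas plus
  rotation deltas converted to mm on a 50 mm sphere. The first frame has
  FD 0.
* **Flagging** applies `FD >= 0.5` mm (the keep criterion is "below 0.5"),
  expanded by 2 frames before and 1 after each bad frame. The window is a
  parameter because conventions differ; the default reflects the common
  reading of "2 before, 1 after".
* **Scrubbing by interpolation, after filtering.** Interpolated frames keep
  the frame count intact, so the correlation window is identical for every
  subject and the zero-phase filter sees an uninterrupted series. The
  scrub-before-filter order is available (`scrub_before_filter = TRUE`) for
  sensitivity analysis. Scrubbing is idempotent under a fixed plan; leading
  or trailing flagged runs take the nearest unflagged value.
* **Nuisance model**: Friston-24 motion expansion (parameters, one-frame
  lags, both squared; lag backfilled with 0) plus WM, CSF and global mean
  frame series — 27 columns. Collinear columns are dropped with a warning
  rather than failing the subject. Global-signal regression is on by
  default and is a flag.
* **Band-pass 0.01–0.1 Hz** as an order-2 Butterworth applied
  forward-backward (zero phase), with odd-reflection padding to tame edge
  transients at these short series lengths. The recursion is vectorized
  across voxels and is tested against the reference single-series filter;
  an ideal FFT filter sits behind `filter_type = "fft"` (it is exactly
  idempotent, which the Butterworth is not).
* **Subject exclusion** ("moved more than one voxel") is evaluated as
  max |translation| or max |rotation|·50 mm exceeding the smallest voxel
  size, and reported per subject rather than silently dropping anyone.

## 3. Group inference

`voxelwise_glm_ttest()` fits, per voxel, an OLS model with intercept, group
indicator (patients = 1) and mean-centered age, sex (M = 1) and education;
the reported t is the group coefficient (it equals the classical pooled
two-sample t when the covariates are absent, which the tests assert at
1e-8). Cluster-forming threshold: two-sided voxel-level p < 0.001 on the t
distribution with n − p df; connected components are labelled at
18-connectivity by default (6 and 26 available), positive and negative
tails separately.

Cluster-level correction is a **label-permutation max-extent procedure**:
group labels are permuted (covariates stay with their subjects), the t map
and its suprathreshold clusters are rebuilt, and the maximum extent over
both tails forms the null; corrected
p = (1 + #{perm max ≥ observed}) / (n_perm + 1), so p is never zero and
fixed seeds reproduce exactly. This choice is assumption-light and honest
at desk scale; parametric random-field corrections would not match it
numerically, which is fine for a method whose validity claim is the
permutation argument itself. Type-I behavior is measured, not assumed: on
20 null cohorts the fraction with any corrected-significant cluster must
stay within binomial slack of the nominal 0.05 (see the acceptance tests).

`summary_ttest()` (pooled-variance t from printed means/SDs) and
`chi_square_2x2()` cover demographic-table statistics; both are thin,
tested wrappers so tables can be reproduced from summaries alone.

## 4. Seed-based FC and biomarker evaluation

The seed is the suprathreshold cluster from the association contrast
(frozen before FC computation); a sphere at a peak coordinate is available
(`sphere_seed()`) since either convention appears in practice. FC is the
Pearson correlation of each in-mask voxel with the mean seed series,
Fisher-z transformed with clipping at |r| = 1 − 1e−7 (`atanh` of the
clipped value ≈ 8.41 marks seed voxels in single-voxel seeds).

Features for classification are cluster means of the association-z and
FC-z maps. The default reproduces the common (and circular) design in
which clusters are defined on the full sample before cross-validation;
this is deliberate — the package exists to reproduce that procedure — but
the honest alternative is available by re-running cluster definition
inside each training fold with the exported stage functions, and the
circularity is flagged here so nobody mistakes the default LOOCV accuracy
for an unbiased generalization estimate.

The classifier is a linear SVM, cost 1, features standardized on each
training fold only; metrics come from pooled held-out predictions, AUC
from held-out decision values with patients as the positive class
(Mann–Whitney formulation with midrank ties; equal to trapezoidal ROC
integration, and cross-checked against an independent ROC implementation
in the tests). One caveat worth stating: on *exactly balanced* samples
with permuted labels, LOOCV sits systematically below 50% (each training
fold's majority class is the wrong class for the held-out subject) — about
44% under the default conditions. Chance-level checks therefore draw
labels Bernoulli(0.5), under which the chance level is exactly 50%.

Brain–behavior correlations are Pearson r with two-sided p per
(feature, score) pair and Benjamini–Hochberg q over the full family tested
in one run; zero-variance inputs are excluded from the family with a
warning rather than contributing meaningless tests.

## 5. The synthetic cohort

No patient data ship with the package, so the generator *is* the
acceptance surface: it must produce data on which every downstream claim
is checkable against known truth.

**Geometry.** A 12×12×12 grid at 3 mm isotropic (affine centred on the
origin); the brain mask is the interior 10×10×10 cuboid (1000 voxels);
eight 3×3×3 regions sit at the brain-mask corners; small WM/CSF blocks
occupy the region-free central band. Axis-aligned cuboids make ground
truth trivially maskable — no anatomical atlas is pretended.

**Signal model.** All latent and noise series are unit-variance AR(1)
(φ = 0.3 by default) plus white innovations. Region r's latent combines a
hub signal H (variance share `hub_coupling`), a neighbor-shared signal S
(`neighbor_coupling_*`), for the two DMN-like regions an extra signal D
(`seed_fc_gain_ad`, patients only), and an independent remainder. Voxels
mix their region latent (share `base_r` = 0.9, the within-region
correlation) with voxel-specific noise, and every in-brain voxel carries a
brain-wide global signal (share `global_amp` = 0.3). Background brain
voxels are global + noise only.

The global component deserves a word: global-signal regression projects
out the brain-mean series, and in a 1000-voxel phantom where the coupled
regions are a fifth of the brain, the community signal would dominate that
mean and GSR would silently remove the planted couplings — an effect we
measured while designing the generator. Real data contain a large
unspecific global component (that is why GSR exists); giving the phantom
one both makes it more realistic and keeps the planted structure
identifiable under the default GSR-on pipeline.

**Planted effects.**

* *Association deficit* at the hub region, through two complementary
  mechanisms: the hub-to-region coupling drops in patients
  (`hub_coupling` 0.25 → `hub_coupling_ad` 0.02), shrinking the hub's
  neighborhood quadratically in `C(N,2)`, and the non-hub regions are
  mutually coupled (`neighbor_coupling_hc` 0.02 → `neighbor_coupling_ad`
  0.15), directly interconnecting the hub's remaining neighbors. Both
  lower hub Asso; the monotone effect of the neighbor coupling on the
  expected patient hub Asso is a tested generator property. The coupling
  drop is the dominant default because, at these series lengths, the
  band-passed noise floor (null correlation SD ≈ 0.16–0.19 at ~40
  effective df) creates enough incidental edges that a pure
  neighbor-closure effect is diluted by open pairs with noise neighbors.
* *Seed-FC increase* from hub to the two DMN-like regions via the shared
  signal D in patients.
* *Motion*: smooth sinusoidal drift plus white jitter, with
  Bernoulli-per-frame translation steps of 1 mm that exceed the 0.5 mm FD
  criterion, so scrubbing is exercised on every subject.
* *Cognition*: each subject's realized hub coupling (group value plus
  N(0, `coupling_sd`) jitter) drives MMSE and MoCA linearly, mapped so the
  group means land on the demographic targets (21.3/28.24 and
  16.92/26.95), clamped to 0–30 and rounded; residual noise SD 1.5. Scores
  therefore correlate with the subject's *brain* parameter, not merely the
  group label, so brain–behavior correlations have a recoverable
  within-sample signal. Age, education and sex are drawn from
  target-matched normals and Bernoulli(0.5), independent of the brain
  model.

**Calibration.** The study conditions are 20 + 20 subjects, t = 120 at
TR = 2 s. The planted magnitudes above were calibrated once, by pilot
simulation during design, so that cluster-level recovery of both effects
has power ≈ 0.9 at those sizes, and then frozen; they are configuration,
not claims about any real effect size. Weak realizations do occur (a hub
t just under the cluster-forming threshold), which is exactly what the
≥ 90% recovery criterion allows for.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamic response dynamics, physiological
(cardiac/respiratory) noise, scanner drift beyond a linear trend, spatial
noise correlations within regions beyond the shared latent, image
registration errors (inputs are assumed on a common grid; realignment and
spatial normalization are out of scope), anatomical geometry, and
non-Gaussian score distributions. Results on the phantom demonstrate
correctness of the machinery under its stated model, not clinical
validity.

## 6. Numerical choices and degenerate inputs

* Voxel indices are 0-based internally; every reported coordinate is mm
  through the NIfTI affine, which all derived maps carry unchanged.
* Maps are written with 0 outside the mask (config for NaN) as 64-bit
  floats, so read-after-write is bitwise exact.
* Fisher-z clipping constant 1e−7; correlations of constant series are 0.
* Gaussian smoothing uses a discrete separable kernel, σ = FWHM/(2√(2 ln 2))
  per axis in voxel units, truncated at 3.5 σ and renormalized; boundary
  handling is `"nearest"` (preserves constants) or `"zero"` (preserves
  total mass).
* The permutation estimator uses the +1 correction; n_perm < 100 is
  refused, and a warning fires when 1/(n_perm+1) cannot resolve the
  requested cluster-level α.
* Degenerate inputs fail loudly with named quantities: motion/BOLD length
  mismatches, empty masks, all-flagged scrub plans, rank-deficient
  designs, zero-variance z-scoring, `K > C(N,2)`.
* Problem sizes used in the shipped tests (the package's own choice of
  desk scale): 12³ grids, 1000-voxel brains, cohorts of 40, 200
  permutations, 20 null and 20 planted cohorts, 50 random graphs of up to
  200 voxels for the brute-force equivalence check.

## 7. Known limitations

Memory for the voxel graph grows as V² (blockwise products bound the
triangle count, not the correlation matrix); masks beyond ~20k voxels need
the block path and patience. The permutation correction is Monte-Carlo,
not exhaustive. The default feature-extraction design is circular by
construction (Section 4). The generator's regions are rectangular and its
noise white-in-space; none of the spatial-statistics subtleties of real
fMRI (autocorrelation-aware cluster inference, non-stationary smoothness)
are modelled, and the cluster correction's validity on real data rests on
the permutation argument, not on anything tested here.
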