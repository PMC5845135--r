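---
title: "Statistical shape analysis of 3D foot scans with footmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of 3D foot scans with footmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Foot morphology is usually quantified from 2D footprints, which discard
the vertical dimension: arch height, instep girth, Achilles tendon shape,
toe height.  Dense 3D surface scans retain that information, but raw scan
meshes cannot be compared vertex-by-vertex — every scan has its own vertex
count, ordering, pose, and size.  `footmorph` implements the full
geometric-morphometrics chain that turns a set of triangulated foot scans
into a statistical shape model and relates subject characteristics to
shape:

1. **Preprocessing** (`mirror_mesh`, `crop_above_ankle`, `measure_foot`):
   left feet are mirrored across the sagittal plane into the right-foot
   frame, scans are cropped just above the ankle (clipping straddling
   triangles exactly at the plane), and foot length/breadth are measured
   as extents along the principal axes of the plantar vertex subset.
2. **Correspondence** (`elastic_register`): one reference mesh is
   deformed onto every scan so all scans share the reference's vertex
   count and ordering, with vertices at matching anatomical positions.
3. **Alignment** (`gpa`): Generalized Procrustes Analysis removes
   position (centroid), size (centroid size), and orientation (optimal
   rotation to the iteratively re-estimated mean).
4. **Shape model** (`fit_pca`): a principal-component point distribution
   model, `X = M + sum_i P_i w_i`, with orthonormal components `P_i`
   ordered by explained variance and per-scan scores `w_i`.
5. **Factor statistics** (`forward_select_pcs`, `fit_factor_model`,
   `posthoc_power`, `pc_factor_correlations`, `deviation_field`,
   `predict_shape`): multivariate linear regression `F = W B + E` of the
   subject factors (sex, age, shoe size, sport hours, BMI, foot loading,
   foot side) on the scores of the BIC-selected components, with post-hoc
   power, per-pair correlations, per-vertex asymmetry/loading measures,
   and factor-conditioned shape predictions exported as per-vertex
   distance maps.

Because no scan data ship with the package, a first-class synthetic
cohort generator (`sample_cohort`) provides foot-like meshes with known
ground truth at every level; all validation rests on it.

## Elastic correspondence

The registration model is `X_target ≈ T(X_reference) + d`: an affine
transform `T` composed with a per-vertex elastic displacement field `d`.
The two parts are solved alternately — `T` by least squares with `d`
fixed, `d` with `T` fixed — under a graph-Laplacian smoothness penalty on
`d` whose weight is `1/beta`.  The elasticity `beta` increases over a
schedule of stages, so early stages are near-rigid and later stages
progressively admit local deformation as the alignment improves.

Engineering choices that proved necessary, and their defaults:

* **Initialization.**  ICP started from the identity stalls in a
  wrong-assignment fixed point when the initial pose offset exceeds the
  mesh sampling distance.  Registration therefore starts by aligning the
  principal-axes frames of the two vertex clouds (axis signs fixed by the
  third moment of the projections — feet are skew along every axis),
  followed by a similarity-constrained ICP phase without matching caps,
  and only then a full affine phase with caps.
* **Symmetric matching.**  Nearest-neighbour constraints are collected in
  both directions (template vertex to nearest target vertex, and target
  vertex to nearest template vertex).  One-way matching leaves the
  template free to slide tangentially along the foot's long axis (we
  measured a systematic ~8 mm drift); reverse matches keep uncovered
  target regions pulling the template back.
* **Caps.**  Matches farther than `nn_distance_cap` (default 15 mm) or
  with normals disagreeing by more than `normal_angle_cap` (default 60
  degrees) are rejected; crop-boundary vertices of the target are never
  match candidates (the boundary is an artifact of the crop height, not
  anatomy).  Template vertices with no accepted match take the
  smoothness-interpolated position, which handles partial overlap at the
  crop boundary.
* **Schedule.**  `beta_schedule = c(0.1, 0.3, 1, 3, 10)` (five stages
  over two decades), at most 12 iterations per stage, and a 0.05 mm
  vertex-motion convergence threshold.  These were tuned on synthetic
  targets for accuracy-per-second; all are exposed in
  `registration_params()`.
* **Determinism.**  Nearest-neighbour ties break to the lowest vertex
  index; the elastic solve reuses one symbolic Cholesky factorization of
  the fixed sparsity pattern.

On remeshed, vertex-shuffled, posed synthetic scans this recovers
ground-truth correspondence to about 2 mm mean error (0.8% of foot
length) at the default 2,500-vertex template.

## Procrustes alignment and the shape model

`gpa` follows the classic three-step scheme: center, scale to unit
centroid size, rotate to the current mean (orthogonal Procrustes with
reflections excluded — left feet are already mirrored), re-estimate the
mean, and iterate to a 1e-10 relative objective tolerance; the whole loop
is repeated with the converged mean as the new reference
(`reference_update_iters`, default 3, mirroring the usual
reference-debiasing practice).  Scale is fixed at unit size after the
scaling step rather than re-estimated inside the rotation loop.  The
arbitrary global orientation of Procrustes space is fixed by rotating the
final mean onto the first input shape, which makes outputs reproducible
without changing any shape relation.

`fit_pca` computes the model by singular value decomposition of the
centered `N x 3V` data matrix (never the `3V x 3V` covariance, which is
infeasible at scan-scale vertex counts).  Score SDs use the `N - 1`
denominator.  Component signs follow a deterministic convention (the
largest-magnitude entry of each component is positive).  The pipeline
re-expresses synthesized shapes in millimetres by multiplying by the mean
centroid size when writing meshes.

## Factor regression

The regression keeps the direction of the underlying model: the factor
matrix is the response, the selected PC scores the predictors, estimated
by ordinary least squares per factor column.  Consequences of that
orientation:

* The BIC used by forward selection is the sum over factor columns of
  univariate Gaussian-likelihood BICs (independent residuals), with
  `k + 2` parameters per column (intercept, `k` slopes, variance).
  Selection is greedy, stops at the first non-improving addition, and
  breaks ties toward the lower PC index.
* Per factor we report R-squared, the overall F-test p-value, and
  post-hoc power with effect size `f2 = R2/(1 - R2)`, noncentrality
  `n * f2`, and `(k, n - k - 1)` degrees of freedom.  The closed form is
  validated against a Monte-Carlo oracle (`mc_power`) to 0.01 absolute.
* Predicting a shape for given factor values (`predict_shape`) requires
  inverting the fitted map; since the model predicts factors from scores,
  the expected scores at a factor setting are obtained with the
  Moore-Penrose pseudo-inverse of the coefficient matrix.  The varied
  factor's low/high settings follow a range rule: 5th/95th percentiles of
  the cohort (or a subgroup) for `"quantile90"` — our reading of a
  "90% contour" when only one factor varies — `mean ± 2 SD`, or the
  observed extremes.
* PC-factor correlation tables default to Pearson (the fitted relation is
  linear), with Spearman available by flag; the choice is a genuine
  ambiguity and both are first-class.  P-values are reported raw with a
  0.05 significance flag and no multiplicity correction, matching the
  tabular convention of morphometric studies.
* All scans enter as independent observations (`n` = scans).  This
  replicates common practice but understates within-subject dependence:
  subject-level factors (sex, age, shoe size, sport, BMI) are constant
  over a subject's four scans, so their effective sample size is the
  number of subjects, and pooled p-values for them are anti-conservative
  (we measure 12-15% type-I at the nominal 5% on synthetic null
  cohorts).  The within-subject factors (loading, side) vary i.i.d.
  across scans and are correctly calibrated in the pooled analysis.  The
  calibrated alternative for subject factors — averaging each subject's
  score rows before selection and fitting — is what the validation
  studies use for subject-level inference; it is also better powered,
  since averaging four scans halves the residual score SD.

The per-vertex **asymmetry** measure is the Euclidean distance between
corresponding vertices of the aligned right foot and mirrored left foot
(at matched loading), and the **loading** measure the same between half-
and full-loaded scans (at matched side).  These per-subject distance
vectors get their own PCA and factor regression
(`deviation_regression`).

A caution established during validation: the select-then-test procedure
is anti-conservative at small samples.  With 62 subjects and ~60
candidate deviation PCs, pure-noise fields lead BIC to admit a PC in
about half of replicate cohorts, and the admitted PC's best factor then
flags at nominal 0.05 far more often than 5%.  At `n = 248` rows the BIC
gate stays shut under the null.  Low-power findings from the deviation
analyses should be read with this in mind.

## The synthetic cohort generator

`sample_cohort` emulates a scan study of healthy adults; its defaults are
the study conditions used throughout the tests:

* 62 subjects, half female, four scans each (left/right x half/full
  load), 248 scans.
* Factor distributions: age truncated-normal 38.9 ± 13.5 in [18, 60];
  shoe size by sex (male 43.9 ± 1.6, female 39.8 ± 2.2, EU, in [36, 46]);
  BMI 23.7 ± 3.5 in [18.6, 35.8] with a planted age correlation of 0.35;
  sport 3.7 ± 4.1 h/week in [0, 15]; weight derived exactly from BMI and
  height.  The sex/shoe-size confound (t-test separation) and the
  age/BMI correlation reproduce the dependence structure such cohorts
  show.
* Six deformation modes built from smooth anatomical fields (arch height,
  ball width + toe spread, global width, hallux angle, hallux-vs-second-
  toe length, midfoot width), orthonormalized after projecting out the
  similarity tangent space (translations, rotations, uniform scaling).
  The projection matters: a "global width" field is partly a uniform
  scaling, which Procrustes normalization would remove, and leaving it in
  mixes the recovered components.  Pure-shape modes are also what a shape
  mode ought to be.
* Mode weight SDs `c(60, 40, 30, 22, 16, 12)` (strictly decreasing so PC
  order is identifiable); weights are `t(B) z + e` with `z` the
  standardized factors and `e` drawn per scan.  Drawing the residual per
  scan (rather than per subject) makes the scan-level covariance
  converge to the configured value and matches the pooled-scan
  regression; the cost is that the generator has no true repeated-
  measures structure — a stated difference from real cohorts.
* The default effect matrix activates three factors, each driving mainly
  one mode (sex on mode 1, shoe size on mode 2, sport on mode 3) with
  amplitudes 25/15/12: strong enough for near-certain detection at 248
  scans, weak enough not to disturb mode recovery.
* A bilateral-asymmetry field (per-subject amplitude, SD 2) applied with
  opposite sign to the two sides, and an arch-flattening loading field
  (weight 6) applied to fully loaded scans; both orthogonal to the six
  modes.
* Per-vertex Gaussian measurement noise at 0.3 mm (the accuracy class of
  laser foot scanners), a random similarity pose per scan (up to 10
  degrees, 30 mm, 3% scale), and optional remeshing: the same continuous
  template surface triangulated at a 1.31x vertex budget, displaced by
  barycentric interpolation of the deformation, then vertex-shuffled.
  The analytic variance budget of these defaults puts just over 92% of
  scan-to-scan variance in the six modes, which is what the shape model
  recovers.

What passing tests on this cohort do show: the registration, alignment,
model, and inference machinery recover known truth under realistic noise,
pose, and retriangulation.  What they do not show: performance on real
scanner artifacts (holes, outliers, soft-tissue motion), non-linear
factor effects, or cohorts whose shape variation departs from the
six-mode linear model.

## Numerical choices and degenerate inputs

* Cropping clips triangles against the half-space so boundary vertices
  lie exactly on the plane; a cut at or above the mesh maximum returns
  the mesh unchanged, at or below the minimum is an error.
* The plantar band for measurements is `z <= min(z) + 3 mm` (a scanner
  resolution); the measurement is invariant to rigid motions preserving
  the vertical axis.
* STL stores float32 by the format standard; OBJ and ASCII PLY are
  written with enough digits for 1e-6 mm round-trips, binary PLY stores
  doubles exactly.  STL round-trips are bit-stable after the first
  quantization.
* `scale_to_unit` rejects zero-size shapes; `optimal_rotation` rejects
  rank-deficient (collinear) configurations; `fit_factor_model` names the
  collinear columns when the design is rank-deficient.
* Shape vectors are the column-major vectorization of the `V x 3`
  coordinate matrix everywhere.

## Problem sizes used by the test-suite studies

The validation studies run at sizes chosen to exercise the full method on
a desktop: registration accuracy on 20 remeshed scans at the default
2,500-vertex template; shape-model recovery on the full 62 x 4 cohort;
factor-effect recovery on 20 replicate cohorts at a 300-vertex
resolution (mode recovery is resolution-independent, so the replicates
trade vertices for replication); power calibration with 50,000
Monte-Carlo datasets per grid point; correlation calibration with 10,000
null pairs.

## Known limitations

* The template is stylized: toe lobes, arch, heel, and ankle stub are
  plausible but not anthropometric; absolute measurements (for example
  the ~101 mm breadth) are not calibrated to shoe-last standards.
* Correspondence assumes the target is a complete foot surface in
  roughly canonical orientation after principal-axes initialization;
  partial scans or scans dominated by non-foot geometry will misalign.
* The regression is linear throughout, with no interactions, matching
  the modelling scope of the morphometric studies it implements.
* Select-then-test p-values are anti-conservative at small n (see
  above); power values are post-hoc by construction and inherit the
  usual caveats of observed power.
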