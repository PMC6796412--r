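---
title: "Knowledge-based plan parameter prediction for lung SBRT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based plan parameter prediction for lung SBRT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbplan)
```

## The planning problem

Stereotactic body radiotherapy (SBRT) for early-stage non-small-cell lung
cancer delivers an ablative dose (here 50 Gy in 5 fractions, prescribed so
that the prescription dose covers 95% of the planning target volume, PTV)
with steep gradients into the surrounding lung. Two per-patient decisions
dominate the quality of a volumetric-modulated arc therapy (VMAT) plan and
normally require an experienced planner:

1. **the arc geometry** — the start and stop gantry angles of the (partial)
   arcs, chosen from the tumour's position within the thorax; and
2. **the lung-dose objectives** — the mean lung dose (MLD) and the lung
   V10/V20 that are *achievable* for this particular anatomy, used as
   optimization objectives so the optimizer is neither under- nor
   over-constrained.

`kbplan` treats both as supervised-learning problems over a library of
historical expert plans: plan parameters are regressed on anatomical
geometry features, and the fitted models turn a new patient's structure set
into a complete plan-parameter specification. Everything downstream of that
specification — inverse optimization, dose calculation, MLC sequencing — is
the job of a treatment planning system and is out of scope here.

## Geometry features

Eleven scalar features are extracted from the binary masks of the PTV, the
lung and the heart (`compute_features()`): the three volumes
(`V_PTV`, `V_Lung`, `V_Heart`), the 3D Euclidean distances between the PTV
mass centre and the lung / heart mass centres (`D_PL`, `D_PH`), the overlap
lengths of the PTV with lung and heart along the superior-inferior axis
(`OVZ_PL`, `OVZ_PH`), and the per-axis offsets of the PTV centre from the
lung / heart centres (`X_PL`, `Y_PL`, `X_PH`, `Y_PH`).

Design choices where the problem was genuinely open:

* **Mass centres are unweighted binary-mask centroids.** No CT-density
  weighting is applied; only masks are assumed available.
* **Per-axis offsets are signed** (PTV minus organ). The sign is what
  plausibly drives the left/right arc choice; absolute offsets would fold
  mirrored anatomies onto each other and discard exactly the information the
  angle models need.
* **Axis convention is fixed** (x left-right, y anterior-posterior,
  z superior-inferior) and validated at ingestion, because signed offsets
  are meaningless without it.
* **z extents** use the occupied-slice interval widened by half a voxel at
  each end, so a one-slice structure has extent `dz` and results are
  consistent across resolutions.
* Voxel `i` (1-based) is centred at `origin + (i - 0.5) * spacing`; all
  eleven features are invariant under rigid translation of the grid.

## Feature selection

Spearman's rank correlation of each feature against each of the five targets
screens out irrelevant features (`spearman_correlations()`,
`select_features()`): a feature is retained for a target *group* (angle
group: start/stop; dose group: MLD/V10/V20) iff P <= 0.05 for at least one
target in the group. P values use the large-sample t approximation by
default — adequate at the library sizes this method is designed for
(n = 125) — with a permutation option for small cohorts. On the published
clinical screen of the 125-plan library (shipped as
`inst/extdata/clinical_correlation_screen.csv`), the rule retains
`D_PL, D_PH, X_PL, Y_PL, X_PH` for the angle group and
`V_PTV, V_Lung, D_PL, D_PH, OVZ_PL, OVZ_PH` for the dose group, and excludes
`V_Heart` and `Y_PH` entirely.

## Regression models

One independent epsilon-SVR per target (five models), for three reasons: the
clinical evidence reports per-target errors; the angle and dose groups use
different feature sets; and independent models keep the failure modes
legible. The epsilon-insensitive loss is a deliberate match to the data:
expert plans are not unique — two planners produce slightly different but
equally acceptable parameters — and errors below the tube width should not
be penalized.

Training (`fit_svr_grid_loo()`):

* Features are standardized to mean 0 / unit *population* variance with
  training-set statistics only; targets stay in native units.
* An exhaustive grid search over kernel in {RBF, linear},
  C in {0.1, 1, 10, 100}, epsilon in {0.01, 0.1, 0.5, 1} and RBF width in
  {scale heuristic, 0.01, 0.1, 1} scores every point by leave-one-out (LOO)
  cross-validation (negative LOO RMSE); ties go to the first point in
  declared grid order, making the search deterministic. A compact grid
  (`svr_grid_compact()`) is provided for repeated simulation studies.
* The winning point is refit on all cases; the stored model keeps the
  support-vector expansion explicitly, so models serialize to versioned
  JSON (17 significant digits) and round-trip bit-exactly with no binary
  artifacts.

**Angles are regressed as plain scalars in [0, 360).** The screening step
correlates raw angles, and clinical arcs live in a band far from the 0/360
discontinuity, so scalar regression is well posed; a circular RMSE (wrapped
differences in (-180, 180]) is available for *reporting* wraparound-robust
errors, but a circular regression mode is deliberately not implemented.

Post-processing of predictions (`predict_plan_parameters()`) restores
physical ranges the independent models cannot guarantee: angles are reduced
modulo 360, MLD is floored at 0, V10/V20 are clipped to [0, 100], and V20 is
clamped to V20 <= V10 (a DVH identity: volume receiving 20 Gy cannot exceed
volume receiving 10 Gy). Every adjustment is logged.

## Plan specification and evaluation

`assemble_plan_spec()` merges the per-patient predictions with the invariant
protocol template (`default_plan_template()`): 50 Gy / 5 fractions at 95%
PTV coverage with a 150% maximum-dose cap; two coplanar arcs at 4 degree
control-point spacing, collimator and couch 0; and the clinical dose
criteria (PTV Dmin > 45.5 Gy, Dmax < 70 Gy, Paddick CI > 0.8; maximum doses
bronchus < 30, esophagus < 32.5, spinal cord < 30, rib < 54, heart < 30 Gy;
lung mean < 5 Gy, V10 < 15%, V20 < 10%). Serial-organ objectives are kept
constant by design: the marginal benefit of individualizing them is small,
and a fixed template keeps the automated procedure simple and auditable.
Constraint inequalities are strict — a metric exactly at its bound counts as
a violation. A predicted arc span outside a 180-300 degree sanity window
triggers a warning and, optionally, a clamp into the historical 220-260
degree range. PTV coverage is enforced by normalization
(`normalize_to_coverage()` rescales the grid so D95% equals the
prescription exactly; the operation is exactly idempotent because the DVH
interpolation is linear in dose) rather than checked as a constraint.

Evaluation metrics follow the standard definitions: Vx is the percentage of
ROI volume receiving >= x Gy; Dp is the largest dose covering at least p% of
the volume, linearly interpolated between adjacent sorted voxel doses;
homogeneity index HI = (D2% - D98%) / D50%; Paddick conformity index
CI = TV_PIV^2 / (TV x PIV) at the prescription isodose. Dmin/Dmax are true
voxel extrema, not percentile surrogates, since the clinical criteria list
them separately from HI. Dose and mask grids must be co-registered; a
mismatch is an error, never a silent resample, to avoid interpolation bias.
Cohorts of plans are compared index-by-index with the paired Wilcoxon
signed-rank test (exact distribution up to n = 25 without ties, normal
approximation with continuity correction above).

## The synthetic cohort generator

No clinical structure sets are distributable, so `generate_anatomy()`,
`generate_ground_truth()` and `generate_dose_grid()` produce a fully
synthetic testbed at the study scale (125 training + 30 test cases by
default):

* **Anatomy**: two lung ellipsoids with jittered sizes/positions, a heart
  ellipsoid carved out of the lung, and a spherical PTV placed strictly
  inside one lung at a random eccentric position. PTV volumes are drawn
  log-uniformly over the clinical range 3.19-357.20 cm^3 (truncated to what
  fits in the hosting lung). The heart's anterior-posterior centre is drawn
  *correlated with the tumour's* (full tracking plus independent jitter):
  this makes the tumour-heart offset `Y_PH` statistically independent of the
  tumour-lung offset `Y_PL`, reproducing the clinical finding that `Y_PL`
  carries beam-angle information while `Y_PH` and `V_Heart` carry none.
* **Ground truth**: a documented closed-form mapping
  (`default_target_mapping()`) — bounded `tanh` terms over normalized
  features — encodes the clinically observed monotone structure: lung dose
  burden rises with `V_PTV` and `OVZ_PL` and falls with `V_Lung`, `D_PL`,
  `D_PH`; arc angles rise with `X_PL`, `Y_PL`, `X_PH` and fall with `D_PH`.
  The mapping is low-order on purpose: recovery experiments must test the
  pipeline, not the capacity limit of the regressor. Gaussian noise emulates
  planner-to-planner variability with SDs chosen to echo the prediction
  errors reported clinically (15 and 10 degrees for start/stop, 0.8 Gy MLD,
  3.0% V10, 1.71% V20); the V10/V20 draws are correlated (rho = 0.8) because
  a hot plan is hot at both dose levels. Angle ground truth stays inside a
  wraparound-free band so scalar regression is well posed.
* **Dose**: an analytic stand-in for an optimized dose — prescription
  plateau with a mild parabolic central boost (noiseless maximum 125% of
  prescription, inside the 150% cap) and exponential radial falloff
  (12 mm length constant) outside the PTV, optional log-normal voxel noise,
  normalized to D95% = 50 Gy.

Everything derives deterministically from `(master seed, case index)`, so
cohorts are reproducible case-by-case and a run manifest of checksums
suffices to verify a rerun bit-for-bit.

**What the generator does not emulate** — and hence what passing tests do
not show about clinical data: real CT intensities, irregular tumour shapes,
lung heterogeneity and atelectasis, respiratory motion, and genuinely
optimized dose distributions that bend around serial organs (the isotropic
falloff means some synthetic plans violate serial-organ limits that a real
optimizer would respect). Recovery results certify the pipeline's
statistical machinery at the study's scale and noise level, not clinical
performance.

## Numerical choices and degenerate inputs

* Dp interpolation is linear on the empirical cumulative curve; p below the
  first sampled coverage returns the maximum voxel dose, p = 100 the
  minimum.
* Zero-variance feature columns abort standardization with the column named;
  constant targets yield a constant predictor with a warning; a constant
  screening column is reported non-significant with a warning.
* Empty prescription isodose gives CI = 0 with a warning; D50% = 0 makes HI
  an error; an all-zero PTV dose makes normalization an error.
* Grid-search ties are broken by declared grid order; LOO per-fold
  predictions are computed with the held-out case fully excluded (verified
  by a fold-isolation test).
* All-zero paired differences give Wilcoxon P = 1 flagged degenerate.

## Problem sizes used by the test-suite experiments

The suite's simulation studies run on a 64 x 64 x 54 grid at 4.5 mm spacing
(the package default is 96 x 96 x 80 at 3 mm): correlation-structure checks
on a 500-case cohort, noise-recovery checks on 400 cases, and the
parameter-recovery experiment on ten independent 125/30 cohorts with the
compact hyperparameter grid. These sizes give stable statistics (rank
correlations resolve to about +/-0.05, RMSE ratios to a few percent) while
keeping a full run of the suite inexpensive.

## Known limitations

* Start and stop angles are modelled independently; nothing constrains the
  predicted span beyond the sanity window (the clamp is opt-in).
* The screen tests marginal rank correlations only; a feature relevant only
  jointly would be dropped. This mirrors the method being implemented.
* Serial-organ dose objectives are template constants; patients with a
  tumour abutting the chest wall may need individualized rib objectives.
* The exact-Wilcoxon path requires untied non-zero differences; with ties it
  falls back to the normal approximation, as standard.
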