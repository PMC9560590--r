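---
title: "Auditing DBS electrode accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DBS electrode accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsaudit)
```

## Why this package exists

Deep brain stimulation (DBS) for Parkinson's disease places one electrode
per hemisphere into the subthalamic nucleus (STN) or the internal globus
pallidus (GPi).  How close the implanted lead ends up to the planned
target — and what drives it off target — is a key surgical audit
question.  Image-based localisation pipelines answer it by reconstructing
the electrode from post-operative CT, normalising everything to a
standard space, and measuring the electrode against an atlas segmentation
of the nucleus and its motor sub-territory.

`dbsaudit` packages the quantitative core of such an audit as tested,
reusable functions: the accuracy metrics, pneumocephalus and brain-shift
quantification, a simplified volume-of-activated-tissue (VAT) field
model, the standard statistical battery, and — because patient imaging
is not shareable — a synthetic cohort generator that produces complete
subjects with known ground truth, so every metric can be validated by
parameter recovery rather than by eye.

## Accuracy metrics

Two complementary definitions are implemented, both in world millimetres
(RAS+; X lateral, positive right; Y anterior; Z superior):

* **Boundary distance** (`boundary_distance`): the shortest Euclidean
  distance between *any* electrode contact centre and the surface of the
  target region.  A contact centre inside a labelled voxel gives exactly
  0 — an electrode inside the nucleus is on target, which is why cohort
  means of a fraction of a millimetre are attainable.  Signed penetration
  depth is available as an opt-in diagnostic (`signed = TRUE`).
* **Centroid offset** (`centroid_offset`): the displacement of the
  electrode from the centre of gravity of the target region, decomposed
  into X/Y/Z for target plots and per-axis variance analysis.  The
  reference contact is the contact nearest the centroid, paralleling the
  "any contact" convention of the boundary metric; the metric itself
  does not name a canonical contact, so this choice is the package's.

The boundary distance is computed from an exact Euclidean distance
transform (Felzenszwalb–Huttenlocher, anisotropic spacing, compiled) of
the labelled voxel set, sampled at the contact positions with trilinear
interpolation.  The test suite checks it against a brute-force scan over
surface voxels (a labelled voxel with at least one unlabelled
6-neighbour) on randomly generated ellipsoids, to within one voxel
diagonal, and checks invariance under rigid motions applied jointly to
electrode and volume.  The distance transform requires orthogonal grid
axes (rigid motion plus per-axis scaling of the voxel lattice); sheared
affines are refused.

Outliers are flagged with a one-sided Tukey rule (above
`Q3 + 1.5 * IQR`); distances are non-negative, so only the high side is
meaningful.  The boxplot convention behind published raincloud plots
never states its rule, so the conventional 1.5 IQR criterion is used.
"Within target" counts use the boundary distance with a configurable
threshold defaulting to 2 mm, the conventional clinical revision
threshold.

## Brain shift and pneumocephalus

Intraoperative brain shift is compensated in localisation pipelines by
an additional linear registration of subcortical structures ("subcortical
refine", SCRF).  The package treats the SCRF as a given 4x4 affine:
`apply_scrf` maps an electrode through it, and every accuracy table is
emitted with and without it (the `SCRF`/`nSCRF` variants), so the effect
of the refinement itself is auditable.

The shift *magnitude* (`shift_magnitude`) is the summed elementwise
absolute deviation of the matrix from identity over the 12 active
elements.  This matches the "summed transformation matrix" convention of
shift reporting; it is zero exactly at identity and increases linearly
along a translation ray, but deliberately mixes unitless rotation terms
with millimetre translations — it is a proxy, not a distance, and is
documented as such.  Where a study does not state whether one or both
hemispheres enter the summary, the package averages the two hemisphere
magnitudes (configurable by calling `shift_magnitude` directly).

Pneumocephalus is the difference between an expected (template) brain
volume and the actual extracted brain volume, in mL
(`pneumocephalus_volume`).  Real segmentations can exceed the template;
the negative case is clamped to zero with a warning because the
definition ignores it.

## The VAT field model

The clinical VAT is produced by a finite-element model on a tetrahedral
mesh with four compartments (grey matter, white matter, conducting and
non-conducting electrode parts), thresholding the field magnitude at
0.2 V/mm.  `dbsaudit` implements the same contract on the regular voxel
grid with a finite-difference discretisation: `solve_potential` solves
`div(sigma grad V) = 0` with the active contact held at the stimulation
amplitude and the domain boundary grounded, using successive
over-relaxation with harmonic-mean face conductances.  This is a
desk-scale stand-in for the meshed solver — same compartments, same
threshold, same overlap definition — chosen because the regular-grid
solver is a few hundred lines, exactly testable against closed forms,
and fast enough to run a whole cohort.

Defaults (all configurable): conductivities 0.33 / 0.14 / 1e8 / 1e-6 S/m
(grey / white / contact metal / insulation) — conventional isotropic
values; monopolar stimulation against the grounded outer boundary; a
40 mm cube at 0.5 mm spacing around the active contact; convergence when
the maximum voxel-equation imbalance (normalised by its diagonal) falls
below 1e-6 of the amplitude.  The relaxation factor defaults to the
near-optimal `2 / (1 + sin(pi / n))`, giving convergence in roughly 200
sweeps.

Validation uses the one closed form available: a spherical contact of
radius $r_0$ at amplitude $V_0$ inside a grounded spherical shell of
radius $R$ in homogeneous tissue, where
$V(r) = V_0 \, (1/r - 1/R) / (1/r_0 - 1/R)$.  As $R \to \infty$ this is
the point-source (monopole) law $V_0 r_0 / r$; at finite $R$ the
correction term is *not* negligible (tens of percent at mid radii), so
the tests compare against the shell solution — the analytic solution of
the problem actually solved — and additionally check the activation
radius against the monopole prediction
$r_{VAT} = \sqrt{V_0 / (1/r_0 - 1/R) / 0.2}$, which is insensitive to
the ground because the constant drops out of the gradient.  Agreement:
potential within 5% (measured ≤ 2.5%) at radii 2–12 mm on a 0.5 mm
grid, activation radius within one voxel, and halving the grid spacing
moves the radius by under 5%.

Overlap of the binarised VAT with the nucleus and its motor
sub-territory (`vat_overlap`) is a voxel count times voxel volume plus
the covered fraction, with atlas labels resampled onto the solver grid
by nearest neighbour.

## Statistical battery

All tests are two-sided and wrap the reference implementations in
`stats` (`t.test`, `oneway.test`, `cor.test`, `lm`, `p.adjust`) behind
uniform contracts with explicit degenerate-input behaviour:

* `paired_t`: all-zero differences are a genuine "no change" (t = 0,
  p = 1); non-zero constant differences are undefined and error.
* `two_sample_t`: pooled-variance Student t (df = n1 + n2 - 2), the
  convention implied when 60 + 60 observations print df = 118.
* `anova_oneway`, `pearson` (with `r_squared`), `glm_fit` (OLS,
  intercept always included, rank deficiency errors naming the collinear
  columns), `bonferroni` (`min(1, m p)`).
* `required_n_correlation`: Fisher z sample-size formula
  `n = ceil(((z_{1-a/2} + z_{power}) / C)^2 + 3)`,
  `C = atanh(r)`; its inverse `power_correlation` is used in tests to
  verify minimality of the returned n.

The Bonferroni family is always explicit: `stat_table` applies one
shared family across a reporting table and logs it in the `family`
column; the accuracy–shift–pneumocephalus analysis uses a family of 3
(its three pairwise tests) by default.  Calibration is tested by
simulation: 2000 seeded null replicates per test must reject at
0.05 ± 0.02.

## The synthetic cohort generator

The generator's defaults encode the study conditions the analysis is
meant to exercise, and they are fixed once:

* 38 subjects, GPi:STN mix 15:23 (per-subject Bernoulli draw with
  p = 15/38, so that subject k is invariant to cohort size).
* Atlas: axis-aligned ellipsoids per hemisphere — GPi ≈ 470 mm³ and
  STN ≈ 160 mm³ per side (order-of-magnitude anatomical volumes), at
  roughly standard-space positions, inside an ellipsoidal brain mask.  The motor sub-territory
  is the posterior half (STN) or posteroventral half (GPi) of the
  ellipsoid — a geometric stand-in for a functional atlas subdivision.
* Electrodes: the planned target is the centre of gravity of the motor
  sub-region; the realised position displaces the most distal contact
  from it by a per-stratum Gaussian (hemisphere x nucleus), with the
  right-hemisphere (second-implanted) X standard deviation multiplied by
  2 by default.  Gaussian per-axis noise is the simplest model that
  supports the lateral-variance manipulation.  Default SDs: 0.3 mm per
  axis (STN), 0.6/0.5/0.5 mm (GPi), means zero — calibrated so that GPi
  implants are noisier than STN ones and most electrodes stay inside
  the nucleus, reproducing sub-millimetre cohort means.
* Post-operative state: a spherical air cavity of Uniform(0, 25) mL
  carved from the frontal (most-anterior third) brain mask — per-subject
  air volumes are not published, so the range is a free choice in the
  clinically reported range of tens of mL; small rigid SCRF transforms
  (1 mm / 1 degree SDs).  The recorded truth is the *actual carved*
  voxel volume, so recovery tests are exact, not approximate.
* Outcomes: pre scores Gaussian around published baselines; post =
  pre x (1 + pct/100) with the percentage drawn per score.  Published
  outcome tables print mean (± 2 SD), so generator SDs are half the
  printed dispersion.  LEDD effects are nucleus-specific (−54.3% STN,
  +0.9% GPi); all scores floor at 0.
* Determinism: a single root seed expands into per-subject, per-stage
  substreams; identical configuration and seed give byte-identical
  cohorts, and subject k's record does not change when `n_subjects`
  grows.

What the generator does *not* emulate: image intensities, CT metal
artifact, nonlinear deformation, registration error, atlas–anatomy
mismatch, or any correlation between displacement and shift /
pneumocephalus (they are independent streams by default).  Passing
parameter-recovery tests therefore demonstrates that the *metrics* are
correct and unbiased, not that real-world accuracy estimates are —
real data adds every one of those unmodelled error sources.

## Pipeline, attrition and problem sizes

`run_pipeline` chains simulate → metrics → volumetry → VAT → statistics
→ report, writes one tidy CSV per analysis (accuracy per electrode x
reference x SCRF state, stratified summaries, target plots,
shift/pneumocephalus correlations, outcome tables and tests, VAT
overlaps, outcome GLM) plus a manifest with the seed and versions, and
aborts with the stage name (leaving an `INVALID` marker) on any stage
failure.  `simulate_failures` reproduces pipeline attrition by excluding
randomly chosen subjects at the registration or VAT stage; only
completers enter downstream tables.  Underpowered analyses are skipped
with a message (the LEDD nucleus contrast needs both groups, the
outcome GLM at least five STN completers) rather than erroring, mirroring
how audits drop strata with insufficient data.

The left hemisphere is always implantation order 1; every table carries
both hemisphere and order so "second electrode" analyses are
unambiguous.

Problem sizes: the package's test suite runs cohorts of 2–10 subjects
on an 80x92x80 1 mm grid with VAT at 1–1.25 mm spacing, plus one
200-subject generator run for parameter recovery; a full default run
(38 subjects, VAT at 0.5 mm) completes in a few minutes on one CPU.
These sizes were chosen to keep the whole validation suite fast while
exercising every code path at full fidelity.

## Known limitations

* Directional leads are modelled as rings at each contact level; segment
  azimuths and current steering are out of scope, as the accuracy
  metrics are purely positional.
* The shift magnitude mixes units (see above) and is only a proxy.
* The finite-difference VAT ignores tissue anisotropy, capacitive
  effects and pulse-width dependence; it matches the meshed model's
  contract, not its microstructure.
* The atlas is geometric; no claim is made about anatomical shape
  fidelity beyond volumes, laterality and sub-territory topology.
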