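---
title: "radnorm: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radnorm: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A radiomic feature extracted from a CT volume of interest (VOI) is a
function of three things: the underlying tissue texture, the number of
voxels `N` the VOI happens to be sampled with, and the number of gray
levels `d` the intensities are discretized to. Only the first is of
biological interest. `N` is set jointly by the physical VOI volume and the
reconstruction voxel size `V_s(P, T) = P·P·T` through the identity

$$N(P, T) = \mathrm{VOI} / V_s(P, T),$$

which the package enforces exactly: every `voi_mask` stores both `N` and
`voi_volume = N·P·P·T`, and the residual of this identity is asserted to
$10^{-6}$ throughout the test suite, including after resampling.

Features whose defining sums run over voxels (Intensity-Energy $\sum I^2$,
total gray-level variation), over runs (GLRLM-GLNU, GLRLM-RLNU) or over
neighborhood difference sums (NGTDM Coarseness, Texture Strength) scale
with `N` — directly or inversely — irrespective of texture. Features built
on discretized levels scale with `d`: entropy-type features grow like
$\log_2 d$, level-average-type features like $d$, squared-level and
squared-difference features like $d^2$. The package's purpose is to expose
these dependencies experimentally and remove them by per-feature
normalization:

* voxel size: exactly one of $f_n = f\,N$, $f_n = f/N$, $f_n = f/\log N$
  (natural log) per feature; 10 of the 24 features carry a rule;
* gray level: $f_n = f / g(d)$ with $g \in \{1, d, d^2, \log_2 d\}$; 17 of
  the texture features (9 GLCM, 3 GLRLM, 1 GLSZM, 4 NGTDM) are in the
  panel.

Both assignments live in one editable table, `feature_definitions()`. The
rule-to-feature map is a declared default chosen by scaling analysis of
each formula (e.g. $\sum I^2 \propto N$ hence `divide_N`; Coarseness
$\propto 1/(\sum_i p_i s_i)$ with $s_i$ an un-normalized per-level sum,
hence `multiply_N`; entropies $\propto \log_2 d$ hence `log2d`). Users with
a different convention can pass an edited table to the normalization
functions.

## Feature formulary

The 24-feature panel comprises 4 intensity-histogram features, 11 GLCM, 4
GLRLM, 1 GLSZM and 4 NGTDM features. Conventions that the field leaves
open, fixed here once:

* **3D throughout.** GLCM pairs and GLRLM runs use the 13 unique lattice
  directions at Chebyshev distance 1 (in voxel units, not mm); GLSZM zones
  and NGTDM neighborhoods use 26-connectivity. A 2D slice-wise mode is out
  of scope.
* **GLCM aggregation.** Per-direction count matrices are symmetrized
  (each ordered pair counted once per orientation), normalized, and
  averaged over the directions that contain at least one in-mask pair;
  pooled-count aggregation (`"merge"`) is available. Sum/difference
  marginals $p_{x+y}, p_{x-y}$ are derived from the averaged matrix.
* **Sum/Difference Variance** are mean-centered (second moment about the
  sum/difference average), not entropy-centered.
* **GLRLM aggregation** sums run counts over the 13 directions (averaging
  available); runs are maximal and confined to the mask.
* **NGTDM neighborhoods** are restricted to in-mask voxels, so small or
  irregular VOIs remain usable; voxels with no in-mask neighbor are
  excluded from `N_valid`. `ε = 10⁻⁶` guards the Coarseness and Strength
  denominators, so a perfectly homogeneous VOI returns Coarseness
  `1/ε = 10⁶` with the degenerate value well-defined.
* **Entropies** are in bits ($\log_2$); the voxel-size rule's $\log N$ is
  natural — the choice of base rescales values but leaves every rank-based
  and ICC analysis unchanged.
* **Discretization** is equispaced over the VOI min–max
  (`level = 1 + floor(d·(I − I_min)/(I_max − I_min))`, clamped at `d`),
  matching relative-binning practice; a fixed-HU-range mode is available
  as a config alternative. A constant VOI discretizes to level 1 with a
  warning rather than an error. `d = 64` is the default for the voxel-size
  experiment — the printed choice for GLRLM/GLSZM/NGTDM, extended to GLCM
  for uniformity since no separate GLCM value is stated anywhere.

## Resampling design

`resample_volume()` is trilinear interpolation on the voxel-center
lattice: the output grid shares the input origin, covers the input extent
(`n_out = ceil((n_in − 1)·s_in/s_out) + 1`), and clamps out-of-support
queries to edge values rather than extrapolating. Resampling to the native
spacing is the exact identity, and the interpolation is exact on affine
intensity fields — both are tested. Masks are interpolated as 0/1 fields
and re-thresholded at 0.5 (nearest-neighbor lookup available), which
preserves physical VOI volume within 10% across the default grid on
smooth convex masks (measured ≤ 6% on ellipsoids).

The default experimental grid is one-factor-at-a-time: pixel sizes
{0.58, 0.78, 1.17, 1.38} mm at the original slice thickness and slice
thicknesses {1, 1.5, 2, 2.5, 3.5, 4} mm at the original pixel size, which
together with the original yields 11 data sets per subject and hence
198 / 88 data sets for an 18-subject cohort / 8-scanner phantom. Only the
range endpoints and counts of this grid are prescribed; the interior
values are package defaults and are configurable. Note that the 1.17 mm
entry coincides with the default original pixel size, so that variant is
an identity resample — it is still a distinct data-set row, keeping the
bookkeeping counts exact.

## Robustness statistics

`spearman_abs()` ranks with average ties and returns `|r_s|` plus a 95%
Fisher-z interval on the signed coefficient (`SE = 1/sqrt(n − 3)`).
Categories: no (< 0.5), moderate, high (> 0.9); boundary values fall in
the middle class, since the source inequalities are strict and leave the
boundaries unassigned.

`icc_consistency()` implements the two-way consistency ICC without
replication:

$$ICC = \frac{BMS - RMS}{BMS + (d - 1)\,RMS},$$

with `BMS` the between-subjects mean square and `RMS` the residual after
removing subject *and* level effects; the 95% CI uses F-distribution
bounds on `BMS/RMS` with `(n−1, (n−1)(d−1))` degrees of freedom. Negative
ICCs are legitimate outputs (within-subject disagreement exceeding
between-subject spread) and are exercised in the tests. Two consequences
of the two-way choice are worth understanding when reading reports:

* any change that is *additive and common across subjects* (such as a
  level-column shift) is absorbed into the level effect and does not
  lower the ICC — the statistic is also invariant under global rescaling,
  so normalization by a *constant* never changes it;
* non-normalized entropy-type features, which grow almost additively in
  $\log_2 d$, can therefore score a *high* consistency ICC even though
  their raw values vary by over 100% across the ladder. Gray-level
  normalization is still what makes the values themselves comparable
  across studies; for entropy-type features its effect shows in the value
  scale, not always in the consistency ICC. A one-way ICC (level effect
  counted as error) would rank these features differently; the two-way
  form was chosen because it is what the formula above states and what
  the operation's contract and invariants (level-shift invariance,
  negative-value examples) require.

## The synthetic cohort

No patient or phantom scans are distributable, so the package ships a
generator whose output is a *stand-in*: a stationary Gaussian random field
smoothed to a per-subject correlation length (3–12 mm), with

* CT-like image noise: a white-noise component correlated in-plane by a
  reconstruction-kernel-scale filter (~0.6 pixel) and independent across
  slices, contributing a log-uniform 5–90% of the intensity variance;
* per-subject mean 45 ± 10 and total SD 45–60 (HU-like);
* ellipsoidal VOIs with semi-axis ratios 0.6–1.4 and analytic volumes
  drawn log-uniformly from 4–123 cm³ on a 1.17 × 1.17 × 3 mm grid
  (realized voxel volume within 5% of the draw);
* Poisson(1.5) flat-topped focal inclusions per tumor (±80–350 HU
  contrast, radius 0.15–0.35 of the mean semi-axis), emulating
  calcification-like and necrosis-like components that stretch each
  subject's intensity range individually.

Each ingredient exists to make one family of scaling laws observable the
way real cohorts show them: volume spread drives the `N`-dependence;
voxel-scale noise makes run/zone statistics track `N` rather than voxel
size; histogram heterogeneity (noise fraction, focal components) gives
subjects distinct per-voxel feature levels so that *normalized* features
decorrelate from `N`. The phantom generator instead replicates one
homogeneous cuboidal VOI of 14.2 cm³ at 0.98 × 0.98 × 3 mm across 8
pseudo-scanners that differ only by an intensity offset and noise
realization.

What the generator does *not* emulate: CT physics (beam hardening,
reconstruction kernels, HU calibration), irregular segmented boundaries,
spatially non-stationary tumor biology. Passing tests on this cohort
demonstrate that the implementation reproduces the *mechanics* of the
voxel-count and gray-level dependencies and their removal; they are not
evidence about any particular patient population.

Determinism: one seed fixes geometry and texture; a separate `field_seed`
(derived from the main seed by default) lets users redraw textures while
holding mask geometry fixed.

## Problem sizes and numerical choices

The experiment drivers default to the full study geometry — 18 subjects
of 4–123 cm³ (about 10³–3·10⁴ VOI voxels each), 11 resampling variants,
`d = 64`, and a 6-point gray-level ladder — which runs in well under a
minute per experiment on one CPU thanks to the compiled matrix kernels;
unit tests use 5 × 5 × 3 grids where brute-force oracles are feasible.
Other choices: interpolation clamps at volume edges; mask binarization
threshold is 0.5; GLCM directions with no valid pair are dropped from the
average (a single-voxel VOI is an error, "GLCM undefined"); `log N`
normalization requires `N > 1`; degenerate single-level VOIs yield defined
feature values (entropies 0, Inverse Variance 0) rather than failures.

## Known limitations

* The per-feature rule tables are scaling-analysis defaults, not a
  transcription of any external convention; four voxel-normalized
  features (GLCM-Mean, GLCM-Inverse Variance, Intensity-Contrast,
  Intensity-Entropy) are only partially corrected by any single rule and
  retain moderate residual `N`-correlation — visible in the shipped
  experiments.
* GLRLM-GLNU scales like `N · c(d)` — multiplicatively in both factors —
  so its raw-scale two-way ICC across gray levels is intrinsically
  mediocre on wide-volume-range cohorts even though the feature is
  well-behaved per subject; a log-scale ICC would be the better statistic
  but is outside the implemented contract.
* Trilinear up-sampling correlates adjacent voxels, slightly lengthening
  runs on fine grids; normalized run-length features therefore retain a
  few-percent systematic trend across the resampling grid. This is a
  property of interpolation-based resampling itself, not of the
  implementation.
* DICOM ingestion, RTSTRUCT contours, 4D volumes, B-spline interpolation,
  shape features beyond volume, and prognostic modeling are out of scope.
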