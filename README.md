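# radnorm

Voxel-size and gray-level normalization of CT radiomic texture features.

## The problem

Radiomic features — intensity-histogram statistics and texture summaries
built from the gray level co-occurrence (GLCM), run length (GLRLM), size
zone (GLSZM) and neighborhood gray tone difference (NGTDM) matrices — are
candidate imaging biomarkers, but many of them are not measurements of
tissue texture alone. Their numerical values depend on

* **N**, the number of voxels inside the volume of interest (VOI), which is
  set jointly by the physical VOI volume and the reconstruction voxel size
  `V_s(P, T) = P·P·T` (pixel size `P`, slice thickness `T`), via
  `N(P, T) = VOI / V_s(P, T)`; and
* **d**, the number of gray levels the VOI intensities are discretized to
  before building texture matrices (here equispaced binning over the VOI
  min–max, `d ∈ {8, 16, 32, 64, 128, 256}`).

Features such as Intensity-Energy (`Σ I²`), GLRLM gray-level and run-length
non-uniformity (GLNU, RLNU) or NGTDM-Coarseness scale essentially linearly
(or inversely) with `N`; entropy-type GLCM features grow like `log₂ d`;
average/variance-type GLCM features scale like `d` or `d²`. radnorm
implements the corrective normalizations

```
f_n = f · N        f_n = f / N        f_n = f / log N       (voxel size)
f_n = f / g(d),    g(d) ∈ {1, d, d², log₂ d}                (gray level)
```

with exactly one rule per feature (10 features carry a voxel-size rule, 17
texture features a gray-level factor; see `feature_definitions()`), plus
everything needed to evaluate them:

* NIfTI volume/mask I/O and VOI extraction (`load_volume()`, `load_mask()`,
  `extract_voi()`);
* trilinear resampling to arbitrary `(P, T)` and the one-factor-at-a-time
  resampling design — original + 4 pixel sizes (0.58–1.38 mm) + 6 slice
  thicknesses (1–4 mm) = 11 data sets per subject
  (`resample_volume()`, `resample_mask()`, `expand_resampled_set()`);
* equispaced discretization and the four texture-matrix builders in
  compiled code, using 13 lattice directions and 26-connectivity
  (`discretize()`, `build_glcm()`, `build_glrlm()`, `build_glszm()`,
  `build_ngtdm()`);
* the 24-feature panel (`extract_features()`) and the two normalizations
  (`apply_voxel_normalization()`, `apply_gl_normalization()`);
* robustness statistics: absolute Spearman rank correlation of features
  with `N` (categories: no < 0.5, moderate, high > 0.9) and the two-way
  consistency ICC `(BMS − RMS) / (BMS + (d − 1)·RMS)` across gray-level
  ladders (not stable < 0.5, intermediate, highly stable > 0.8)
  (`spearman_abs()`, `icc_consistency()`);
* a synthetic-data generator emulating a lung-tumor cohort (18 subjects,
  4–123 cm³, 1.17 × 1.17 × 3 mm grid) and a homogeneous texture phantom
  replicated across 8 pseudo-scanners (`generate_tumor_cohort()`,
  `generate_phantom_scans()`);
* end-to-end experiment drivers with CSV/JSON/figure reports
  (`run_voxel_experiment()`, `run_gl_experiment()`, `write_report()`), and
  a command-line front end at `inst/cli/radnorm.R`.

## Worked example

```r
library(radnorm)

spec    <- cohort_spec(n_subjects = 3, volume_range_cm3 = c(4, 40), seed = 7)
cohort  <- generate_tumor_cohort(spec)
subject <- cohort[[1]]
subject$mask
#> <voi_mask> N = 9522 voxels, volume 39104.0 mm^3

feats <- extract_features(subject$volume, subject$mask, d = 64)
round(feats[c("Intensity-Energy", "GLCM-Entropy", "GLRLM-RLNU",
              "NGTDM-Coarseness")], 4)
#> Intensity-Energy     GLCM-Entropy       GLRLM-RLNU NGTDM-Coarseness
#>     7.411505e+07     9.317600e+00     9.719937e+04     1.300000e-03

norm <- apply_voxel_normalization(feats, attr(feats, "n_voxels"))
round(norm[c("Intensity-Energy", "GLRLM-RLNU", "NGTDM-Coarseness")], 4)
#> Intensity-Energy       GLRLM-RLNU NGTDM-Coarseness
#>        7783.5587          10.2079          12.6660
```

Energy and RLNU are dominated by `N` (7.4·10⁷ and 9.7·10⁴ on ~10⁴ voxels);
after division by `N` they become per-voxel quantities comparable across
VOI sizes, and Coarseness — which falls as `1/N` — is rescaled by `·N`.

A full experiment on the default 18-subject cohort expands every subject
across the 11-point resampling set (198 data sets), extracts both feature
variants at `d = 64`, and reports `|r_s|` versus `N` per feature:

```r
res <- run_voxel_experiment(experiment_config())
subset(res$report, feature == "GLRLM-RLNU")
#>       feature          variant    statistic estimate ... category   n
#>    GLRLM-RLNU   non-normalized spearman_abs    0.992 ...     high 198
#>    GLRLM-RLNU voxel-normalized spearman_abs    0.498 ...       no 198
```

i.e. the non-normalized feature is essentially an `N`-meter (`|r_s| ≈ 1`),
while its normalized form is uncorrelated with voxel count. The analogous
gray-level experiment (`run_gl_experiment()`) extracts the 17-feature panel
at 6 gray-level counts (108 data sets) and computes the across-level ICC
before/after gray-level normalization.

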