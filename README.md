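# dvfqa

Voxel-by-voxel quality assurance for deformable image registration (DIR)
vector fields.

Deformable registration of respiration-resolved CT produces a dense
displacement vector field (DVF) `u(x)` — one millimetre-valued 3-vector per
voxel — that drives contour propagation, dose accumulation and ventilation
estimates. Ground truth is almost never available for a clinical image pair,
so this package implements the two things that *can* be checked: whether a
DVF behaves physically, and whether two DVFs computed on the same anatomy
agree. It is aimed at medical-physics and image-analysis groups commissioning
or comparing DIR algorithms.

## What it computes

- **Jacobian-determinant maps**: `J = det(I + ∇u)` per voxel from
  spacing-normalized central differences over the immediate one-voxel
  neighbourhood, signed (negative values flag physically impossible folding),
  with the outermost voxel shell set to unity where no central difference
  exists.
- **Jacobian volume histograms (JVH)** over contoured structures, with
  volume-weighted mean (the structure's total volume-change estimate,
  `V_deformed / V_target ≈ (1/V) Σ v_i J_i`), weighted SD, and two-sided
  fractional-volume tail boundaries `J_X` for factor-of-two physicality
  screening.
- **Spatial-discrepancy (SD) maps** between two DVFs, `|u_A − u_B|` in cm,
  with high-tail boundaries `(SD)_X` for X from 2.5 to 35% of structure
  volume.
- **DICE contour propagation checks**: `2|A∩B|/(|A|+|B|)` before and after
  warping the moving-phase contour through each DVF (nearest-neighbour
  pull-back).
- **Cohort summaries**: per-structure mean ± SD / min / max across patients
  and paired two-tailed Student's t-tests with discrepancy (`p < 0.05`) and
  agreement (`p > 0.05`) significance flags.
- **Synthetic deformations with closed-form Jacobians** (affine, axial
  sinusoid, injectable folding defects, randomized multi-patient cohorts) so
  every statistic can be validated against analytic truth.
- **IO**: NIfTI (`.nii`/`.nii.gz`) and MetaImage (`.mhd`/`.mha`) readers and
  writers for vector fields, masks and scalar maps, with lossless float64
  round trips; JSON planar-contour rasterization.

## Worked example

Thirteen synthetic exhale→inhale cases, each "registered" by two algorithms
that disagree by up to 10 mm:

```r
library(dvfqa)

cohort <- make_synthetic_cohort(13, seed = 7, discrepancy = 10)
case <- cohort[[1]]

# JVH statistics of algorithm A on the left lung phantom
j <- jacobian_map(case$field_a)
s <- sample_structure(j, case$masks$left_lung)
weighted_mean(s)                      # 1.1049 — matches the true volume
case$truth$volume_ratio["left_lung"]  # 1.1049    ratio to 4 decimals
weighted_std(s)                       # 0.0291
tail_boundary(s, 2.5, "low")$boundary   # 1.0504
tail_boundary(s, 2.5, "high")$boundary  # 1.1614

# Where do the two algorithms disagree, and by how much?
sd_samples <- sample_structure(sd_map(case$field_a, case$field_b),
                               case$masks$left_lung)
sd_boundary_series(sd_samples, c(2.5, 10, 35))
#>       X side  boundary
#> 1   2.5 high     1.000      # worst 2.5% of the lung disagrees by >= 1.000 cm
#> 2  10   high     0.999
#> 3  35   high     0.989
```

The mean JVH reproduces the analytic volume ratio because the generator's
Jacobian is known in closed form; the `(SD)_X` boundaries sit just under
1 cm because the injected disagreement peaks at 10 mm.

Cohort-level reporting with a significance test:

```r
records <- dplyr::bind_rows(lapply(cohort, function(cs)
  analyze_patient(list(algA = cs$field_a, algB = cs$field_b), cs$masks,
                  volume_ratios = cs$truth$volume_ratio,
                  patient_id = cs$patient_id, x_list = c(2.5, 35))))

summ <- summarize_cohort(records, comparisons = list(
  comparison("left_lung",
             a = list(metric = "sd_2.5", algorithm = "algA", algorithm_b = "algB"),
             b = "zero", mode = "discrepancy")))

cohort_table(summ, "sd_2.5")
#>   structure  `algA-algB`
#> 1 gtv        0.97 ± 0.031
#> 2 left_lung  1 ± 0.007
#> 3 right_lung 1 ± 0.0059
summ$tests
#>   label                           structure mode        n  p_value     significant
#> 1 left_lung sd_2.5:algA:algB vs 0 left_lung discrepancy 13 2.11e-27    TRUE
```

The paired t-test flags the injected inter-algorithm discrepancy as
significant, and the 2.5% SD boundary recovers its magnitude (1 cm) in every
structure. `tidy(summ)` returns the full per-cell statistics;
`autoplot(build_histogram(s))` and `plot_sd_boundaries()` draw the standard
JVH/SDVH figures.

A thin command line covering the same operations ships in `inst/cli/dvfqa`
(subcommands `synth`, `jacobian`, `sdmap`, `dice`, `warp-mask`, `jvh`,
`sdvh`, `analyze`); see `?dvfqa_cli`.

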