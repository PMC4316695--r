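---
title: "Voxel-wise QA of deformable registration vector fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise QA of deformable registration vector fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvfqa)
```

## The problem

Deformable image registration (DIR) of respiration-resolved CT produces a
dense displacement vector field (DVF): one 3-vector per voxel mapping, say,
the exhale anatomy onto the inhale anatomy. DVFs drive contour propagation,
dose accumulation and ventilation estimation, yet ground truth for a clinical
image pair is essentially never available. A practical alternative is
*pairwise* QA: run two algorithms on the same anatomy and quantify where and
by how much their DVFs disagree, and screen each DVF for behaviour that
cannot be physical regardless of any ground truth. If two DVFs agree they may
still both be wrong, but if they disagree at least one of them is — which is
often all a clinic needs to know before trusting a propagated contour or an
accumulated dose.

dvfqa implements that analysis as a composable library plus a thin command
line. Three families of statistics are produced, each over contoured
structures rather than whole volumes:

1. **Jacobian volume histograms (JVH).** Interpreting the DVF literally as
   tissue flow, the Jacobian determinant `J = det(I + ∇u)` measures local
   fractional volume change: `J > 1` expansion, `J < 1` compression, `J ≤ 0`
   a fold in space, which is physically impossible. The volume-weighted mean
   of a structure's JVH estimates the structure's total volume change; the
   weighted SD and the tail boundaries `J_X` characterise how wildly the
   field oscillates locally.
2. **Spatial discrepancy (SD) maps.** The voxel-wise Euclidean norm of the
   difference of two DVFs, reported in cm. Summarised by high-tail boundaries
   `(SD)_X`: the smallest discrepancy found in the worst-X% sub-volume of a
   structure, for X from 2.5 to 35%.
3. **DICE contour propagation.** `2|A∩B|/(|A|+|B|)` between an observer's
   target-phase contour and the moving-phase contour propagated through the
   DVF, against the no-deformation baseline.

Cohort-level reporting aggregates per-patient values into mean ± SD / min /
max cells and runs paired Student's t-tests with two significance
conventions: expected-discrepancy comparisons claim significance at
`p < 0.05`, expected-agreement comparisons at `p > 0.05` (both strict).

## Numerical choices

**Jacobian stencil.** The displacement gradient is estimated on the immediate
one-voxel neighbourhood. We use the central difference
`(u(i+1) − u(i−1)) / (2h)` per axis, with `h` the physical spacing of that
axis, making the scheme second-order accurate and exact on affine fields;
the test suite verifies the error on smooth fields falls ~4× when spacing is
halved. The one-voxel boundary shell, where no central difference exists, is
pinned to exactly `J = 1` (unity: no measured volume change). The determinant
is kept **signed**: negative values are the folding diagnostic, so taking an
absolute value would destroy the very signal the physicality screens need.
Because edge voxels are pinned rather than measured, structures touching the
grid edge can bias JVH statistics toward 1; `exclude_grid_boundary()`
(`--exclude-grid-boundary` on the CLI) optionally strips that shell before
sampling. Default behaviour includes all in-mask voxels.

**Anisotropic grids** are first-class: every derivative divides by its own
axis spacing, and the default test grid (64×64×48 at 1.5×1.5×2.5 mm) is
deliberately anisotropic so that spacing bugs cannot hide. Oblique lattices
(non-identity direction cosines) are rejected at the readers: voxel-wise
arithmetic across images presumes axis-aligned, co-registered grids, and
`assert_same_grid()` (dims exact; spacing/origin within 1e-3 mm, absorbing
float header round-off) guards every binary operation.

**Units.** Displacements and geometry are millimetres throughout; SD maps are
*reported* in cm because clinically notable inter-algorithm disagreement
lives on the cm scale. Jacobians are dimensionless.

**Volume histogram statistics are bin-free.** The weighted mean
`Σ v_i J_i / Σ v_i`, weighted (population) SD, and the tail boundaries are
computed from exact weighted order statistics on the samples; binning exists
only for plotting (default 200 bins) and cannot move a headline number. The
tail rule is literal: sort, accumulate volume until it first reaches X% of
the structure, and report the value of the last sample included — the
minimum value of the top-X% sub-volume (high side) or the maximum of the
bottom-X% (low side). No interpolation between sample values is applied.
Population rather than n−1 SD is used; structures contain 10³–10⁵ voxels, so
the distinction is negligible, but tests pin the convention.

**Sampling weights.** Projecting a map onto a structure assigns every set
voxel its full voxel volume `s_x s_y s_z` as weight, with the value sampled
at the voxel centre (on a shared grid, trilinear interpolation at voxel
centres reduces to exact lookup). The alternative — fractional, partial-volume
weights at the structure boundary — differs only in a one-voxel surface layer
and would require a sub-voxel mask model the bitmap inputs do not carry.

**Mask warping** uses pull-back semantics with nearest-neighbour
interpolation: output voxel `x` looks up the source bitmap at `x + u(x)`.
Pull-back is the standard resampling convention (every output voxel gets a
defined value; no holes), but it means a field of constant displacement `+d`
shifts a mask by `−d`; this is documented on `warp_mask()` because
push-forward would negate the sign convention. Out-of-grid lookups return
background, so structures carried outside the field of view vanish rather
than smear against the edge. Nearest-neighbour is used for bitmaps to keep
them binary.

**Contour rasterization** sets a voxel iff its centre is inside the slice
polygon under the even-odd rule, which is orientation-free and lets nested
contours carve holes. Edge handling is half-open (left/bottom edges in,
right/top out) so abutting polygons tile without double counting. The test
suite cross-checks against an independent winding-parity implementation.

**Paired t-tests** delegate to `stats::t.test(paired = TRUE)`, two-tailed —
the conventional reading of a paired Student's t-test between per-patient
series. Two degenerate cases get explicit answers: all differences exactly
zero (perfect agreement) returns `p = 1`; a nonzero constant difference
(unbounded t) returns `p = 0`. The agreement-mode flag (`p > 0.05` claims
significant agreement) reproduces a common QA reporting procedure; it is
*not* an equivalence test, and absence of a significant difference is not by
itself evidence of equivalence — use it as a screen, not a certification.

## The synthetic-data generator

Real 4DCT cohorts with multiple DIR solutions are proprietary and, more
fundamentally, carry no voxel-level ground truth. The generator therefore
builds *analytic* deformations whose Jacobians are known in closed form, so
every downstream statistic has an exact target:

- `make_affine_field()`: `u = A(x − x_c) + t`, Jacobian `det(I + A)`
  everywhere. Central differences are exact here, which separates stencil
  bugs from discretization error.
- `make_axial_sinusoid_field()`: `u_z = a sin(k z + φ)`, Jacobian
  `1 + a k cos(k z + φ)` — a diaphragm-like band of compression/stretch in an
  otherwise quiet volume. `|a k| < 1` is enforced so the map never folds.
- `inject_fold()`: a compactly supported radial inversion bump
  `u ← u − s (1 − (r/R)²)² (x − c)`; at the centre the Jacobian is
  `(1 − s)³`, so `s > 1` plants a guaranteed negative-Jacobian defect while
  leaving the field bit-exact outside the ball. This emulates the localized,
  physically impossible registration features that Jacobian screening exists
  to catch.
- `make_synthetic_cohort(n, seed, discrepancy)`: per case, `field_a` mixes a
  diagonal affine inflation (in-plane factors drawn from U(1.00, 1.05), the
  dominant z factor from U(1.05, 1.12), translations U(−3, 3) mm) with a
  z-sinusoid (amplitude U(3, 8) mm, wavenumber U(0.02, 0.04) /mm, random
  phase) — magnitudes chosen to mimic quiet-breathing lung inflation with
  diaphragm-dominated motion on the desk-scale grid. Spherical phantom masks
  stand in for lungs and a GTV. `field_b` adds the inter-algorithm
  disagreement: a smooth unit direction field (three low-frequency
  sinusoids, offset away from zero norm before normalizing) scaled by a
  near-uniform magnitude `discrepancy × (0.95 + 0.05 sin(k·x + φ))`.

Two properties of the perturbation are deliberate. Its magnitude lies in
`[0.9, 1.0] × discrepancy` *everywhere*, so the injected level is recoverable
from any sub-volume statistic — `(SD)_X` of any structure must land in that
band, giving cohort-recovery tests a tight analytic target; and it is
band-limited, so its exact magnitude map is stored as truth alongside the
closed-form Jacobian of `field_a` and the volume-weighted mean of that
Jacobian over each mask (a midpoint-rule quadrature of the analytic volume
ratio — exact for the affine part, O(h²) for the sinusoid).

Seeding is a single master integer; per-patient streams derive from it by a
fixed offset, and the caller's RNG state is restored afterwards, so cohorts
are pure functions of `(n_patients, seed, discrepancy)`.

**What the generator does not emulate.** Fields are globally smooth apart
from injected folds; real DVFs carry discontinuities at sliding interfaces
(lung–chest wall), intensity-artifact-driven noise, and spatially
heterogeneous regularization. Masks are spheres, not anatomical shapes, and
no CT intensities are synthesized at all — every statistic here consumes
fields and masks only. Passing tests therefore demonstrate that the
*measurement machinery* is correct to analytic truth, not that any particular
DIR algorithm is accurate on clinical data.

## Problem sizes and defaults

Desk-scale analyses use the 64×64×48 default grid (clinical grids are
512×512 in-plane; all operations scale linearly in voxel count and are
vectorized). Cohort examples use 13 cases, a realistic small-protocol size.
Defaults: grid tolerance 1e-3 mm; mask binarization threshold 0.5; histogram
bins 200; X-list {2.5, 5, 10, 15, 20, 25, 30, 35}%; two-sided Jacobian tails
at X = 2.5%; significance threshold α = 0.05; factor-of-two Jacobian
physicality screen (J outside [0.5, 2] treated as non-physical in reports).

## Known limitations

- No resampling between mismatched grids: inputs must already share a
  lattice, by design.
- 4-D (time-series) fields are out of scope; analyze extracted 3-D phase
  pairs.
- DICOM/DICOM-RTSTRUCT ingestion is out of scope; convert to NIfTI/MetaImage
  and the JSON contour schema first.
- The agreement flag inherits the usual caveat of significance-based
  agreement claims (see above).
- Tail boundaries are sample statistics; on very small structures (tens of
  voxels) `X = 2.5%` may correspond to a single voxel.
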