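---
title: "Fetal head-pose detection from scout volumes: methods and design"
author: "FetalScout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal head-pose detection from scout volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural fetal-brain MRI is acquired as stacks of thick 2D slices. The
fetus moves between the moment a technologist prescribes a stack and the
moment it is acquired, so a substantial fraction of clinical stacks come
out obliquely oriented relative to the brain and have limited diagnostic
value. A fast full-uterus EPI scout (a few seconds) contains enough
information to determine the current pose of the fetal head; if the pose
can be derived automatically within seconds, the follow-up anatomical
stack can be prescribed in true sagittal/coronal/axial planes of the
*fetal* brain.

FetalScout implements that pose detection. Its product is an orthonormal
anatomical frame — left-right (LR), posterior-anterior (PA),
inferior-superior (IS) axes plus the brain centre `B` — derived from three
landmarks: the brain centre and the centres of the two eyes.

## Pipeline

1. **Per-slice preparation** (`prepareSlice`). Each slice is divided by a
   heavily blurred copy of itself (Gaussian FWHM `fNU = 20` mm), which
   removes coil shading and normalizes intensity scale, and multiplied by
   inverted difference-of-Gaussian weights (FWHM `f1 = 10`, `f2 = 5` mm,
   computed on the original slice, negatives clipped, rescaled to [0, 1],
   inverted) that suppress the dark skull rim and sharpen the boundary of
   bright blobs. All kernels are parameterized by FWHM in mm and converted
   per axis to pixel sigmas (`sigma = FWHM / (2 sqrt(2 ln 2))`), with
   mirrored boundaries and kernel radius at least `3 sigma`. The
   boundary-handling choice is ours; it keeps the flattening ratio
   unbiased at the image edge.

2. **Maximally stable extremal regions** (`detectMsers`). Bright-polarity
   MSERs are connected components of upper level sets `{I >= t}` whose
   area is stable across thresholds. The implementation (C++ max-tree via
   union-find over descending quantized levels) uses a precise region
   semantics that the pure-R brute-force oracle `mserOracle`
   re-derives independently by thresholding at every level; the test suite
   requires the two to return identical pixel sets. The definition:
   intensities are min-max quantized to 256 integer levels; every distinct
   component pixel set is a tree node with `hi(N)` = the smallest
   intensity in `N`; the node's seed is its highest-intensity pixel
   (smallest column-major index on ties); the variation is
   `q(N) = (|comp(seed, hi - delta)| - |comp(seed, hi + delta)|) / |N|`
   with both probe thresholds clamped to the attainable range; a node is
   reported when `q` is a local minimum along its seed chain (missing
   neighbours count as satisfied), `q <= 0.5`, and its area lies in
   `[9 px, 40%]` of the slice; nested candidates closer than 20% in
   relative area are deduplicated greedily by `(q, area, seed)`. These
   MSER-level bounds are deliberately loose — the anatomical filters do
   the real selection — and are exposed in `pipelineConfig()`.

3. **Age-specific filtering** (`applyFilters`). An equal-moment ellipse is
   fitted to each region (pixel-centre second moments plus the per-pixel
   uniform moment `spacing^2/12`; full axes `a >= b` in mm). Regions are
   kept only if their normalized descriptors fall inside the stage's
   bounds: area over the reference ellipse area `pi (a_ref/2)(b_ref/2)`,
   aspect ratio over `a_ref/b_ref`, major axis over `a_ref`, Dice overlap
   with the rasterized ellipse, distance from the brain centre over
   `OFD/2`, and (for eyes) the local contrast `C` — the ratio of the
   median intensity inside the fitted ellipse to the median in a
   surrounding ribbon whose axes are 50% longer. References are
   `a_ref = OFD`, `b_ref = BPD` for the brain stages and
   `a_ref = b_ref = OD` for the eyes, all looked up at the given
   gestational age (GA, weeks) by linear interpolation in the biometry
   table. All thresholds are evaluated in mm world coordinates so they are
   independent of voxel anisotropy.

4. **Global brain search** (`meanShiftModes`, `assignMembers`,
   `selectBrain`). Region barycentres are clustered across slices by
   Gaussian mean shift (kernel FWHM `0.5 x OFD`, start grid spacing
   `0.5 x OFD`, tolerance 1 mm, at most 100 iterations; converged starts
   closer than 10 tolerances are merged). Every region within `0.5 x OFD`
   of a mode joins that cluster — multi-membership is allowed; the fill
   factor disambiguates. Clusters are ranked by the fill factor
   `F = |M ∩ E| - |E \ M|`, where `E` is the set of grid voxels inside
   the 3D ellipsoid moment-fitted to the cluster mask `M`; masks with
   fewer than 4 non-coplanar voxels score `-Inf`. Ties break by larger
   mask, then smaller third world coordinate. The winning mask is
   regularized slice-wise: 2D hole filling, interior empty slices filled
   with the intersection of their nearest non-empty neighbours, then
   protrusion removal (a voxel survives only if present on the nearest
   non-empty slice on at least one side, computed simultaneously). The
   brain centre `B` is the mask barycentre.

5. **Local masking and the brain ellipsoid** (`localBrainSearch`,
   `parabolaPrune`, `fitEllipsoid`). MSER detection is repeated on partial
   slices inside a box of side `sqrt(2) x OFD` centred on `B`, filtered
   with the looser brain-mask stage plus the distance bound, and unioned
   with the global mask. A parabola is then fitted to the per-slice major
   axes of the central 50% of non-empty slices; the signed deviation of
   every slice from the fit is converted to z-scores using the SD of the
   central residuals, and slices with `z > zPoly = 1.5` are discarded —
   only if the parabola is concave, and never the largest-axis slice. We
   read the deviation as signed deliberately: the pruning exists to remove
   slices whose cross-section is too large for a rise-to-a-maximum-and-
   fall profile (typically amniotic fluid beyond the skull); an absolute
   z-score would also prune the genuinely tapering polar slices of a
   clean ellipsoidal mask, whose sqrt-shaped axis profile always deviates
   from a central-band parabola at the margins, and would bias the brain
   centre along the slice axis. Gaps are closed by 1D hole filling along
   the slice axis and protrusion removal. Finally a 3D ellipsoid is
   moment-fitted to the mask: eigendecomposition of the voxel second
   central moments, semi-axes `sqrt(5 lambda_k)` (the factor that makes a
   solid uniform ellipsoid reproduce its own axes; the 2D ellipse uses
   the solid-disk factor `2 sqrt(lambda)`). Its centre is the updated
   `B`; its major axis feeds the left-right disambiguation.

6. **Eye detection** (`detectEyeCandidates`, `pairError`, `selectEyes`).
   The brain box is resampled isotropically at half the in-plane voxel
   size (trilinear) so the small eyes span enough pixels. After per-slice
   MSER detection and eye-stage filtering (including `C >= 2` and the
   `[0.6, 1.3] x OFD/2` distance window), each region together with all
   regions within `0.75 x OD` forms one candidate cluster; duplicate
   member sets are merged, candidate barycentres are unweighted means.
   Every unordered candidate pair is scored by
   `epsilon = |(u_j + u_k)/OFD - 1| + 2 lambda |u_j - u_k|/(u_j + u_k) +
   |w/d_io - 1| + |(s_j + s_k)/(2 s_max) - 1|`
   (brain-eye distance prior, symmetry with `lambda = 4`, eye-separation
   prior, slice support). Each term is wrapped in an absolute value so
   every deviation is a penalty. The expected eye separation `d_io` is
   not recoverable from published material; we use `d_io = 2 x OD`
   (centre separation = one ocular diameter plus an interocular gap of
   about the same size), exposed in the configuration — this is a
   documented stand-in, not a published constant. The minimal-epsilon
   pair wins; ties resolve by the deterministic lexicographic candidate
   order.

7. **Frame construction** (`buildFrame`, `resolveLeftRight`,
   `applyTilt`). `LR0` is the unit vector between the eyes, `PA` points
   from `B` through the eye midpoint, `IS = LR0 x PA`, and `LR = PA x IS`
   restores exact orthonormality when motion leaves `LR0` and `PA`
   slightly non-perpendicular. The plane containing the brain ellipsoid's
   major axis and parallel to `LR` separates the inferior half (which
   contains the eyes) from the superior half: if `IS` points into the
   eyes' half-space, `LR` and `IS` are both negated, preserving
   `det = +1`. The eye on the `+LR` side is then labelled the right eye
   (RAS convention). If the ellipsoid is nearly spherical (anisotropy
   <= 1.05), its major axis nearly parallel to `LR` (<= 10 degrees), or
   the eyes lie in the separating plane, the frame is returned with
   labels `"ambiguous"` rather than guessed. Because the eye plane sits
   about `theta = 30` degrees below the brain's axial plane, `PA` and
   `IS` are finally rotated about `LR` by `theta`, with the sense chosen
   so `IS` moves away from the eyes (they are inferior). We resolve
   left-right before tilting; the tilt preserves `LR`, and the test suite
   checks that the two orders commute on realistic geometry. The tilt
   sign is exposed (`tiltSign`) for the opposite convention.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fNU` | 20 | mm | flattening blur FWHM |
| `f1`, `f2` | 10, 5 | mm | difference-of-Gaussian FWHMs |
| `zPoly` | 1.5 | z-score | slice-pruning threshold |
| `lambda` | 4 | – | eye-symmetry weight in epsilon |
| `thetaDeg` | 30 | degrees | eye-plane tilt about LR |
| `fClustFactor` | 0.5 | x OFD | mean-shift kernel FWHM |
| `rhoClustFactor` | 0.75 | x OD | eye clustering radius |
| `rhoSuccessFactor` | 1.2 | x OD | evaluation success radius |
| `dIoFactor` | 2 | x OD | expected eye separation |
| `eyeIsoFactor` | 0.5 | x in-plane voxel | eye-box resampling |
| `mserDelta` etc. | 5, 9 px, 40%, 0.5, 0.2 | quantized levels / px | loose MSER bounds |

The biometry table shipped in `inst/extdata/biometry_default.tsv` is a
*synthetic stand-in* for published growth norms: smooth quadratic curves
anchored at OD(31 wk) = 14 mm and OFD(31 wk) = 96 mm, with
field-typical endpoints (OFD 34→113, BPD 28→95, OD 6→17 mm over
14→40 weeks) and a cephalic index near 0.82. Supply your own TSV
(`ga_weeks  ofd_mm  bpd_mm  od_mm`) to use exact published norms.

## The phantom generator

`generatePhantom` builds the study conditions the tests run under: a
68 x 68 x 48 grid at 3 mm (about 204 x 204 x 144 mm field of view, 48
slices — inside the 30–90 slice range of clinical scouts), holding

* a **skull**: a dark (0.2) shell whose outer surface is the
  OFD x BPD x BPD ellipsoid (OFD along PA) — OFD/BPD are skull diameters;
* a **brain**: the bright (1.0) shell interior (semi-axes minus 3 mm);
* two **eyes**: bright (1.2) spheres of diameter OD at `0.55 x OFD` from
  the brain centre, separated by `2 x OD`, their plane tilted 30 degrees
  inferior-anterior about LR, each inside a dark (0.35) orbital pocket of
  radius OD carved outside the cranium — without the pockets the eyes
  would border bright parenchyma and no detector could reach the required
  local contrast of 2;
* a smooth maternal **texture** (mean 0.5, 12 mm correlation length), a
  low-frequency multiplicative **bias field** (±15%, 40 mm), additive
  Gaussian **noise** (sigma = 0.05 of the brain intensity by default),
  optional bright **decoy** blobs near the head, and an optional in-plane
  displacement of the fetal structures on odd-numbered slices emulating
  interleaved-acquisition motion.

Everything is evaluated analytically in the head's canonical coordinates
mapped through the rigid pose, so arbitrary rotations introduce no
resampling artifacts, and the whole volume is deterministic in the seed.
`phantomCohort` draws poses uniformly over rotations with ±8 mm
translation jitter and GA uniform over the requested range; the cohort
conditions used throughout the tests are 40 phantoms, GA in [26, 37]
weeks, noise 0.05 and a 1 mm odd/even shift.

**What the phantom does not emulate:** EPI geometric distortion,
spin-history intensity variation between slices, wrap-around artifacts,
maternal anatomy with competing bright structures (bladder, amniotic
fluid pools of brain-like scale), ventriculomegaly or other abnormal
anatomy, and second-trimester contrast (where the real method is known to
degrade). Passing the phantom cohort therefore demonstrates the
geometric/algorithmic correctness of the chain, not clinical performance.

## Numerical choices and degenerate inputs

* Quantization for MSER is linear min-max to 256 levels; the stability
  probe `delta` lives on that scale. Region sets are consequently
  invariant under affine intensity remaps, which the suite tests.
* The flattening guard is `1e-6 x max(slice)` (scale-free); an all-zero
  slice maps to zeros, a constant slice to 1. A constant slice makes the
  DOG rescale degenerate; the weights are then all 1 (no de-emphasis).
* Collinear pixel sets get their minor axis floored at one pixel width by
  the per-pixel moment and are flagged `degenerate`.
* A region whose contrast ribbon falls entirely outside the slice is
  rejected (its contrast is undefined).
* Mask degeneracies: fewer than 4 non-coplanar voxels make the fill
  factor `-Inf`; fewer than 10 make the brain-ellipsoid fit a detection
  failure. Zero brain clusters or fewer than two eye candidates abort
  with a structured detection failure that `detectHeadPose` reports in
  the result object rather than throwing.
* Tie-breaks are deterministic everywhere: brain selection by fill
  factor, then mask size, then centroid; eye pairs by lexicographic
  candidate order; MSER deduplication by `(variation, area, seed)`.
* Eigenvector signs in ellipsoid fits are fixed by making the largest
  component positive, so axis directions are reproducible.

## Problem sizes in the test suite

The suite was sized to run comfortably on one CPU: 200 random 24 x 24
images for the detector/oracle equivalence, a 40-phantom cohort at
68 x 68 x 48 voxels for pose recovery (about six minutes), ten rotated
phantoms for equivariance, and one mirrored phantom for the left-right
swap property. `scripts/acceptance.R` re-generates the cohort and the
noise-free phantom from a command-line seed and reports success rate,
mean rotation/translation errors, noise-free exactness and
detector/oracle agreement.

## Known limitations

* The affine handling assumes scanner-axis-aligned volumes (permutations
  and flips are fine; oblique voxel-to-world rotations of the *grid* are
  not resampled first).
* Single fetus only: one brain cluster is selected; twins would need a
  multi-modal extension of the fill-factor ranking.
* The biometry defaults are synthetic (see above); for clinical-grade
  thresholds, supply published growth tables.
* `d_io` (expected eye separation) is a calibrated stand-in, configurable
  via `dIoFactor`.
* Runtime is a few seconds per scout in this R implementation —
  sufficient for the prescription loop, but not micro-optimized.
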