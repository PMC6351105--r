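---
title: "Quantifying liquid-phase bacterial aggregates in 3D fluorescence stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liquid-phase bacterial aggregates in 3D fluorescence stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscan)
```

## The measurement problem

Bacteria such as *Vibrio cholerae* can form multicellular aggregates
suspended in liquid culture, distinct from surface-attached biofilms.
Confocal imaging of a fluorescent reporter yields a z-stack: a series of
2D optical sections at increasing depth above the coverslip. The
quantities of biological interest are how much of the imaged volume the
aggregates occupy, and how large they are — summarized so that the answer
reflects the experience of a *cell*, not of an *aggregate*.

`aggscan` implements that measurement as a deterministic pipeline:

1. a single global intensity threshold applied to every z-plane;
2. 2D connected-component labeling of each plane;
3. convexity-driven bisection of merged ("under-segmented") objects;
4. reconstruction of 3D aggregates by linking overlapping 2D regions in
   adjacent planes;
5. physical-unit size filtering;
6. summary statistics and pooled two-sample Kolmogorov–Smirnov
   comparisons between conditions.

All parameters live in one `run_config` object that is attached to every
result, and every stage is a pure function of its inputs — running the
pipeline twice on the same stack and config produces byte-identical
outputs. There is deliberately no interactive or manual correction step:
what the configuration says is what happens.

## Statistics reported

For aggregates with volumes $v_1, \dots, v_N$ inside a total imaged
volume $V$:

* **Volume fraction** $\phi = \sum_i v_i / V$ — the fraction of the
  imaged region occupied by aggregates. An aggregate-free sample has
  $\phi = 0$.
* **Volume-weighted mean volume**
  $\bar v_w = \sum_i v_i^2 / \sum_i v_i$ — the expected volume of the
  aggregate containing a randomly chosen cell. Because cells are counted,
  not objects, a few large aggregates dominate, exactly as they dominate
  the population. By the Cauchy–Schwarz inequality $\bar v_w$ is never
  below the arithmetic mean, with equality only for equal-sized
  aggregates. An aggregate-free sample has *no* weighted mean volume; the
  statistic is reported as null, never as zero, because conflating the
  two would bias size plots toward zero.
* The same weighting applied to cross-sectional areas
  ($\sum a_i^2/\sum a_i$) serves the 2D whole-well (tile-scan) analysis.
* **Replicate summaries** are the arithmetic mean and sample SD (n − 1)
  of the *untransformed* per-replicate values. On logarithmic axes the
  mean ± SD error bars are therefore asymmetric; that is a property of
  the convention, not an error.
* **Condition comparisons** pool the per-aggregate sizes from all
  biological replicates of each condition and apply a two-sample
  Kolmogorov–Smirnov test (`stats::ks.test`, asymptotic p-value).
  Replicate means are never tested — the distributions are. The D
  statistic is the primary quantity; the asymptotic p-value is reported
  alongside.
* **RLU** normalizes bioluminescence: counts min⁻¹ mL⁻¹ divided by
  OD₆₀₀.

## Segmentation model and its assumptions

**Thresholding.** A single global threshold per run (no adaptive or
per-plane adjustment): segmentation is then monotone in the threshold and
trivially reproducible. Imaging regimes where large aggregates shade
their own distal side are handled by *lowering the configured threshold*,
a config change rather than a code path.

**2D labeling.** Connected components under 8-connectivity by default
(configurable to 4). Labels are assigned in raster-scan order of each
component's first pixel, making label order deterministic.

**Convexity scoring.** Liquid-phase aggregates are compact and roughly
convex, so a merged pair of aggregates betrays itself as a single
non-convex 2D object. For an object of pixel area $A$ with rasterized
convex-hull area $H$, the deviation score is the root mean square of the
per-hull-pixel deficit indicator,

$$ s = \sqrt{(H - A)/H} = \sqrt{1 - \text{solidity}}, $$

which is 0 exactly for objects that fill their hull and is comparable
across object sizes. The unnormalized deficit $H - A$ is available as an
alternative scorer (`convexity_method = "raw_deficit"`) because the bare
difference between area and convex area is also a defensible reading of
"deviation between area and convex area"; the normalized form is the
default since a fixed cutoff then means the same thing for small and
large objects. Degenerate objects — fewer than 3 pixels, or collinear —
score 0 by convention.

**Bisection.** An object whose deviation exceeds `rmsd_cutoff` is treated
as a merged pair and cut along the shortest chord through its neck:

* boundary pixels (object pixels with a 4-neighbor outside) are assigned
  to quadrants around the object centroid. Membership is band-inclusive:
  a pixel within half a pixel of a dividing line belongs to both adjacent
  quadrants. Without the band, a neck lying exactly on a centroid axis —
  the generic case for a symmetric dumbbell — would have its endpoints in
  adjacent quadrants and never be considered.
* candidate cuts are straight chords between boundary pixels that span
  different quadrants, i.e. the chord crosses at least one centroid axis.
  This is what steers cuts through the neck rather than along an edge.
* a candidate is *valid* when its 8-connected rasterization lies entirely
  inside the object and removing its pixels leaves exactly two
  components, each of at least 6 pixels. The two-component requirement is
  the point of the operation — a chord that fails to bisect is not a
  bisection — and the minimum child size rejects degenerate corner shaves
  (a 1-pixel chord near a rounded edge can technically "disconnect" a
  single pixel).
* the shortest valid chord wins; ties break on the raster order of the
  endpoints, so the choice is deterministic. At most 512 candidates are
  component-checked per object before giving up; an object with no valid
  chord is returned unchanged and logged, never errored.
* children still exceeding the cutoff are split again, up to
  `split_max_iterations` (default 3) levels, which resolves short chains
  of three or more merged objects.

Cut pixels are removed from the segmentation and accounted for in the cut
log — pixel conservation (children plus cut pixels equal the parent) is
enforced by tests.

An alternative `quadrant_frame = "principal"` rotates the quadrant
convention into the object's principal axes for strongly diagonal pairs;
the image-axis frame is the default because it is simpler and the
band-inclusive membership already handles the common orientations.

**3D reconstruction.** Objects in adjacent planes are merged when their
(y, x) footprints share at least `overlap_min_voxels` pixels (default 1).
Merging is transitive via union-find, so a branched aggregate linked
through a single object in an intermediate plane is one object. 3D
connectivity is defined *only* through inter-plane footprint overlap —
not through 26-connected voxel labeling — and no re-splitting happens in
3D.

**Size filtering** happens after 3D reconstruction, in physical units
(µm³), so that thin mid-planes of real aggregates are not deleted
prematurely and results are invariant to the voxel pitch of a particular
objective. The minimum object volume removes planktonic cells and noise
specks; the optional maximum cluster volume serves the high-magnification
cluster regime. Every removal is logged with its reason; no voxel
disappears silently.

## Parameters, defaults, and how they were chosen

| parameter | default | unit | rationale |
|---|---|---|---|
| `intensity_threshold` | 70 | intensity | midpoint between the synthetic background (20) and aggregate level (120); on blurred noisy scenes at the default conditions the midpoint threshold recovers volumes with ≤ 1% bias |
| `min_object_volume` | 50–100 | µm³ | well above a ~2 µm³ single cell, well below the smallest aggregates of interest; there is no published value, this is a pipeline default |
| `max_cluster_volume` | none / 500 | µm³ | only in the cluster ("63x") preset |
| `rmsd_cutoff` | 0.2 | – | calibrated on synthetic scenes: clean convex ellipsoid footprints score exactly 0 while abutting-pair contact planes score 0.237–0.399, so 0.2 separates the populations with margin on both sides; equivalent to solidity < 0.96 |
| `split_max_iterations` | 3 | – | resolves chains of up to four merged objects; recursion depth beyond that has no observed effect on the synthetic regimes |
| `overlap_min_voxels` | 1 | px | any overlap links planes, the most permissive (and the literal) reading of "overlapping 2D regions" |
| `connectivity_2d` | 8 | – | standard for bright blobs |

No threshold, size cutoff or convexity cutoff value is taken from
published work — none are printed there; all defaults are calibrated on
the synthetic scenes described below and are recorded in every run's
config and manifest.

## The synthetic-scene generator

Acceptance of the pipeline is property-based: the generator renders
scenes with known ground truth, and the pipeline must recover that truth.
A scene contains:

* **aggregates** as solid ellipsoids with volumes drawn from a log-normal
  distribution (default meanlog = log(1000) µm³, sdlog = 0.5 — chosen as
  a plausible size spectrum for early liquid-phase aggregates at low
  magnification; real size distributions are not published numerically,
  so this is a stand-in, not a claim), axis ratios uniform in
  `aspect_ratio_range`;
* **touching pairs**: a configurable fraction of aggregates is placed
  abutting a partner at the same depth along a lateral axis with half a
  voxel of interpenetration, voxelized keep-first and nudged until the
  two voxel sets share a face. The merged footprint at the contact plane
  is a non-convex dumbbell — the fixture that must trigger bisection.
  Distinct non-partner objects keep a 3 µm clearance, so they can never
  merge;
* **planktonic cells** as 0.8 µm-radius spheres at an intermediate
  intensity;
* optics and noise: isotropic Gaussian blur (µm), linear depth
  attenuation toward larger z (the objective is below the sample;
  intensity decays into the stack), then optional Poisson and additive
  Gaussian noise.

Placement is rejection sampling *in physical coordinates*, so one seed
produces the same physical scene at any voxel resolution — this is what
makes the anisotropy test (halving dz while doubling nz changes volumes
by < 10%) meaningful. Ground-truth labels record the pre-blur, pre-noise
voxel memberships. Identical config and seed give bit-identical scenes.

Default imaging conditions are `noise_sd = 10` (contrast-to-noise ≈ 9
against the 100-unit aggregate–background contrast), `blur_sigma = 0.5`
µm and `depth_attenuation = 0.001`/µm — a clean but not noise-free
acquisition. Presets mirror the two real regimes: "10x"
(2048 × 2048 px at 0.568 µm/px, 50 planes at 2 µm) and "63x"
(1984 × 1984 px at 1 µm/px, 50 planes at 1 µm), plus a fast "small"
256 × 256 × 25 grid at (1, 1, 2) µm used throughout the tests.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: a physical point-spread function
(asymmetric, depth-dependent), spectral cross-talk, non-convex or hollow
aggregates, aggregate motion during acquisition, tile-scan stitching
artifacts, and density-dependent background from unresolved planktonic
cells. The generator validates the *algorithmic* contract (recovery of
known geometry under controlled corruption), not instrument realism.

## Numerical choices and degenerate inputs

* Hull rasterization selects pixels whose centers lie inside (or within
  10⁻⁷ px of) the convex hull polygon of the pixel centers, by scanline
  filling; the hull always contains the object.
* Convex-hull vertices come from `grDevices::chull`; collinear objects
  fall back to "score 0".
* All chord geometry is integer; tie-breaks are lexicographic in raster
  order, so no floating-point comparison decides a cut.
* Empty samples: volume fraction 0, weighted mean volume null (reported
  as JSON null), header-only CSV.
* A single replicate yields SD 0 with a warning rather than NA, so
  plotting code does not silently drop the point.
* Stacks are written as 16-bit TIFF with a JSON geometry sidecar; label
  volumes as 32-bit TIFF (stored by the `tiff` package as scaled
  samples and rounded back to integers on read, exact for labels below
  2²⁴). A missing sidecar is an error: voxel geometry is never assumed.

## Problem sizes used in the tests

The test-suite scenes are deliberately small so the whole suite runs in
well under a minute: exact-recovery tests use the 256 × 256 × 25 "small"
preset; noisy-recovery tests use twenty 160 × 160 × 20 scenes with eight
aggregates each; splitting tests use twenty 128 × 128 × 16 scenes with
seven aggregates at a 30% touching fraction. These sizes were chosen as
the smallest grids on which the objects are comfortably resolved
(smallest aggregates ≥ ~200 µm³ ≈ 100 voxels); nothing in the pipeline
depends on grid size.

## Known limitations

* Blur erodes small convex objects: at `blur_sigma` of a full voxel the
  half-max threshold underestimates volumes of ~5 µm-radius objects by up
  to ~20% (curvature shrinkage ≈ σ²·2/r). At the default 0.5 µm blur the
  bias is below 1%. Users with strongly blurred data should lower the
  threshold or calibrate against beads of known size.
* A merged pair that touches across several planes must be bisected in
  *every* contact plane; a single missed plane re-merges the pair through
  the 3D linking step. The within-one-object-per-scene guarantee in the
  tests reflects this.
* The chord search is exhaustive over boundary-pixel pairs; for very
  large, very ragged single objects this is bounded by the 512-candidate
  cap, after which the object is left unsplit (and logged).
* The KS p-value is asymptotic; for very small pooled samples the D
  statistic should be interpreted directly.
* Mosaic assembly assumes exact, non-overlapping tiles (as produced by
  the generator); registration and illumination flat-fielding of real
  tile scans are out of scope.
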