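---
title: "Methods: 3D morphometry, karyotyping and spatial statistics for volume EM label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry, karyotyping and spatial statistics for volume EM label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vemmorph analyses segmented serial block-face scanning electron microscopy
(SBF-SEM) volumes of dividing cells: per-object 3D morphometry,
ultrastructure-based karyotyping of metaphase chromatids, chromosomal and
organelle spatial statistics, aligned regional density maps, and phase-wise
Welch comparisons. Because raw vEM stacks are rarely shareable, the package
also ships a phantom generator that produces label + intensity volumes with
exact ground truth, so every stage can be validated end to end. This
vignette records the models, conventions and numerical choices behind each
stage, and what validation on phantoms does and does not establish about
real data.

## Coordinate and unit conventions

Arrays are indexed `(z, y, x)` — a stack of slices — with voxel sizes
`(sz, sy, sx)` in nanometres. The physical centre of voxel `(k, j, i)`
(1-based) is `((i - 0.5) sx, (j - 0.5) sy, (k - 0.5) sz)`, i.e. the origin
sits at the corner of the first voxel; this removes the half-voxel ambiguity
that plagues mixed toolchains. All internal quantities are nm / nm^2 / nm^3
and are converted exactly once, at the reporting boundary, to um-based units
(volumes um^3, areas um^2, displacements um; distance matrices stay in nm).
Anisotropic voxels are supported throughout because stacks binned by
different factors must remain comparable.

Volumes travel as multipage TIFF with a JSON sidecar holding the voxel size
and object index. A voxel size is *never* assumed: reading a volume without
one is an error. Label values are restricted to the 16-bit range of the
TIFF writer; larger segmentations should be relabelled per cell.

## Morphometry

**Volume** is the exact voxel count times the voxel volume — no mesh
interior estimate, no partial-volume model. This makes volume additive
under label splits, which the tests exploit as an invariant.

**Centre of mass** is the unweighted mean of member-voxel centres.
Segmented objects carry no reliable internal intensity gradient after
heavy-metal staining, so a geometry-only COM is both simpler and closer to
what contour-model tools report. An `invert_intensity` flag exists for the
stain-intensity fields because backscatter contrast can place dense
chromatin at either end of the grayscale; the default applies no inversion.

**Integrated density** is the raw grayscale sum over the object's voxels;
the per-voxel mean is that sum over the voxel count. Summing per slice and
totalling is algebraically identical and is asserted as a test invariant
rather than implemented as a second path. Where a "mean stain intensity"
is reported it is the per-voxel mean within the object, not a per-slice
average of means; with near-constant slice areas the two differ little, but
the per-voxel mean is the one with a clean interpretation.

**Surface area** is the area of the 0.5 iso-surface extracted by a
crease-aware dual surface-nets mesher written for this package:

1. One mesh vertex per surface-crossing 2x2x2 cell of voxel centres, one
   quad per surface-crossing lattice edge (split along its shorter
   diagonal).
2. *Smooth* cells place the vertex at the centroid of the cell's
   edge-crossing midpoints and Newton-project it onto the 0.5 level of the
   Gaussian-smoothed mask (sigma = 1 voxel, trilinear sampling, two
   iterations, clamped to the cell). This removes the staircase
   overestimate that plain binary iso-surfacing suffers (roughly +9% on
   digital spheres for marching cubes, +50% for voxel-face counting).
3. *Crease* cells snap each vertex coordinate to the mean crossing plane of
   its axis, which reproduces axis-aligned faces, edges and corners
   exactly. Creases are detected from the orientation tensor of outward
   quad normals pooled over a 5x5x5 cell window: its middle eigenvalue is
   about 0.5 when two normal clusters meet at 90 degrees but stays below
   about 0.12 for the normal cone of a smooth surface. The threshold 0.16
   sits in the measured gap (creases >= 0.26, smooth <= 0.12 on
   calibration solids), with one dilation pass so the smoothing-affected
   band around a crease is also snapped.

Measured accuracy on analytic solids: axis-aligned boxes (isotropic and
anisotropic voxels) are exact to machine precision; digital spheres err by
-2.2% at r = 10 voxels, -0.3% at r = 25 and +0.003% at r = 40; a 20 x 12 x 8
voxel ellipsoid errs by about -1%. Below roughly r = 8 voxels the estimate
degrades (about -8% at r = 5); surface areas of objects only a few voxels
across should not be trusted, which matters for vesicle-scale organelles at
coarse binning.

Objects flagged as truncated (touching the stack boundary) stay in all
tables but are meant to be excluded from phase statistics by the caller;
`validate_inputs()` lists them.

## Karyotyping

The ovine diploid complement is 2n = 54: 26 autosome pairs — the three
largest metacentric, the remaining 23 acrocentric — plus a large
submetacentric X and a small acrocentric Y. The karyotype stage works on
per-chromatid morphometry (volume, surface, COM, centromere class) and does
not require masks once those are measured.

**Centromere detection** avoids full 3D thinning. The chromatid's geodesic
diameter (26-neighbourhood chamfer metric, two farthest-point sweeps)
defines an arclength coordinate `t = (d_A - d_B + L) / 2` for every voxel;
binning voxels by `t` gives a cross-sectional width profile along the rod,
which is smoothed with a 3-bin running mean. The centromere is the profile
minimum within the central 90% of arclength, and the arm ratio is the
longer over the shorter arc about it. Masks that are fragmented
(unreachable voxels) or insufficiently elongated (geodesic diameter below
1.6 volume-equivalent sphere diameters, or under 4 voxels) return
`unresolved` rather than an error. Closed-loop tests on generated rods
recover planted arm ratios within about 10%.

**Centromere classes** use the Levan cytogenetic convention: metacentric
for arm ratio <= 1.7, submetacentric to 3.0, acrocentric above — numeric
stand-ins for what a microscopist classifies visually.

**Homolog pairing** encodes the stated priority order volume >> morphology
>> proximity as the cost
`0.7 |V1 - V2| / mean(V) + 0.2 [classes differ] + 0.1 d(COM) / D(cell)`,
with a hard constraint forbidding pairs whose volumes differ by more than
35% of their mean. Chromatid-to-chromatid pairing within one cell is a
*non-bipartite* minimum-weight matching problem; no suitable exact solver
is available as a dependency, so the implementation uses greedy global
minimum-cost pairing followed by 2-opt refinement (swap partners between
two pairs whenever that lowers total cost, to convergence). On templates
whose between-pair volume gaps exceed the within-pair noise this local
optimum is the exact optimum, and the tests verify 100% recovery there.
When adjacent pairs differ by only ~4% in volume (the acro II region of
the packaged template), within-pair noise above ~1% can make cross-pairing
genuinely cheaper — a property of the data, not the optimiser; the package
documents 1% noise as the recovery limit for the ovine template.

**Sex chromosomes**: after pairing, X is the largest-volume submetacentric
candidate among unpaired chromatids, Y the smallest-volume acrocentric one;
ties break by surface area then object id. Either may be absent without
error. **Group assignment**: sex labels override; metacentric autosomes
form one group; acrocentric autosomes split at pair mean volumes of 3 um^3
(strictly above: group I) and 2 um^3 (2-3 inclusive: group II; strictly
below: group III) — the unique boundary reading consistent with "greater
than 3", "between 2 and 3" and "less than 2". A submetacentric autosome is
unresolved with a warning, since only X is expected to be submetacentric in
sheep. Autosome pairs are numbered 1..26 by descending pair mean volume
(per-pair means for numbering; per-chromatid values stay in the output),
ties broken by descending surface area then object id, so the table is
deterministic under input permutation.

The pipeline runs the karyotype stage from measured volumes only (no
centromere morphology) unless per-chromatid classes are supplied, because
geodesic profiling of 54 chromatids is the one genuinely expensive step; a
volume-only karyotype numbers the pairs but leaves X/Y unassigned.

## Spatial statistics

Distances are Euclidean on physical coordinates; the distance matrix is in
nm, displacements and nearest-neighbour distances in um. The proximity
network's edge criterion is not something the source imagery pins down, so
it is an explicit, logged parameter: the default is mutual k-nearest
neighbours with k = 3 (every degree <= k; edge sets grow monotonically in
k; neighbour ties break by distance then id), with an absolute-threshold
rule as the alternative. Analyses should not assume any particular printed
network topology is reproduced.

K-means clustering uses `stats::kmeans` with 25 random restarts per
candidate k (a seeded, deterministic procedure; restarts also make empty
clusters a non-issue in practice) and the candidate k maximising the mean
silhouette width wins, ties to the smaller k; the default range is
2..min(10, n-1). Gaussian-mixture clustering fits full-covariance (VVV)
models for 1..G components via `mclust` and selects by BIC; component
counts whose fit is singular are skipped with a warning. Clustering is done
on COM coordinates only; augmenting with volume or intensity features is
possible but changes the meaning of "spatial cluster" and is deliberately
not the default. Recovery calibration: silhouette-selected k matches a
planted k in {2, 3, 4} on 10-sigma-separated Gaussian blobs in >= 95 of 100
seeded runs; the residual misses are genuine silhouette behaviour when two
of four blobs sit near the separation floor.

## Aligned density maps

Cells are aligned by the principal axes of their voxel-coordinate
covariance: x' is the longest axis, then y', then z'. Signs follow the
skewness of the projected coordinates (non-negative, ties to +) and the
rotation is made proper; a mask whose eigenvalues all agree within 1% is
declared degenerate and gets the identity. The 3x3 regional density map
z-projects the aligned cell, splits the projected bounding box into nine
equal rectangles, counts organelle centroids per region, and divides by the
physical projected cell area inside each region (um^2), computed by
rasterising projected voxel centres on a pixel grid at the in-plane voxel
pitch, anchored at the aligned-frame origin. That anchoring, plus a tiny
centre-ward nudge in region binning, makes the grid commute with rigid
rotations of the input scene up to rasterisation noise. Normalising by
physical area is what makes cells imaged at different binning comparable —
the "voxel-corrected" density. The bounding-box frame (rather than
mask-area-equalised regions) was chosen so the 3x3 map is shape-normalised
across cells; the alternative would equalise region areas instead and is
noted as a possible extension. Centroids that project outside the footprint
are counted in the nearest region and flagged, so counts always conserve.

Hotspot maps are Gaussian kernel densities (`MASS::kde2d`) of the projected
centroids on a 64 x 64 grid over the projected bounding box, scaled to
integrate to the centroid count. The default bandwidth is Silverman's rule
per axis; a fixed bandwidth override exists for cross-cell comparability
and is the right choice when comparing phases. ER is better treated in
mass-weighted mode (per-fragment centroids weight large fragments the same
as small ones).

## Phase statistics

Group comparisons use the two-tailed unpaired t-test with Welch's
correction; s.d. uses the n-1 denominator; p-values come from the
Student-t survival function at Welch-Satterthwaite degrees of freedom. Two
identical constant groups return p = 1 by convention. No multiple-testing
correction is applied by default — matching the original analysis style of
unadjusted pairwise panels — with a Holm option behind a flag. Calibration:
10,000 equal-mean replicates at n = 10/10 reject at alpha = 0.05 at a rate
of 5.1% (seed-dependent, within 5% +- 0.6%). Cells are pooled across
follicles; follicle-level nesting would need a mixed model and is a known
limitation, not implemented.

## The phantom generator

The generator is first-class, tested code, not a fixture. A phantom cell is
an ellipsoid (default 15 x 15 x 12 um) at a stated mitotic phase; cells up
to late prophase contain a nucleus (0.74 of the cell's semi-axes) enclosing
the chromosomes, from metaphase onwards chromosomes sit free in the
cytoplasm. Default voxels are 30 nm isotropic, matching the emulated
acquisition; tests and the acceptance script run the same physical scene at
90 nm — the bin-by-three working resolution — for speed, and that choice is
a documented problem size, with full resolution available.

Chromatids inside phantom cells are convex ellipsoidal solids (aspect
2.2 : 1.1 : 0.85 free in the cytoplasm, 1.7 : 1.1 : 0.92 inside the
nucleus, where the full 166 um^3 complement must pack into ~30% of the
envelope volume). The waisted bent-rod realisation with a true centromeric
constriction lives in `generate_chromatid()` and is exercised by the
centromere closed-loop tests; packing 54 waisted rods by rejection is not
feasible at realistic nuclear fill, and no downstream closed-loop statistic
depends on rod morphology. Ellipsoid voxelisation is calibrated: sub-voxel
centre jitter decouples realised counts from lattice quantisation and axes
are rescaled until the count is within ~3% of target, so "target volume"
is a meaningful ground truth even for ~200-voxel objects.

Placement draws a target point per object — radial law for chromosomes,
uniform / central-hotspot / cortical / clustered patterns for organelles —
then spiral-searches around it with Gaussian offsets of growing scale
(re-orienting the object periodically) until a non-overlapping position in
the allowed region is found; exhausting the attempt budget raises an error
with packing diagnostics. The chromosomal radial law is a Beta distribution
over the available radius with mean equal to the phase's displacement
fraction: full support keeps packing feasible while the mean plants the
trend. The default phase effects plant the qualitative patterns the
analysis is designed to detect: chromosomal displacement rising steadily
from prophase to cytokinesis (fractions 0.45 - 0.92, with prophase
chromosome volumes scaled 0.55 / 0.75 / 0.90 to emulate progressive
condensation — which also gives the radial law room to act inside the
nucleus), mitochondrial volume building to a telophase peak with a central
hotspot, vesicle count and volume peaking at metaphase, ER volume expanding
at anaphase with fragment counts dipping early and rising late, and
non-dividing cells about 7% smaller linearly. Stain means per class
(background 30, cytoplasm 100, nucleus 140, ER 150, vesicle 160,
mitochondrion 170, chromosome 200 on a uint8 scale, Gaussian noise
s.d. 8) are fixed, documented, and non-physical.

`generate_phase_table()` is a numeric-level companion for power studies: it
samples per-cell volumes directly (non-dividing 1150 +- 85 um^3, dividing
shifted by a stated multiple of the s.d., default 3.1, with n = 8 vs 9),
without voxelisation, so 100-replicate power simulations stay cheap.

**What phantom validation shows — and does not.** Closed-loop tests
demonstrate that measurement, karyotyping, spatial statistics and density
mapping recover what the generator planted: volumes within 5% for objects
of at least 200 voxels, monotone displacement trends, hotspot argmax at the
centre region, exact count conservation, planted cluster counts, and the
planted dividing-cell volume effect at p <= 0.01 in >= 95 of 100 runs.
Phantoms do not emulate segmentation error, stack misalignment, anisotropic
point-spread, partial cells at stack boundaries beyond a flag, or real
chromatin texture; passing on phantoms therefore validates the analysis
given a correct segmentation, not the segmentation itself.

## Numerical choices and degenerate inputs

* Empty masks are errors everywhere; fragmented or non-elongated chromatids
  are `unresolved`, not errors.
* The seeded RNG is an explicit argument of every stochastic operation
  (default 1729); pipeline runs record the resolved configuration, its MD5
  and the seed in a manifest, and re-running a config reproduces all
  outputs bit-identically.
* k-means ties and silhouette ties resolve to the smaller k; neighbour ties
  in the network resolve by (distance, id).
* Region-boundary points in the 3x3 grid are assigned with a 1e-9
  centre-ward nudge so binning is mirror-symmetric; exact lattice
  coincidences are otherwise tie-broken by `ceiling`.
* The pairing hard constraint (35% of mean volume) is deliberately loose:
  it exists to keep X/Y unpaired, not to adjudicate close autosome calls.

## Problem sizes used in the shipped validation

Tests and the acceptance script generate: one full phantom phase series (8
cells, 54 chromatids plus 60-90 organelles each) at 90 nm voxels; reduced
phantoms (volumes scaled 1/6, 120-150 nm voxels) for I/O and pipeline
tests; analytic solids up to r = 40 voxels for the surface estimator; 100
seeded cluster-recovery runs; and 10,000 Welch null replicates. These sizes
were chosen as the smallest that still exercise every code path at the
stated tolerances.
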