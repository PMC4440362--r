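---
title: "Methods: 3D spine morphometry and connectivity from volume EM stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D spine morphometry and connectivity from volume EM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`spinemorph` reconstructs and quantifies DAB-labeled dendrites, their
spines, synaptic junctions and presynaptic boutons from anisotropic
FIB/SEM image stacks (serial block-face images, typically 3.7 nm/px in
XY and 25 nm steps in Z).  The pipeline runs from slice alignment and
intensity normalization, through seeded region growing and spine
isolation, to per-object morphometry (volume, surface area, Wadell
sphericity), morphological spine typing, spine-synapse-bouton
connectivity with the synaptic bouton index (SBi), and a binned
two-regime threshold regression of morphometric variables against spine
volume.  A parametric phantom generator produces synthetic stacks with
exact voxel-level ground truth so that every stage can be validated
end to end without real data.

# Stack preparation

**Alignment.**  Block-face acquisitions are nearly aligned by
construction; the residual per-slice displacement is a small integer
translation.  `align_translation()` therefore performs rigid
registration without rotation: each slice is matched to its predecessor
by exhaustively scoring integer shifts with normalized cross-correlation
over the overlap region, and the stack is cropped to the window valid in
every slice.  Ties prefer the smallest displacement, so an already
aligned stack is returned unchanged.  Because the *relative* shift
between consecutive slices spans twice the per-slice jitter, the search
window should be at least twice the expected jitter; the default is
±20 px.  Sub-pixel refinement is deliberately off: the acquisition
jitter is integer-valued and an exhaustive integer search is exact and
deterministic.  Zero-variance slices cannot be registered; they receive
a zero shift and a flag.

**Normalization.**  `normalize_slices()` removes per-slice detector gain
and brightness drift by matching each slice's location and scale
statistics to the across-slice median.  The default statistics are the
median and MAD rather than mean and SD: the robust pair tracks the
neuropil background level and texture scale and is insensitive to how
much dark labeled structure a particular slice happens to contain,
whereas moment matching compresses the absolute contrast of
structure-rich slices and breaks any downstream absolute-intensity
threshold.  Moment matching remains available (`method = "moment"`).
The operation is an affine map per slice and is idempotent.  Per-slice
gain recovery is well-posed only when slices are statistically
homogeneous; with additive noise the slice scale is no longer
proportional to the applied gain, so exact drift recovery is expected
only in the noiseless setting (and is tested there).

**Companion blur.**  Seed growing operates on a Gaussian-blurred copy of
the stack (`blur_stack()`, default radius 10 px).  The "radius" follows
the common imaging-GUI convention `sigma = radius / 2`, applied in 2D
per slice; boundaries are handled by symmetric reflection.  The blurred
stack is only ever used to grow seeds — all measurements are taken on
unblurred masks.

# Segmentation

`seed_grow()` implements absolute-intensity seeded region growing: the
mask is the 26-connected component of the thresholded set containing the
seed (dark objects by default, i.e. intensity below the threshold).  No
morphological smoothing is applied before or after.  The threshold is
user-supplied (an absolute intensity) or defaults to the pooled Otsu
threshold of the stack.  Objects use 26-connectivity and background
6-connectivity, the standard digital-topology pairing.

Synaptic junctions are traced independently (in practice, painted label
volumes imported with `import_labels()` together with a sidecar table of
categories); touching junction labels are never merged.

**Spine isolation.**  `split_dendrite()` separates a connected dendrite
mask into shaft and spines:

1. a central skeleton path is extracted between the two ends of the
   mask's principal axis, using a geodesic weighted toward the interior
   (weight inversely proportional to the inscribed-ball radius);
2. the shaft is the maximal inscribed tube around that path.  The tube
   radius is read off the radial shell-count profile of the mask around
   the path: shell populations grow roughly linearly with radius inside
   a tube and collapse at its surface to the small cross-sections of the
   protrusions, so the last radius whose shell holds at least a quarter
   of the densest shell marks the shaft surface robustly even when the
   segmented surface is rough (a one-voxel margin is added).  Distances
   to the path are exact anisotropic Euclidean distances, not chamfer
   approximations, which matters at 3.7 x 3.7 x 25 nm voxels;
3. every 26-connected protrusion outside the tube is a candidate spine.
   Its cut is refined to a cross-section minimum within the first 30%
   of the branch length, measured on geodesic shells from the
   attachment interface.  Shell counts on anisotropic grids fluctuate by
   roughly 10%, so the cut is placed at the *earliest* point within 20%
   of the minimal cross-section: a capsule-like neck of constant calibre
   is cut at its base, while a pronounced constriction above a flaring
   base is still found.  Protrusions shorter than two voxels (or below
   `min_spine_voxels`) are merged back into the shaft and logged.

Branched spines deliberately leave this stage as a single mask; their
heads are individualized later.

# Morphometry

Volume is the voxel count times the anisotropic voxel volume.  The
default surface estimator (`voxel_face`) sums the exposed voxel-face
areas; it overestimates smooth surfaces by a known factor (about 1.5 for
a ball) that is shared by all objects measured at the same voxel size,
so comparisons between objects remain valid — records carry a method tag
and sphericities are only comparable within one method.  No smoothing of
any kind is applied before measurement.

The `mesh` estimator exists for convergence checks: the binary indicator
is band-limited with a small separable Gaussian (1 voxel per axis — an
anti-aliasing step on the sampled field, not a morphological operation
on the object) and its 0.5 level set is triangulated by marching
tetrahedra on the Kuhn decomposition of each cell; the triangulation
itself is never smoothed.  Area and enclosed volume both come from the
mesh (divergence theorem on the closed outward-oriented surface), so
mesh sphericities satisfy the isoperimetric bound by construction, and
on digitized balls of radius 20 voxels or more the area agrees with the
analytic sphere to well within 3%.  Masks thinner than about two voxels
vanish at this bandwidth; the function fails loudly rather than
returning a degenerate surface.

Wadell sphericity is `pi^(1/3) (6V)^(2/3) / A`: the surface area of the
equal-volume sphere over the object's surface area; 1 for a ball, lower
for more complex shapes.  The sphere-equivalent diameter is
`(6V/pi)^(1/3)`.  Synapse size is the volume of the junction mask (PSD
plus apposed presynaptic membrane), measured with the same composition
of estimators.

**Spine geometry.**  Feature extraction and head detection share one
skeleton-path construction: geodesic distances from the neck-base
attachment point (or from one end of the geodesic diameter when no base
is known), with the base expanded into the attachment disc by two
EDT-guided passes so that geodesic shells approximate true
cross-sections even for wide-based (stubby) spines.  The neck diameter
is the minimal cross-section over the proximal 15-70% of the path, the
head diameter the maximal inscribed ball in the distal part, and the
total length the base-to-tip skeleton distance.

**Head counting and branched splitting.**  Candidate heads are distal
cores whose inscribed radius exceeds 1.2x the neck radius.  Two
candidates only count as distinct heads if the path between them passes
a pronounced isthmus (inscribed radius dropping below 75% of the smaller
head); otherwise they are facets of one head and merge.  This valley
test is what prevents boundary roughness along long filopodial necks
from faking branched spines.  `split_branched()` then assigns every
voxel to its geodesically nearest head, so the partition boundary passes
through the shared-neck isthmus; masks are disjoint and their union is
exactly the input.

# Spine classification

The five classes are qualitative in origin; `classify_spine()`
operationalizes them as a fixed-order total cascade over the quantitative
features — branched (≥ 2 heads), stubby (length ≈ neck width), mushroom
(large head), filopodial (long, head ≈ neck), thin (everything else).
All cut-offs live in `spine_thresholds()` and are reported in output
provenance.  Defaults: `t_stub = 1.8` (the shaft-tube cut trims the
proximal part of stubby spines, biasing their measured length/neck ratio
up to ~1.5-1.6, while no other class measures below ~3), `t_head =
350 nm`, `t_ratio = 1.5`, `t_filo = 1.25` (digitization erodes thin
necks slightly more than curved head surfaces, inflating measured
head/neck ratios of filopodia to ~1.15-1.25), `t_len = 3`.  These are
package defaults, not literature values; exact reproduction of any
particular study's counts is impossible by construction because the
original classifications were qualitative.

Composition tables round percentages to integers with a
largest-remainder correction so they always sum to 100.

# Connectivity

`build_graph()` links every junction to its presynaptic bouton and
postsynaptic element by 26-adjacency of label voxels (minimum contact
one voxel pair, configurable).  A junction adjacent to zero or several
boutons is an error listing the offending ids; among candidate
postsynaptic elements the largest contact wins.  Synapses on one spine
from different boutons stay distinct records; spines without a junction
are flagged non-synaptic.  SBi is the number of distinct postsynaptic
elements of a bouton; SSB means SBi = 1, MSB means SBi ≥ 2.  Only the
varicosity presynaptic to the labeled spine is scored — whatever the
parent axon does elsewhere is out of scope.  Synapse location is the
majority vote of the junction's contact voxels over the head/neck
partition of the spine, with exact ties going to the head.

# Statistics

Spearman correlation (midranks, two-tailed) and the Mann-Whitney U test
wrap the standard R implementations; U counts pairs with ties at one
half, and for samples below 8 observations each the two-tailed p-value
comes from exact enumeration of all group assignments, which stays valid
under ties.  No multiple-testing correction is applied anywhere, and the
output says so.

The two-regime analysis bins spine volume into fixed-width bins
(default 5.0e6 nm^3), averages x and y within bins, and excludes bins
holding a single point.  Candidate thresholds are the bin boundaries
leaving at least 3 retained bins on each side; for each candidate an
ordinary least-squares line is fitted to the bins below, and the
threshold maximizing the lower-range R^2 is selected.  Two refinements
make this selection well behaved: R^2 differences below a resolution of
`tie_tol = 1e-3` are treated as ties (they are sampling noise, and a
short lower range can win such a comparison by chance), and among tied
candidates the *largest* threshold wins so the linear regime extends as
far as the fit quality supports.  Exact ties across every candidate mean
there is no detectable upper regime: the smallest candidate is returned
with a `degenerate_linear` flag.  The upper regime is summarized by its
own fit *and* its mean, since a flat regime is described equally well by
either.  95% confidence bands (t distribution) and slope-versus-zero
p-values are reported for both regimes.

# The phantom generator

`build_phantom()` renders parametric scenes with exact ground truth:

* a dendritic shaft (capsule, 250 nm radius) crossing the volume, with
  spines of the five classes attached at 900 nm pitch; capsule necks
  with spherical heads, stubby heads fused to the shaft, branched spines
  bifurcating into 2-3 heads;
* asymmetric junctions as thin discs (50 nm) carved between the spine
  membrane and the bouton, which guarantees 26-adjacency on both sides;
* boutons as vesicle-textured bright spheres, each contacting the
  labeled spine plus `SBi - 1` unlabeled elements drawn from the SBi
  distribution (default: 28% SBi 1, long right tail to 10, matching the
  connectivity rates reported for mature granule cells); about 2% of
  spines carry no synapse and about 3% of synapses sit on the neck;
* DAB contrast: labeled structures dark (0.15), junctions darkest
  (0.05), boutons bright (0.75), unlabeled elements near neuropil
  (0.45), background mid-grey (0.55) — the intensity statistics of real
  DAB material are not published, so contrast is a documented free
  parameter;
* a smooth "neuropil" texture on the background so every slice carries
  registrable content — a flat background makes translation registration
  ill-posed, which real neuropil never is.

Objects are defined in nm and sampled directly on the anisotropic grid
(no post-hoc scaling).  One seeded generator drives each phantom;
identical spec and seed give bit-identical output.  The grid auto-sizes
around the scene unless a shape is requested, in which case overflowing
geometry is an error.  `apply_acquisition_artifacts()` adds the
imperfections that alignment and normalization must undo — integer
per-slice jitter (the first slice is the unshifted reference),
multiplicative drift, additive Gaussian noise — and returns the applied
values for oracle tests.

What the phantom does **not** emulate: membrane ultrastructure,
organelles, partial labeling, curtaining or charging artifacts, or the
anatomical continuity of axons beyond the scored varicosity.  Passing
recovery tests on phantoms therefore demonstrates the correctness of the
algorithms under known geometry, not segmentation performance on real
tissue.  Two further generator conventions matter for interpretation:
filopodial head radii are sampled at 1.0-1.1x the neck radius (the class
definition requires similar diameters, so sampling them independently
would generate contradictions), and branched-spine heads diverge widely
(±45° for two heads, ±60° for three) so each head's bouton complex stays
clear of its sibling's — with narrow angles and large SBi the satellite
fans of sibling boutons can intersect, which is a generator limitation,
not a biological claim.

`sample_spine_population()` draws from the same type mixture and
geometry ranges without rasterizing, for statistical simulations that
only need realistic per-spine volume and synapse-size distributions.

# Numerical choices and problem sizes

* Storage order is `(y, x, z)`; world coordinates are voxel centres at
  `index * spacing`, 0-based.
* Stacks are stored as 16-bit multi-page TIFF (65535 levels over [0,1],
  the native depth of most EM detectors); label grids as 16-bit with
  exact integer round trips.  `write_stack()` quantizes to the storage
  grid, after which write/read cycles are exact.
* Distance transforms are exact anisotropic Euclidean (parabola-envelope
  algorithm); geodesics are Dijkstra over the 26-neighbourhood with
  physical step lengths.
* The test suite exercises full-resolution (3.7 x 3.7 x 25 nm) phantoms
  for segmentation-recovery and classification checks, and
  2x-coarsened (8 x 8 x 25 nm) phantoms where a complete acquisition
  simulation is needed; these sizes keep the whole suite at roughly
  two to three minutes while leaving every structure several voxels
  thick in its thinnest dimension.  The end-to-end pipeline example
  uses a three-spine scene for the same reason.

# Known limitations

* The shaft-tube model assumes one dominant, roughly straight shaft;
  strongly curved or branching dendrites would need a branched skeleton.
* Spine isolation claims a thin band (one tube margin, ~25-40 nm) of
  each spine's base for the shaft; per-spine voxel recovery on binary
  phantoms is ≥ 0.9 IoU but not exact.
* Heavy blur relative to neck calibre (e.g. a 10 px radius at coarsened
  resolution) can sever thin branch necks in the grown mask; at the
  native 3.7 nm resolution this does not occur in the tested ranges.
* Mesh statistics require objects at least ~2 voxels thick.
* The five-class typing is a descriptive discretization of a continuum;
  the cascade order resolves overlapping definitions and is documented
  rather than claimed optimal.
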