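---
title: "Quantifying keratin filament networks with filnet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying keratin filament networks with filnet: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filnet)
```

## The problem

Keratin intermediate filaments form dense, fishnet-like 3D networks in
epithelial cells.  Open-active-contour segmentation of high-resolution
fluorescence stacks produces *snakes*: polygonal chains of vertices, each
with an xyz position (micrometres) and a brightness value that acts as a
proxy for local filament-bundle thickness.  Snakes delineate filament
centre lines well, but they are not associated with each other at
junctions — they may simply cross, touch, or stop near one another — so
they cannot directly answer questions about mesh topology, branching, or
network-scale anisotropy.

filnet turns a set of snakes into a coherent *node/segment* graph and
computes per-segment and per-cell architecture statistics on it.  Nodes
are junctions or loose ends; segments are node-bounded vertex chains that
retain the full polyline geometry and the brightness profile along them.

## Node detection by epsilon clustering

Two vertices belonging to *different* snakes that lie within a distance
`epsilon` of one another seed a candidate set; any further vertex within
`epsilon` of a member joins the set, until closure (single-linkage
transitive clustering).  Each closed set becomes one node at the
unweighted centroid of its members, every snake start/end vertex is also
a node, and snakes are split at member vertices into segments.

Decisions worth making explicit:

* **Intra-snake pairs are excluded.**  Consecutive vertices of one snake
  are always within `epsilon` of each other, so admitting intra-snake
  pairs would dissolve every snake into a single cluster.  Restricting
  the predicate to inter-snake pairs matches the purpose of the step —
  associating separate snakes at junctions — at the cost of not merging
  the rare self-contact loop of a single snake (detected cases are left
  split).
* **`epsilon` defaults to 1.1 × the reference voxel size** (the largest
  in-plane voxel edge, 0.065 um by default, giving 0.0715 um).  A single
  scalar radius is used in all three directions even though the optical
  axis is sampled more coarsely; the parameter is exposed in
  `graph_params()`.
* **Node centroids are unweighted.**  Brightness-weighted centroids were
  considered and rejected: junction brightness is dominated by overlap of
  the joining bundles and would bias node positions toward thick arms.
* **Zero-length segments cannot arise**: consecutive vertices of one
  snake assigned to the same node are contracted before segments are cut.
* **Determinism.**  Transitive closure has no order dependence; node ids
  are relabelled by sorted centroid so the output is identical under any
  permutation of the input snakes.

Segment endpoints are snapped to their node centroid (at most about
`epsilon` of displacement per node), so total arc length is conserved up
to `epsilon × n_nodes`, which the test suite asserts.  Node degree — the
number of incident segment endpoints — classifies branchings: 3 is a
Y-branch, 4 an X-crossing, 5 and above a star.  Degree-2 nodes (two
consecutive segments within one filament) are retained in the model but
excluded from the branching histogram, which starts at degree 3.

## Geometry metrics

* **Arc and chord length** are the discrete polyline quantities; the
  *bending ratio* chord/arc is 1 for a straight segment and approaches 0
  for a loop (coincident endpoints give exactly 0).
* **Curvature** is the magnitude of the derivative of the unit tangent
  with respect to arc length.  The discretization — uniform arc-length
  resampling (default step 0.044 um, the finest in-plane voxel size),
  centred moving-average smoothing over 5 samples, central-difference
  tangents — is a choice of this package; segmentation noise at airyscan
  sampling otherwise dominates the second derivative.  Circle and helix
  fixtures with known curvature (1/r and r/(r² + c²)) bound the
  discretization error below 5 % in the tests.  Segments too short for
  the stencil are reported as missing and counted, not silently dropped.
* **Apparent persistence length** pools tangent-pair correlations over
  all segments at binned contour lags and fits the 3D worm-like-chain
  decay ⟨cos θ(Δs)⟩ = exp(−Δs/Lp) by through-origin least squares on the
  log.  It is *apparent* because network segments are clamped at nodes
  rather than free; the convention is recorded in the output.  Straight
  input has no decay and reports `Inf`.  Default maximum lag is 2 um,
  comparable to the expected Lp itself; the fit is stable to within 10 %
  under halving the window on synthetic chains.
* **Brightness** of a segment is the unweighted mean of its vertex
  intensities (a length-weighted variant is available); per-cell
  brightness histograms are normalized so the brightest segment is 100,
  making cells with different illumination comparable.
* **Cell volume** thresholds the stack (fixed level or Otsu on the pooled
  histogram) and multiplies the voxel count by the voxel volume; network
  density is total segment length per volume.

## Orientation statistics

Segment endpoints are interchangeable, so orientation is defined modulo
180°: each chord is flipped to the canonical representative with azimuth
in [0°, 180°), elevation in (−90°, 90°].  Azimuth and elevation
histograms use 1° bins, and the deviation from a reference distribution
is the sum of absolute per-bin differences — 0 for a perfect match, at
most 2 − 2/nbins (all mass in one bin).  For elevation two references are
reported: the flat line (every degree equally likely) and the
solid-angle-corrected expectation proportional to cos(elevation), because
an isotropic 3D orientation field is *not* flat in elevation.  Both are
provided rather than asserting one as the intended reference.

The second analysis anchors segments at the cell centre (the mean of the
segments' mean positions): each chord is translated so its endpoint
closer to the centre sits at the origin, making all chords point outward.
Rose histograms (10° bins, weights summed from projected magnitudes) show
the xy and yz distribution, and the *sum vector* — outward unit
directions weighted by segment arc length — measures net polarity.  Its
magnitude normalized by total length, the anisotropy index, is 0 for an
isotropic network and 1 for a fully aligned one.  Ties (endpoints
equidistant from the centre) keep the stored orientation and are counted.
Arc length rather than chord length is used as the weight, favouring the
reading that each segment contributes its full filament length.

## Keratin mass estimation

Two independent estimators convert the total bundle length `L_tot` of a
cell into protein mass:

* **Mass-per-length**: `mass = MPL × L_tot × Bf / N_a`, with the
  experimentally determined MPL of 25 kDa/nm (range 19–30) for a single
  filament and a bundling factor Bf = 19 filaments per imaged bundle.
  For `L_tot` = 4.4 mm this gives 3.47 pg; for 1.63 mm, 1.3 pg.
* **Tetramer-based**: a 44-nm tetramer of 228,165 Da and 6 protofilaments
  per filament give a per-micrometre filament molecular weight of
  1000/44 × 228,165 × 6 ≈ 3.11 × 10⁷ Da; multiplied by `L_tot` and Bf
  this yields ≈ 2.60 × 10¹² Da ≈ 4.3 pg for 4.4 mm.  Note that the
  per-micrometre intermediate sometimes quoted as 1.24 × 10⁸ Da is not
  consistent with these inputs or with the 2.60 × 10¹² Da total; filnet
  computes the chain from first principles, which reproduces the total.

Masses are printed at two significant figures (three where the inputs
support it); both estimators are linear in `L_tot` and Bf with a constant
ratio ≈ 25/31.1.  `tissue_extrapolation()` scales a per-cell length to a
population (0.14 × 10¹² epidermal cells × 4.4 mm ≈ 6 × 10⁵ km of
bundles).

## Rendering-based validation

To check a segmentation against its source stack, every vertex is drawn
as a filled in-plane disc on its nearest z-slice with diameter
proportional to brightness, contributions adding; the disc stack is then
blurred with a separable 3D Gaussian (default sigmas 5, 5, 3 pixels in x,
y, z — interpreted as sigmas, the convention of the common 3D Gaussian
blur implementations, and configurable) to simulate the microscope.
Agreement is scored as the Pearson correlation of voxel intensities,
globally and per slice, replacing purely visual inspection with a
number.  Discs are drawn in-plane only; no attempt is made to model the
true anisotropic point-spread function beyond the Gaussian.

## The synthetic-data generator

No public synthetic ground truth exists for keratin networks, so the
package generates its own and treats it as the reference for every
pipeline stage:

* **Filaments** are discrete worm-like chains: per step of length `h` the
  tangent is perturbed by two transverse Gaussian components of variance
  `h/Lp`, so the tangent correlation decays as exp(−Δs/Lp) (3D
  convention).  Defaults: persistence length 2.6 um — the value measured
  for network-embedded keratin — step 0.1 um, filament length 5 um,
  in a 15 × 15 × 4 um box resembling a flat epithelial cell.
* **Junctions** are planted by splitting a chain at an interior vertex
  into two snakes and attaching a branch chain whose first vertex lies
  within `junction_jitter` (default 0.02 um < epsilon/2) of the split
  vertex, starting perpendicular to the parent — the geometry of a
  Y-branch.  Emitted snakes therefore break exactly at planted junctions
  and each snake is one ground-truth segment with its own log-normal
  brightness (median 50 a.u., log-sd 0.5).
* **Separation.**  With `min_separation` set, chains are resampled until
  they keep that distance from previously placed ones outside planted
  junction neighbourhoods; with `min_separation > 2 epsilon` the graph
  module must recover the planted node set exactly, and the tests demand
  exactly that.
* **Voxelization** deposits brightness-proportional line density into an
  anisotropic voxel grid (defaults 0.065 um in plane, 0.18 um axially),
  blurs with a Gaussian PSF (0.13 um lateral, 0.3 um axial) and adds
  Gaussian read noise plus optional Poisson shot noise.  Brightness acts
  as fluorophore density per unit length, so total noise-free signal is
  proportional to Σ brightness × length, which is asserted in the tests.

What the generator does *not* emulate: airyscan detector geometry,
segmentation failures of the contour evolution itself, intensity
variation along a bundle, and filament-thickness point-spread coupling.
Green tests on synthetic data therefore demonstrate correctness of the
graph/metric pipeline downstream of segmentation, not robustness of
segmentation itself.

`fixture_suite()` adds six deterministic named regimes — isolated
filament, Y-junction, X-crossing, star node, a polarized parallel array
(keratinocyte-like, anisotropy index > 0.8) and an isotropic shell
(simple-epithelium-like, anisotropy index < 0.05).  The parallel fixture
deliberately concentrates most of its arc length in a few long bundles on
one side of the (segment-count weighted) cell centre, since outward
canonicalization cancels any arrangement that is symmetric about the
centre.

## Problem sizes and reproducibility

The shipped tests run the clustering oracle on snake sets of up to 200
vertices (checked against an exact brute-force closure), persistence
recovery on chain ensembles of total length 500 × Lp, orientation
Monte-Carlo bounds on 10³–10⁴ seeded draws, and the blur oracle on 16³
stacks — sizes chosen so the full suite completes in a couple of minutes
while keeping every statistical bound comfortably away from its
threshold.  All stochastic components take explicit seeds; the same seed
reproduces snake files, truth tables and stacks byte for byte.

## Known limitations

* Published per-cell-type measurements (segment length, density,
  curvature, and so on) depend on the original microscopy recordings;
  they ship as regression bands (`reference_measurements()`) applied only
  when that archived data is available locally, not as synthetic-data
  assertions.
* The cell-volume numbers quoted alongside those measurements (a few
  um³ for cells tens of micrometres across) are internally inconsistent
  with the quoted densities; filnet always computes volume from the
  stack rather than assuming literature values.
* TSOAX tracking of networks across movie frames, manual cell-border
  cropping, and cinematic-renderer scripting are out of scope; OBJ
  export writes polylines (or tessellated tubes) with a per-segment
  radius sidecar because the OBJ format has no portable line-thickness
  attribute.
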