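# filnet

Graph reconstruction and quantification of keratin intermediate-filament
networks from 3D fluorescence segmentations.

## What it does, and for whom

Keratin filaments form dense 3D networks in epithelial cells.
Open-active-contour ("snake") segmentation of high-resolution fluorescence
stacks yields polygonal chains of vertices — each with an xyz position in
micrometres and a brightness value proportional to local bundle thickness —
but leaves the chains unconnected at junctions.  filnet is for cell
biologists and biophysicists who have such segmentations (e.g. TSOAX
output) and want a coherent, quantitative network model of the whole cell.

The core step is an epsilon-proximity clustering: vertices of *different*
snakes within `ε = 1.1 × voxel size` of one another are merged (single
linkage, transitively closed) into **nodes**; snakes are split at node
members into **segments**, node-bounded chains that keep the full polyline
geometry and brightness.  On this node/segment graph the package computes:

* branching statistics — node degree 3 = Y-branch, 4 = X-crossing, ≥5 = star;
* per-segment geometry — arc/chord length, bending ratio (chord/arc),
  curvature `κ = |dT/ds|` of the smoothed resampled chain;
* per-cell totals — mean and total segment length, filament density
  (length/volume), brightness histograms normalized to max = 100,
  thickness–curvature Pearson correlation;
* apparent persistence length from the pooled tangent correlation
  `⟨cos θ(Δs)⟩ = exp(−Δs/Lp)`;
* orientation statistics — fold-invariant azimuth/elevation histograms
  with uniformity-deviation scores, centre-translocated radial histograms,
  and the length-weighted sum vector whose normalized magnitude is an
  anisotropy index in [0, 1];
* keratin mass — `mass = MPL · L_tot · Bf / N_a` with MPL = 25 kDa/nm and
  bundling factor Bf = 19, plus an independent tetramer-based estimate
  (44 nm, 228,165 Da, 6 protofilaments), and tissue-scale extrapolation;
* rendering-based validation — vertices re-drawn as brightness-proportional
  discs, Gaussian-blurred, and correlated against the original stack;
* a seeded synthetic-data generator (worm-like-chain filaments, planted
  junctions, voxelization with PSF and noise) providing ground truth for
  every stage.

## Worked example

Generate a synthetic cell, build the network, and quantify it:

```r
library(filnet)
p <- synth_params(n_filaments = 12, branch_probability = 0.5,
                  min_separation = 0.2, box = c(20, 20, 5), seed = 1)
gen <- generate_network(p)
model <- build_network(gen$snakes, graph_params(), cell_id = "demo")
model
#> <filament_network> 'demo': 36 nodes, 24 segments, 89.61 um total length
#>   epsilon = 0.0715 um; branching nodes (degree >= 3): 6

node_degree_histogram(model)      # all planted branches are Y-junctions
#>   3
#>   1

cell_totals(model)
#> <cell_metrics> 'demo'
#>   segments: 24, mean length 3.734 um, total 0.0896 mm
#>   apparent persistence length: 1.75 um
#>   thickness-curvature Pearson r: -0.069

orientation_summary(model)
#> <orientation_summary> 24 segments
#>   azimuth deviation:   1.7444
#>   elevation deviation: 1.7333 (flat), 1.6535 (solid angle)
#>   anisotropy index:    0.2509  sum vector (3.81, 15.60, 15.73) um
```

The 36 recovered nodes and their degrees match the generator's planted
ground truth exactly (`gen$truth`); total arc length agrees to well under
1 %.  The large orientation deviations reflect the small segment count
(24 segments spread over 180 one-degree bins), and the persistence length
is *apparent* — segments are clamped at nodes, so it underestimates the
chain parameter (2.6 um here).

Keratin-mass estimates scale the measured total length; at the bundle
lengths measured for keratinocytes (4.4 mm per cell):

```r
mass_report(4.4)
#> <mass_report> total bundle length 4.4 mm
#>   mass-per-length estimate: 3.47 pg
#>   tetramer-based estimate:  4.3 pg (total MW 2.6e+12 Da)
```

A command-line front end wraps the same functions
(`system.file("cli", "filnet.R", package = "filnet")`) with subcommands
`convert`, `metrics`, `orient`, `mass`, `validate`, `synth`, `export-obj`
and `report`; every run writes a provenance block (version, parameters,
input hashes).

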