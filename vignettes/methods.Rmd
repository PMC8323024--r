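---
title: "Trait extraction from maize chlorophyll fluorescence images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait extraction from maize chlorophyll fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizecfi)
```

## The imaging model

Chlorophyll re-emits part of the absorbed excitation light as fluorescence.
A monochrome camera behind a long-pass filter, synchronized with a blue LED
strobe, therefore sees plant tissue as the only bright object in the scene:
the background of the imaging booth emits essentially nothing in the
fluorescence waveband. Unlike color-index segmentation, this works for
plants of any hue or developmental stage, which is what makes a single
global threshold viable in a high-throughput facility.

The package's coordinate convention is raster order: pixels are `(row,
col)`, row 1 at the top, and the "height" of a pixel is its distance from
the bottom image row. The vendor's camera calibration is replaced by a
single isotropic scale `cm_per_px`: lengths scale linearly and areas
quadratically, which is sufficient for every reported trait. Possible lens
or distance-dependent nonlinearity is not modeled.

## The pipeline, stage by stage

**Segmentation.** Otsu's criterion picks the integer threshold maximizing
the between-class variance of the histogram; pixels at or above the
threshold are foreground. Ties (possible for symmetric histograms) resolve
to the smallest maximizing threshold, recognized through a `1e-9` relative
window so floating-point noise cannot promote a larger one. The binary mask
is cleaned by morphological opening then closing with a disc
(`morph_radius_px`, default 2 px — opening first removes specks before the
closing seals small gaps), components below `min_component_px` (default 64)
are dropped, and only the largest component is kept, since the facility
images one plant at a time.

**Skeletonization.** The mask is thinned to a one-pixel-wide, 8-connected
skeleton by Zhang–Suen parallel thinning followed by a sequential minimal
thinning pass that deletes simple pixels (Yokoi's 8-simplicity test, with
endpoints protected). The second pass matters: the parallel algorithm
leaves "staircase" corner pixels along shallow diagonal strokes, and every
such pixel reads as a spurious degree-3 junction when landmarks are
counted. Terminal branches shorter than `spur_length_px` (default 10 px)
are then pruned iteratively; pruning re-minimalizes, because a removed spur
can leave its base pixel as a redundant bump on the main line.

**Landmarks.** Endpoints have exactly one skeleton neighbour, branch points
three or more; adjacent branch pixels are merged into clusters and each
cluster is represented by its member pixel nearest the cluster centroid.
The *stem start* is the endpoint with the largest row whose column lies
within `midline_tolerance_frac` (default 5 % of mask width) of the mask's
half-area column — the column where the cumulative column-wise area reaches
50 %. A tolerance is mandatory with discrete pixels; the half-area column
operationalizes "the plane splitting the mask into two equal halves". A
drooping leaf tip may sit lower than the stem base, but being far from the
midline it stays a leaf tip. If no endpoint qualifies, the lowest endpoint
is used and the record flagged `stem_start_fallback`, which keeps batch
runs alive while letting flagged rows be filtered later.

**Top node and stem.** In vegetative maize the whorl of unexpanded leaves
towers over the top collar, so the skeleton's center of mass sits near the
top node; the branch point nearest the center of mass (ties: smaller row,
then column) is the top node. The stem path is recovered from the two
geodesic distance fields `d(·, start)` and `d(·, top)` on the skeleton
(unit-cost 8-connected steps — the chessboard metric; the oracle
equivalence and minimality contracts in the tests are stated for this
choice). Their sum attains its regional minimum exactly on the shortest
start-to-top paths, and one such path is reconstructed deterministically by
stepping down the distance-from-start field in fixed neighbour order.

The Euclidean distance transform of the mask, sampled along the path, gives
a per-pixel radius profile. Each sample is reduced by 0.5 px because the
transform measures pixel-center to pixel-center and overshoots the
geometric half-width by half a pixel (the center of a 7-px bar is 4 px from
the first background center but 3.5 px from the boundary). The profile is
median-filtered (`median_window`, default 11, odd; paths shorter than the
window skip the filter and are flagged) and the representative radius is
the median of the filtered profile — robust against the junction bulges
where leaves meet the stalk. The stem mask collects foreground within the
*local* filtered radius of each path pixel, which follows the stalk's taper;
a single global radius either leaves flared-base slivers (that later
masquerade as leaf blobs) or swallows leaf bases near the thin top.

Because "top node height" may mean the chord or the vertical, both are
exported (`stem_height_cm`, straight-line; `vertical_stem_height_cm`), plus
the arc length of the path (`stem_path_length_cm`). The side view measures
the stalk's apparent width; maize stalks are elliptical in cross-section,
so the diameter can overestimate a caliper measurement of the minor axis —
acknowledged, not corrected.

**Leaves.** Subtracting the stem mask leaves the blades and the whorl.
Components smaller than `min_component_px` are discarded but counted, so
the pixel accounting `|plant| = |stem| + |whorl| + Σ|leaf| + |discarded|`
is exact on every run. The highest-center-of-mass blob is the whorl and is
removed; the rest rank bottom-up (the breeder's convention: leaf 1 is the
oldest, lowest leaf). Per-leaf area is the pixel count times `cm_per_px²`.

The tip-to-stem angle θ is measured at the leaf's attachment between the
attachment→tip vector and the stem's local upward direction; upright leaves
give small angles, drooping leaves exceed 90°. Two stability choices are
deliberate. First, the attachment is *not* the single path pixel nearest
the blob: along a collar many path pixels are near-minimal and a hard
argmin hops several pixels when the blob boundary moves by one (mirroring
the image does exactly that), so the vertex is the path location at the
mean height of the blob's collar — the blob pixels within 2.5 px of its
closest approach to the path. Second, the local stem direction is a
principal-axis fit over a 15-px path window that *excludes* the ±3 pixels
nearest the attachment (and shifts fully below the junction for the top
leaf): right at a collar the merging leaf displaces the skeleton by a pixel
or two, which would tilt the fitted axis toward the leaf. Together these
moved the worst-case mirror disagreement from ≈1.5° to under 0.8° and
improved angle recovery on the synthetic suite. The upward (not downward)
stem direction is the reference because it reproduces the expected reading
of drought responses — rolled, more upright leaves give *smaller* angles.

Blobs containing zero or several leaf-tip landmarks are merged or occluded
leaves: they are reported with area but no angle and flagged
`occluded_merged_leaf`, rather than split heuristically. No drooping-leaf
rank correction is attempted.

**Whole plant and orientation.** Height and width are inclusive bounding
box extents (`max − min + 1` pixels); the side-projected area is the
foreground count. The top-view orientation is the angle of the farthest
pair of foreground pixels, folded into `[0, 180)`; the convex hull is used
as a pure speed-up since the farthest pair is always realized on hull
vertices, and ties resolve to the smaller angle.

## The synthetic plant generator

The generator renders the study conditions under which the method is
meant to operate: single vegetative maize plants (V4- to V10-like), bright
on dark. A plant is a vertical tapered stem drawn from the soil line to the
top node (a few crown rows continue below the soil line, as a silhouette
does not end flat at the media surface; ground-truth heights are measured
from the soil line, as a ruler would); curved leaf blades attached at
collars along the stem; and an apical whorl — a rolled-leaf sheath
continuing above the top collar plus a fan of emerging blades. Each blade
starts narrow at its ligule (width ramps up over the first ~18 % of the
blade), leaves the stem with a horizontal tangent, and its collar-to-tip
chord makes the prescribed tip angle with the stem; the blade tapers toward
the tip. Strokes are stamped as discs along a quadratic arc with
half-pixel radius quantization.

Intensities follow the high-contrast CFI regime: foreground
`N(200, 8)`, background `N(20, 5)` on 8 bits, optional Gaussian blur
(default none — the facility's optics resolve blade edges at this working
distance, and noise alone already exercises the thresholding). The spec
enforces `fg_mean − bg_mean ≥ 5 max(sd)`.

Three generator design choices deserve justification:

* **Open-close regularization.** The rendered silhouette is smoothed by
  the same opening-then-closing disc filter the segmentation cleanup
  applies, then reduced to its largest component. The open-close filter is
  idempotent, so the pipeline's cleanup reproduces the rendered mask
  *exactly* on noiseless input — recovery tests measure algorithm error,
  not rasterization error. Small fragments pinched off by the opening
  (thin whorl blade tips) vanish from the ground truth exactly as they
  vanish from a cleaned mask; a render in which a leaf loses more than
  30 % of its pixels this way is rejected as an invalid specification.
* **Whorl sizing.** Top-node detection assumes the skeleton's center of
  mass sits at the top node, which in a real vegetative plant is enforced
  by the massive whorl. The tier templates solve for the whorl blade
  length that places the predicted skeleton center of mass just above the
  stem apex, using chord-length mass for the leaves and a measured
  skeleton moment for the whorl fan (its blades merge near their common
  origin, which no closed form captures well). This is emulation, not
  tuning: it reproduces the architectural regime in which the method is
  valid: roughly through V8, after which overlapping canopies break it —
  exactly the breakdown the overlap tier exhibits.
* **Ground truth is measured, not prescribed.** All truth values — areas,
  the tip position, the tip angle, the stem diameter — are measured on the
  regularized label image. The stem diameter ground truth is the mean
  stem width over all stem rows, the multi-location ruler average of the
  manual protocol; a single mid-row width would quantize in 2-px jumps
  (±20 % at a 10-px stalk). Measured chord angles sit within a few degrees
  of the prescribed nominal angles (tip rounding shifts the farthest-pixel
  chord slightly on drooping blades).

The default suite grades six tiers (V4…V10: 2 to 8 expanded leaves, stem
90 to 230 px at 0.2 cm/px, i.e. stem heights 18–46 cm and diameters around
1.8–2.4 cm — the vegetative range at desk scale). Leaf length increases
and droop decreases with rank, as in vegetative maize; sides alternate in
spirit but are assigned greedily to balance the lateral skeleton moment, so
the column center of mass stays on the stalk. Tip angles are drawn from
roughly [58°, 108°] (a ramp from 105° to 66° plus ±3° jitter): a subset of
the plausible [30°, 130°] range, restricted to where rank-by-center-of-mass
and whorl-topmost assumptions hold for *every* leaf simultaneously —
extreme angles are exercised separately by `prescribed_angle_plant()`,
which renders chords at 30/60/90/120° (pairing the angles so same-side
blades diverge, and keeping the steepest angle off the top collar so no
blade out-tops the whorl). The largest tier deliberately crosses two
same-side mid-canopy blades (52° under 88°, straightened so the cross sits
mid-blade and both tips survive): its merged blob carries two tip
landmarks and must come out flagged, not silently wrong — the behaviour a
practitioner should expect from late-vegetative canopies.

What passing on this suite does *not* show about real data: renders have no
pot, no senescent low-fluorescence tissue, no tillers, no specular
reflections, no blade twisting or perspective foreshortening, and noise is
Gaussian and pixel-independent. The suite validates the geometry engine —
thresholding under ideal bimodality, skeleton topology, geodesic stem
recovery, blob accounting — not the full variability of facility imagery.

## Numerical choices and degenerate inputs

* Geodesic metric: unit-cost 8-connected steps; `stem_path` returns one
  deterministically reconstructed shortest path (fixed neighbour scan
  order) whose step count equals the BFS distance.
* Tie-breaks are deterministic everywhere: smallest threshold (Otsu),
  smaller row then column (top node, branch representatives, stem start),
  smaller angle (orientation ties), first-in-scan-order component labels.
* Constant images raise a degenerate-histogram error; empty masks raise
  `no_plant`; a plant with no branch point (no expanded leaf) yields
  whole-plant traits with stem and leaf traits absent and a `no_top_node`
  flag; stem paths shorter than the median window skip the filter with an
  `unfiltered_radius` flag.
* The pipeline contains no randomness: re-running a batch yields
  byte-identical CSVs. Only the generator consumes seeds, through an
  RNG-state-preserving scope.
* Problem sizes in the tests: the study suite is 30 plants on a 430×640
  canvas; oracle sweeps use 200 images (Otsu), 100 skeletons (BFS), and 50
  blobs (orientation) — sizes at which the brute-force oracles are exact
  and the whole suite runs in a couple of minutes.

## Known limitations

* Stem height carries a small negative bias (≈1–3 %): thinning erodes the
  skeleton endpoint a few pixels up from a blunt mask bottom, and the
  detected top node sits a pixel or two below the collar.
* The side-view diameter overestimates an elliptical stalk's minor axis.
* Counting degrades by design on overlapping canopies (merged blobs are
  flagged, and a top leaf folded into the whorl is undercounted); no
  de-occlusion is attempted. Reproductive-stage plants, whose center of
  mass shifts away from the top node, are out of scope.
* Windowed/adaptive thresholding for partially senescent plants is out of
  scope; the global threshold assumes tissue fluoresces more or less
  uniformly.
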