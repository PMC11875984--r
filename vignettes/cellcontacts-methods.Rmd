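---
title: "Methods: interaction profiling and polarization in 3D multiplexed volumes"
author: "cellContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction profiling and polarization in 3D multiplexed volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models it
implements, the parameters that matter, the numerical conventions it
commits to, and what its synthetic validation does and does not show.

## Data model

A `MultiChannelVolume` holds a `(channel, z, y, x)` array of non-negative
intensities plus the physical voxel size `(sx, sy, sz)` in micrometers.
Multiplexed acquisitions are strongly anisotropic (hundreds of nanometers
laterally, two to three times that between sections), so **all geometry is
done in physical units**: a voxel index `(ix, iy, iz)` maps to the point
`(ix·sx, iy·sy, iz·sz)`, the center of that voxel, with 0-based indices.
Cell centers are kept in voxel coordinates (fractional values allowed, so
positions can be adjusted at sub-voxel precision) and scaled on demand.

Volumes are stored as plain multi-page TIFF (channel-major page order)
with a JSON sidecar carrying shape, spacing, channel names and an
intensity scale. Samples are 32-bit fixed point scaled into [0, 1] by a
power-of-two factor; metadata round-trips exactly and intensities to
about 2⁻³¹ of the intensity range, which is far below microscope noise.
Exports of results are CSV (17 significant digits) or JSON (full double
precision).

## Cell graph

Candidate interactions are the **Gabriel graph** of the cell centers: the
subset of 3D Delaunay edges `{a, b}` for which no third center lies
strictly inside the open ball with diameter `ab`. Conventions:

* **Open-ball test, ties keep the edge.** A point exactly on the sphere is
  boundary contact, not intrusion.
* **Degenerate inputs.** Exactly coplanar point sets (possible in thin
  sections) are triangulated in 2D within their best-fit plane (by
  singular value decomposition of the centered coordinates, relative
  rank tolerance 1e-9); exactly collinear sets become a chain of
  consecutive points; two points form the single edge. Coincident points
  (distance < 1e-12 µm) are rejected naming the pair.
* **Determinism.** Edges are stored as sorted id pairs in lexicographic
  order; rebuilding from identical input reproduces the identical graph.

The triangulation itself is computed by exhaustive empty-circumsphere
testing over all 4-point subsets (compiled code). At the scale the
package targets — tens to a few hundred labeled cells per field — this
costs well under a second, is free of the robustness machinery an
incremental triangulator needs, and cross-checks exactly against an
independent triangulation library on random point sets. Near-degenerate
tetrahedra (relative determinant below 1e-10) are skipped; cospherical
ties keep all valid tetrahedra, so the edge union is the union over all
valid triangulations of the tie.

**Graph edits.** Node additions, removals and moves trigger a full
recompute (no incremental update: correctness over micro-optimization at
this scale). User edge edits are persisted as flags and re-applied after
every recompute: removals persist indefinitely; additions persist while
both endpoints exist. An edge added by hand is *not* re-filtered by the
Gabriel criterion — the user's judgment overrides the heuristic.

## Interaction profiles

For an edge `e = (a, b)` and integration shape (cylinder of radius `r`,
or bicone), every voxel center `v` with parameter
`t = ⟨v−a, b−a⟩/|b−a|²` in `[0, 1]` and perpendicular distance within the
shape is assigned to bin `min(⌊t·n⌋, n−1)` of `n` equal-length bins; the
per-bin, per-channel arithmetic mean of the member voxel intensities is
the profile. Conventions and defaults:

* **Bicone orientation**: apexes at the two cell centers, maximum radius
  `r` at the midpoint — the shape grows toward the inter-cell space and
  captures the spherical sectors of the two cells that face each other.
* **Radius**: given in micrometers or in voxels; voxel radii convert via
  the lateral (x) voxel size. Default `r` = 25 voxels, a practical
  setting for ~10 µm cells at 220 nm lateral resolution.
* **Bin count**: `max(2, round(|e| / sx))` — about one bin per lateral
  voxel of edge length.
* **Voxel membership is point sampling** at voxel centers, no
  partial-volume weighting: simple, exactly reproducible, and directly
  checkable against a brute-force all-voxel oracle (the test suite does
  this at 1e-9).
* **Empty bins** (inevitable near bicone apexes at fine binning) record
  mean 0 with a voxel count of 0; an optional flag fills them by linear
  interpolation but never alters the recorded counts — the package does
  not fabricate signal silently.
* **Normalization** is min–max per (edge, channel) to [0, 1]; a constant
  profile maps to all zeros rather than 0/0.
* **Orientation symmetry.** Membership and binning are computed in a
  canonical edge orientation (smaller node id first) and flipped on
  output, so the profile of `(b, a)` is the *exact* bin-reversal of
  `(a, b)` — not merely equal to rounding.

## Profile similarity and ranking

Profiles are compared channel by channel with the mean Minkowski
distance `(mean |Xᵢ − Yᵢ|^p)^(1/p)` at `p = 1` (a metric; absolutely
homogeneous of degree 1), after resampling the second profile to the
first's bin count by endpoint-anchored linear interpolation (resampling
to the same length is the identity, bit for bit). Channel distances are
**summed** into the total. Distances are computed on the normalized
profiles by default — comparisons then reflect signature shape, not
staining intensity — with a raw-intensity option for magnitude-sensitive
work.

The default metric compares *aligned* positions; a signal shifted by one
bin scores poorly even though a human would call the shapes similar. For
that use case a classical 1D optimal-transport variant is provided
(`metric = "wasserstein"`): each profile is normalized to a probability
mass over bins (an all-zero profile counts as uniform) and the mean
absolute CDF difference is returned. The aligned metric remains the
default because it is the simpler, more predictable instrument; the
choice is recorded in every `RankingResult`.

Ranking sorts candidates ascending by total distance with ties broken by
lexicographic edge key, so results are invariant to candidate input
order; the reference edge itself, when among the candidates, ranks first
at distance exactly 0.

## Polarization

For a cell center `N`, voxels with `inner < |v − N| ≤ r` (micrometers)
are projected orthogonally into a viewing plane with unit normal `u`;
the clock angle `θ = atan2(⟨q, east⟩, ⟨q, north⟩)` (with
`east = north × u`, angles clockwise when viewed along `−u`) assigns the
voxel to sector `⌊θ/30°⌋` of 12. Conventions:

* **Default frame**: `u = +z` (the native section plane) and `north` =
  the projection of `−y`, so "12 o'clock" is screen-up under the y-down
  image convention. Any frame can be requested; a view change is a full
  recompute with no cached sector assignments.
* **Aggregator**: `mean` per sector by default — sector voxel counts
  differ by discretization, and the mean is robust to that; `sum` is
  available and conserves total in-shell intensity exactly (sector sums
  add up to the included voxels' total). Sector statistics are computed
  on voxels directly; for sum aggregation this is identical to first
  accumulating a projected pixel plane.
* **Numerically zero in-plane projections** (`|q| < 1e-9 µm`, e.g.
  voxels on the viewing axis) are excluded rather than assigned to an
  arbitrary sector.
* **Normalization** divides each channel by its sector maximum (all-zero
  channels stay zero), giving the clock-face and unrolled-heatmap
  displays a common [0, 1] scale.
* `innerRadius` (default 0) can exclude the nuclear core when membrane
  polarization should not be diluted by nuclear signal.

## Synthetic volumes and what the tests show

The generator composes channels from analytic primitives evaluated at
voxel centers — Gaussian nuclear blobs, Gaussian-shell membranes, bicone
interaction signal peaking at the edge midpoint, membrane shells
modulated by a von Mises angular density `exp(κ·cos(θ − θ₀))` — plus a
constant background and additive Gaussian noise clipped at zero, all
driven by one seeded RNG stream (the seed is recorded in the truth
object). Cells are placed by rejection sampling with a minimum
separation of two cell radii. Defaults mirror a realistic acquisition:
anisotropic 0.22 × 0.22 × 0.28 µm spacing, ~80 cells of 3 µm radius in a
256 × 256 × 64 volume.

The scaled case-study scene (`caseStudyFixture`) emulates an
immune-oncology panel at desk scale: 8 channels named after common
markers, 256 × 256 × 55 voxels, 20 cells, with (i) a PD1/PDL1
co-localized pair, (ii) a "separated-centers" pair (PD1 in one cell's
center, PDL1 in the other's), and (iii) one CD8A-polarized cell at
θ₀ = 75° (sector 2). Filler cells are kept out of the planted pairs'
diameter balls so both planted edges are guaranteed Gabriel edges.

Validation choices worth stating explicitly:

* **Planted-direction recovery** draws θ₀ uniformly over sectors but
  with a 3° margin from sector boundaries. A direction *on* a boundary
  splits its angular mass evenly between two sectors, so "the argmax
  sector contains θ₀" is not a well-posed expectation there; the margin
  makes the planted truth decidable while exercising the full circle.
  Each trial uses a 44 × 44 × 36 volume, shell radius 2.5 µm, κ = 4 and
  a peak-amplitude-to-noise ratio of 3.
* **Problem sizes.** Oracle equivalence runs on 60-point clouds (graph,
  20 seeds) and 32³ volumes (profiles, 10 seeds); the end-to-end run
  uses the full fixture. These sizes make every brute-force oracle exact
  and the whole suite complete in a couple of minutes.
* **What passing does not show.** The generator has no point-spread
  function, no autofluorescence, no segmentation error, and its noise is
  Gaussian and spatially white — real immunofluorescence differs on all
  counts. Passing tests certify the *geometry and arithmetic* of the
  pipeline (membership, binning, distances, sectors, determinism), not
  robustness to real acquisition artifacts; thresholds for real data
  still need to be chosen per channel (`applyChannelConfig`).

## Known limitations

* The brute-force triangulation is quartic in the number of cells; it is
  instant for hundreds of cells but not intended for tens of thousands.
  The design favors exactness and zero tuning at the tool's actual scale.
* Volumes are held in memory as dense double arrays (~230 MB for the
  case-study scene); there is no out-of-core tiling.
* Thresholding zeroes sub-threshold voxels (a monotone noise gate), not
  background subtraction; value ranges clamp after thresholding.
* Profile normalization is per (edge, channel); comparing raw intensity
  magnitudes across edges requires the `useNormalized = FALSE` path.
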