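# cellContacts

Quantifying cell–cell interactions and single-cell marker polarization in
multi-channel 3D immunofluorescence volumes.

Highly multiplexed imaging (e.g. cyclic immunofluorescence) produces one 3D
intensity channel per protein marker over a tissue volume. Given such a
volume and a table of labeled cell centers, two questions drive spatial
analysis at single-cell resolution: *which pairs of adjacent cells are
candidates for a direct interaction* (for instance an immune synapse with
PD1/PDL1 co-localized between a T cell and a tumor cell), and *how is a
marker distributed angularly around an individual cell* (is a T cell's CD8
polarized toward a neighbor?). `cellContacts` answers both headlessly and
reproducibly, for biologists and image analysts working with volumes on the
order of 10^2 cells and tens of channels.

## Method

**Cell graph.** Cell centers (voxel coordinates scaled to micrometers by the
voxel spacing) are triangulated in 3D (Delaunay) and trimmed to the
**Gabriel graph**: edge {a, b} survives iff no third center c lies strictly
inside the open ball with diameter ab, i.e. ‖c − (a+b)/2‖ < ‖a − b‖/2 for
no c. This removes long Delaunay edges that "pass by" an intervening cell,
leaving plausible neighbor contacts. Exactly coplanar and collinear inputs
(thin sections) fall back to 2D triangulation in the best-fit plane or a
chain. Node edits recompute the graph in full; user edge additions/removals
persist across recomputes.

**Interaction profiles.** For a graph edge e = (a, b), every voxel center v
inside a cylinder of radius r around e — or a bicone with apexes at the two
cells and radius r at the midpoint — is projected onto the edge at
parameter t = ⟨v−a, b−a⟩/‖b−a‖², binned into n equal-length bins, and
averaged per bin and channel. The per-channel profile is min–max
normalized to [0, 1], yielding a channels × positions heatmap per edge.

**Profile similarity.** Two profiles X, Y of equal length n are compared by
the mean Minkowski distance

&nbsp;&nbsp;&nbsp;&nbsp;W_p(X, Y) = ( (1/n) Σᵢ ‖Xᵢ − Yᵢ‖^p )^(1/p), p = 1 by default,

summed over channels; profiles of different lengths are first resampled to
the reference length by endpoint-anchored linear interpolation. A CDF-based
variant (`metric = "wasserstein"`), robust to phase shifts along the edge,
is available. Ranking all edges against a reference edge surfaces
interactions with a similar marker signature.

**Polarization.** Voxels in a spherical shell around a cell are projected
orthogonally onto a viewing plane and binned into 12 clock-face sectors of
30° (sector 0 starts at "12 o'clock", clockwise). Per channel, sector
intensities are aggregated by mean (default) or sum and normalized by the
sector maximum — the angular signature of marker polarization relative to
the current view.

**Synthetic truth.** A generator builds volumes from analytic primitives
(nuclear blobs, membrane shells, bicone interaction signal, von
Mises-polarized shells) with planted, recorded ground truth, so the whole
pipeline is testable without external data.

## Worked example

```r
library(cellContacts)

fx <- caseStudyFixture(seed = 1)        # scaled melanoma-like scene
fx$volume
#> MultiChannelVolume: 8 channel(s), 256 x 256 x 55 (x,y,z) voxels
#>   spacing (um): 0.22 x 0.22 x 0.28
#>   channels: DNA, SOX10, CD3D, CD8A, PD1, PDL1, CD163, HLAA

g <- buildGraph(cellCenters(fx$truth), voxelSpacing(fx$volume))
g
#> CellGraph: 20 nodes, 29 edges (0 user-added, 0 user-removed)

profs <- computeProfiles(fx$volume, g, "all",
                         shapeSpec("cylinder", 25, "voxel"),
                         channels = c("PD1", "PDL1"))
rankEdges(c(1, 2), profs)
#> RankingResult: reference 1-2, 29 candidate(s), p=1, metric=pointwise
#>    a  b     total
#> 1  1  2 0.0000000
#> 2  5 12 0.5123679
#> 3  6 13 0.5366772
#> 4  8 17 0.5417670
#> 5 16 18 0.5705621

pol <- polarizeNodes(fx$volume, g, 5, radius = 3, channels = "CD8A")
round(pol[["5"]]@normalized, 2)
#>      [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10] [,11] [,12]
#> CD8A 0.18 0.61    1 0.64 0.18 0.05 0.03 0.03 0.03  0.03  0.03  0.05
```

The fixture plants PD1/PDL1 signal co-localized between cells 1 and 2;
ranking all 29 graph edges against edge 1–2 puts the reference itself first
at distance exactly 0, and the planted "separated-centers" pattern (PD1 in
cell 3's center, PDL1 in cell 4's center, edge 3–4) near the bottom. Cell
5 carries CD8A planted toward 75° clockwise from 12 o'clock; its sector
vector peaks at sector 2 (60°–90°), matching the recorded truth.

The same pipeline is scriptable from a shell via
`inst/scripts/cellcontacts.R` (subcommands `simulate`, `build-graph`,
`edit-graph`, `profile`, `rank`, `polarize`).

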