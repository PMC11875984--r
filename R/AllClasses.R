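#' @import methods
NULL

#' Multi-channel 3D imaging volume
#'
#' Container for a channel-indexed 3D intensity array with physical voxel
#' spacing, the raw material of all downstream interaction and polarization
#' analysis. Intensities are stored as a 4-D array indexed
#' `(channel, z, y, x)`; spacing is the physical size of one voxel along
#' `(x, y, z)` in micrometers. Voxel coordinates are 0-based and refer to
#' voxel centers, so voxel `(ix, iy, iz)` sits at physical position
#' `(ix * sx, iy * sy, iz * sz)`.
#'
#' @slot intensities 4-D numeric array `(channel, z, y, x)`, all values >= 0.
#' @slot spacing numeric(3), voxel size along `(x, y, z)` in micrometers.
#' @slot channelNames character vector, one unique name per channel.
#'
#' @exportClass MultiChannelVolume
setClass("MultiChannelVolume",
  representation(
    intensities = "array",
    spacing = "numeric",
    channelNames = "character"
  )
)

setValidity("MultiChannelVolume", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 4L)
    msg <- c(msg, "intensities must be a 4-D array (channel, z, y, x)")
  if (anyNA(object@intensities) || min(object@intensities) < 0)
    msg <- c(msg, "intensities must be non-negative and free of NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (x, y, z)")
  if (length(d) == 4L && length(object@channelNames) != d[1L])
    msg <- c(msg, "channelNames length must equal the channel dimension")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Cell neighborhood graph
#'
#' Nodes are labeled cell centers; edges are candidate cell-cell
#' interactions obtained by filtering the 3D Delaunay triangulation of the
#' centers down to its Gabriel graph, plus any user edits. Cell centers are
#' kept in voxel coordinates together with the voxel spacing so node
#' positions in micrometers can always be derived; user-added and
#' user-removed edges are persisted separately so they survive a full
#' recompute after node edits.
#'
#' @slot centers data.frame with columns `id`, `x`, `y`, `z`
#'   (voxel coordinates, possibly fractional).
#' @slot spacing numeric(3) voxel size `(x, y, z)` in micrometers.
#' @slot edges data.frame with integer columns `a`, `b` (`a < b`) and
#'   logical provenance flags `delaunay`, `gabriel`, `userAdded`.
#' @slot userAdded,userRemoved 2-column integer matrices of persisted
#'   user edge edits.
#'
#' @exportClass CellGraph
setClass("CellGraph",
  representation(
    centers = "data.frame",
    spacing = "numeric",
    edges = "data.frame",
    userAdded = "matrix",
    userRemoved = "matrix"
  )
)

setValidity("CellGraph", function(object) {
  msg <- character()
  cn <- object@centers
  if (!all(c("id", "x", "y", "z") %in% names(cn)))
    msg <- c(msg, "centers must have columns id, x, y, z")
  else if (anyDuplicated(cn$id))
    msg <- c(msg, "node ids must be unique")
  e <- object@edges
  if (!all(c("a", "b", "delaunay", "gabriel", "userAdded") %in% names(e)))
    msg <- c(msg, "edges must have columns a, b, delaunay, gabriel, userAdded")
  else if (nrow(e)) {
    if (any(e$a >= e$b))
      msg <- c(msg, "edges must be stored as sorted pairs a < b (no self-loops)")
    if (anyDuplicated(paste(e$a, e$b)))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!all(c(e$a, e$b) %in% cn$id))
      msg <- c(msg, "edges reference unknown node ids")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Per-edge interaction profile
#'
#' One-dimensional intensity distribution along a graph edge, one row per
#' image channel. Voxels inside a cylinder or bicone around the edge are
#' projected onto the edge, binned by their parametric position, and
#' averaged per bin. `normalizedIntensity` is the per-channel min-max
#' rescaling of `meanIntensity` to [0, 1] (all zero when the raw profile
#' is constant).
#'
#' @slot edge integer(2), node ids `(a, b)`; bins run from a to b.
#' @slot shape list with `kind` ("cylinder" or "bicone") and `radius`
#'   (micrometers).
#' @slot nBins integer, number of bins along the edge.
#' @slot binPositions numeric, physical distance (micrometers) of each bin
#'   center from node a; strictly increasing.
#' @slot meanIntensity,normalizedIntensity channel x bin matrices with
#'   channel names as row names.
#' @slot nVoxels integer per bin: voxels assigned to the bin (geometry
#'   only, shared across channels).
#' @slot edgeLength numeric, physical edge length in micrometers.
#'
#' @exportClass InteractionProfile
setClass("InteractionProfile",
  representation(
    edge = "integer",
    shape = "list",
    nBins = "integer",
    binPositions = "numeric",
    meanIntensity = "matrix",
    nVoxels = "integer",
    normalizedIntensity = "matrix",
    edgeLength = "numeric"
  )
)

setValidity("InteractionProfile", function(object) {
  msg <- character()
  nb <- object@nBins
  if (length(object@edge) != 2L) msg <- c(msg, "edge must be two node ids")
  if (nb < 2L) msg <- c(msg, "nBins must be >= 2")
  if (length(object@binPositions) != nb ||
      any(diff(object@binPositions) <= 0) ||
      any(object@binPositions < 0) ||
      any(object@binPositions > object@edgeLength + 1e-9))
    msg <- c(msg, "binPositions must be strictly increasing within [0, edgeLength]")
  if (ncol(object@meanIntensity) != nb ||
      ncol(object@normalizedIntensity) != nb ||
      length(object@nVoxels) != nb)
    msg <- c(msg, "per-bin slots must have nBins columns/elements")
  ni <- object@normalizedIntensity
  if (length(ni) && (min(ni) < -1e-12 || max(ni) > 1 + 1e-12))
    msg <- c(msg, "normalizedIntensity must lie in [0, 1]")
  if (!identical(rownames(object@meanIntensity),
                 rownames(object@normalizedIntensity)))
    msg <- c(msg, "channel row names must agree between intensity matrices")
  if (length(msg)) msg else TRUE
})

#' Cell-centric polarization profile
#'
#' Clock-face summary of marker intensity around one cell: voxels in a
#' spherical shell around the cell center are projected orthogonally onto
#' a viewing plane and binned into `nSectors` angular sectors (12 by
#' default, 30 degrees each, clockwise from "12 o'clock" = the `north`
#' direction when viewed along `-planeNormal`).
#'
#' @slot nodeId integer node id (NA for free positions).
#' @slot center numeric(3) cell center in voxel coordinates.
#' @slot radius,innerRadius numeric, shell radii in micrometers
#'   (`innerRadius < |v - center| <= radius`).
#' @slot planeNormal,north unit 3-vectors; `north` lies in the viewing
#'   plane and defines sector 0.
#' @slot nSectors integer, number of angular sectors.
#' @slot aggregator "mean" or "sum" per sector.
#' @slot sectorValue,normalized channel x sector matrices; `normalized`
#'   is `sectorValue` divided by its per-channel maximum (all zero for an
#'   all-zero channel).
#' @slot sectorCount integer per sector: included voxels (geometry only).
#'
#' @exportClass PolarizationProfile
setClass("PolarizationProfile",
  representation(
    nodeId = "integer",
    center = "numeric",
    radius = "numeric",
    innerRadius = "numeric",
    planeNormal = "numeric",
    north = "numeric",
    nSectors = "integer",
    aggregator = "character",
    sectorValue = "matrix",
    sectorCount = "integer",
    normalized = "matrix"
  )
)

setValidity("PolarizationProfile", function(object) {
  msg <- character()
  u <- object@planeNormal
  nr <- object@north
  if (abs(sum(u^2) - 1) > 1e-9 || abs(sum(nr^2) - 1) > 1e-9)
    msg <- c(msg, "planeNormal and north must be unit vectors")
  if (abs(sum(u * nr)) > 1e-9)
    msg <- c(msg, "north must be orthogonal to planeNormal")
  if (object@radius <= object@innerRadius || object@innerRadius < 0)
    msg <- c(msg, "need radius > innerRadius >= 0")
  k <- object@nSectors
  if (ncol(object@sectorValue) != k || ncol(object@normalized) != k ||
      length(object@sectorCount) != k)
    msg <- c(msg, "sector slots must have nSectors columns/elements")
  nm <- object@normalized
  if (length(nm) && (min(nm) < -1e-12 || max(nm) > 1 + 1e-12))
    msg <- c(msg, "normalized values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Edge similarity ranking
#'
#' Result of ranking candidate edges by profile distance to a reference
#' edge. Entries are sorted ascending by total distance with ties broken
#' by edge key; the total equals the sum of per-channel distances.
#'
#' @slot referenceEdge integer(2) node ids of the reference edge.
#' @slot entries data.frame with columns `a`, `b`, `total`, ordered.
#' @slot perChannel numeric matrix (entries x channels) of per-channel
#'   distances, rows aligned with `entries`.
#' @slot parameters list: `p`, `metric`, `channels`, `useNormalized`.
#'
#' @exportClass RankingResult
setClass("RankingResult",
  representation(
    referenceEdge = "integer",
    entries = "data.frame",
    perChannel = "matrix",
    parameters = "list"
  )
)

setValidity("RankingResult", function(object) {
  msg <- character()
  e <- object@entries
  if (!all(c("a", "b", "total") %in% names(e)))
    msg <- c(msg, "entries must have columns a, b, total")
  else {
    if (nrow(e) && is.unsorted(e$total)) {
      msg <- c(msg, "entries must be sorted ascending by total distance")
    }
    if (nrow(e) && any(e$total < -1e-12))
      msg <- c(msg, "distances must be non-negative")
    if (nrow(e) != nrow(object@perChannel))
      msg <- c(msg, "perChannel rows must align with entries")
    else if (nrow(e) &&
             max(abs(rowSums(object@perChannel) - e$total)) > 1e-12)
      msg <- c(msg, "total must equal the sum of per-channel distances")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic volume
#'
#' Record of everything planted by the synthetic-volume generator: cell
#' centers, interactions with their expected profile class, polarization
#' directions with their expected sector, the noise model and the RNG
#' seed, so every analytic stage can be checked against known answers.
#'
#' @slot centers data.frame `id`, `x`, `y`, `z` (voxel coordinates).
#' @slot plantedInteractions data.frame `a`, `b`, `channels`
#'   (comma-separated channel names), `class` (one of
#'   "midpoint-peak", "co-localization", "separated-centers").
#' @slot plantedPolarizations data.frame `node`, `channel`, `thetaDeg`,
#'   `expectedSector` (under the default viewing frame).
#' @slot noise list: `background`, `sd`.
#' @slot seed integer RNG seed used for generation.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    centers = "data.frame",
    plantedInteractions = "data.frame",
    plantedPolarizations = "data.frame",
    noise = "list",
    seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  pp <- object@plantedPolarizations
  if (nrow(pp) &&
      !all(pp$expectedSector == floor((pp$thetaDeg %% 360) / 30)))
    msg <- c(msg, "expectedSector must equal floor(thetaDeg / 30)")
  pi_ <- object@plantedInteractions
  if (nrow(pi_) && !all(c(pi_$a, pi_$b) %in% object@centers$id))
    msg <- c(msg, "planted edges must connect existing centers")
  if (length(msg)) msg else TRUE
})
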