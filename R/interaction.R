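#' Shape specification for edge-based voxel integration
#'
#' The region of interest around a graph edge: a cylinder of constant
#' radius, or a bicone with its apexes at the two cell centers and
#' maximum radius at the edge midpoint (so it captures roughly the
#' spherical sectors of the two cells that face each other).
#'
#' @param kind `"cylinder"` or `"bicone"`.
#' @param radius base radius, > 0.
#' @param unit `"um"` (default) or `"voxel"`; voxel radii are converted
#'   with the lateral (x) voxel size of the volume they are applied to.
#' @return a list of class `"ShapeSpec"`.
#' @export
shapeSpec <- function(kind = c("cylinder", "bicone"), radius, unit = c("um", "voxel")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("shape radius must be a single positive number")
  structure(list(kind = kind, radius = radius, unit = unit),
            class = "ShapeSpec")
}

.shape_radius_um <- function(shape, lateralSize) {
  if (identical(shape$unit, "voxel")) shape$radius * lateralSize
  else shape$radius
}

#' Point-in-shape test with edge projection
#'
#' Projects a point onto the segment ab and decides membership in the
#' integration shape. With `t = <v-a, b-a> / |b-a|^2` and `d` the
#' perpendicular distance to the line: a cylinder contains the point iff
#' `0 <= t <= 1` and `d <= r`; a bicone iff `0 <= t <= 1` and
#' `d <= r * (1 - |2t - 1|)` (radius 0 at both nodes, r at the midpoint).
#'
#' @param v point(s): numeric(3) or an n x 3 matrix, physical units.
#' @param a,b segment endpoints, numeric(3), physical units; `a != b`.
#' @param shape a [shapeSpec()]; a voxel-unit radius needs `lateralSize`.
#' @param lateralSize lateral voxel size in micrometers (only for
#'   voxel-unit radii).
#' @return list with logical `inside` and numeric `t` (parametric
#'   position along a -> b), vectorized over rows of `v`.
#' @export
shapeMembership <- function(v, a, b, shape, lateralSize = NULL) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 <= 0) stop("degenerate edge: a == b")
  r <- if (identical(shape$unit, "voxel")) {
    if (is.null(lateralSize))
      stop("voxel-unit radius needs lateralSize")
    shape$radius * lateralSize
  } else shape$radius
  dv <- sweep(v, 2L, a)
  t <- as.vector(dv %*% ab) / len2
  proj <- outer(t, ab)
  d2 <- rowSums((dv - proj)^2)
  rmax <- if (shape$kind == "cylinder") rep(r, length(t))
          else r * (1 - abs(2 * t - 1))
  inside <- t >= 0 & t <= 1 & d2 <= rmax^2
  list(inside = inside, t = t)
}

# voxel-center coordinates for an index bounding box, z-fastest ordering
.bbox_grid <- function(lo, hi, spacing) {
  xi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; zi <- lo[3L]:hi[3L]
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  list(
    ix = rep(xi, each = nz * ny),
    iy = rep(rep(yi, each = nz), times = nx),
    iz = rep(zi, times = ny * nx),
    px = rep(xi, each = nz * ny) * spacing[1L],
    py = rep(rep(yi, each = nz), times = nx) * spacing[2L],
    pz = rep(zi, times = ny * nx) * spacing[3L]
  )
}

.clamp_bbox <- function(pmin_um, pmax_um, spacing, dims) {
  lo <- pmax(floor(pmin_um / spacing), 0)
  hi <- pmin(ceiling(pmax_um / spacing), dims - 1L)
  if (any(lo > hi)) NULL else list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Compute the interaction profile of a graph edge
#'
#' Every voxel center inside the integration shape around the edge is
#' projected onto the edge, assigned to one of `nBins` equal-length bins
#' by its parametric position (`min(floor(t * nBins), nBins - 1)`), and
#' the per-bin, per-channel arithmetic mean intensity forms the profile.
#' Empty bins get mean 0 with a recorded voxel count of 0 (optionally
#' filled by linear interpolation). Per channel, the profile is min-max
#' normalized to [0, 1]; a constant profile normalizes to all 0.
#'
#' The profile of edge (b, a) is the exact bin-reversal of the profile of
#' (a, b): membership and binning are computed in a canonical edge
#' orientation and flipped on output.
#'
#' @param volume a [MultiChannelVolume-class] (apply channel thresholds
#'   with [applyChannelConfig()] beforehand if wanted).
#' @param graph a [CellGraph-class].
#' @param edge integer(2) node ids; must be an edge of `graph`.
#' @param shape a [shapeSpec()]; default cylinder of radius 25 voxels.
#' @param channels channel names to profile (default: all).
#' @param nBins number of bins (>= 2); default one bin per lateral voxel
#'   of edge length, `max(2, round(length / sx))`.
#' @param fillEmptyBins if TRUE, empty-bin means are filled by linear
#'   interpolation between neighboring non-empty bins (never silently:
#'   `nVoxels` stays 0 there).
#' @return an [InteractionProfile-class].
#' @export
computeInteractionProfile <- function(volume, graph, edge,
                                      shape = shapeSpec("cylinder", 25, "voxel"),
                                      channels = NULL, nBins = NULL,
                                      fillEmptyBins = FALSE) {
  stopifnot(is(volume, "MultiChannelVolume"), is(graph, "CellGraph"))
  edge <- as.integer(edge)
  if (!.graph_has_edge(graph, edge))
    stop("edge ", edge[1L], "-", edge[2L], " is not in the graph")
  if (is.null(channels)) channels <- volume@channelNames
  chIdx <- match(channels, volume@channelNames)
  if (anyNA(chIdx)) stop("unknown channel(s): ",
                         paste(channels[is.na(chIdx)], collapse = ", "))
  sp <- volume@spacing
  d <- dim(volume@intensities)
  dims <- c(d[4L], d[3L], d[2L])  # (nx, ny, nz)
  pos <- nodePositions(graph)
  # canonical orientation (smaller id first) so reversal is exact
  lo_id <- min(edge); hi_id <- max(edge)
  a <- pos[as.character(lo_id), ]
  b <- pos[as.character(hi_id), ]
  len <- sqrt(sum((b - a)^2))
  r <- .shape_radius_um(shape, sp[1L])
  if (is.null(nBins)) nBins <- max(2L, as.integer(round(len / sp[1L])))
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  bb <- .clamp_bbox(pmin(a, b) - r, pmax(a, b) + r, sp, dims)
  if (is.null(bb)) stop("edge shape lies outside the volume")
  g <- .bbox_grid(bb$lo, bb$hi, sp)
  mem <- shapeMembership(cbind(g$px, g$py, g$pz), a, b,
                         shapeSpec(shape$kind, r, "um"))
  sel <- which(mem$inside)
  t <- mem$t[sel]
  bins <- pmin(floor(t * nBins), nBins - 1L)
  nVox <- tabulate(bins + 1L, nBins)
  idxZ <- g$iz[sel] + 1L
  idxY <- g$iy[sel] + 1L
  idxX <- g$ix[sel] + 1L
  meanI <- matrix(0, length(chIdx), nBins,
                  dimnames = list(channels, NULL))
  for (i in seq_along(chIdx)) {
    s <- numeric(nBins)
    if (length(sel)) {
      vals <- volume@intensities[cbind(chIdx[i], idxZ, idxY, idxX)]
      agg <- rowsum(vals, bins)
      s[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    }
    m <- numeric(nBins)
    m[nVox > 0] <- s[nVox > 0] / nVox[nVox > 0]
    meanI[i, ] <- m
  }
  if (fillEmptyBins && any(nVox == 0) && any(nVox > 0)) {
    filled <- which(nVox > 0)
    for (i in seq_len(nrow(meanI)))
      meanI[i, ] <- stats::approx(filled, meanI[i, filled],
                                  xout = seq_len(nBins), rule = 2)$y
  }
  binPos <- (seq_len(nBins) - 0.5) / nBins * len
  if (edge[1L] != lo_id) {  # requested orientation is reversed
    meanI <- meanI[, nBins:1L, drop = FALSE]
    nVox <- rev(nVox)
  }
  norm <- t(apply(meanI, 1L, function(v) {
    rng <- range(v)
    if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L])
    else rep(0, length(v))
  }))
  dimnames(norm) <- dimnames(meanI)
  new("InteractionProfile",
      edge = edge,
      shape = list(kind = shape$kind, radius = r),
      nBins = nBins, binPositions = binPos,
      meanIntensity = meanI, nVoxels = as.integer(nVox),
      normalizedIntensity = norm, edgeLength = len)
}

#' Compute profiles for many edges
#'
#' @param volume,shape,channels,nBins,fillEmptyBins as in
#'   [computeInteractionProfile()].
#' @param graph a [CellGraph-class].
#' @param edges 2-column matrix of node-id pairs, or `"all"` for every
#'   graph edge.
#' @return named list of [InteractionProfile-class] objects, keyed
#'   `"a-b"`.
#' @export
computeProfiles <- function(volume, graph, edges = "all",
                            shape = shapeSpec("cylinder", 25, "voxel"),
                            channels = NULL, nBins = NULL,
                            fillEmptyBins = FALSE) {
  if (identical(edges, "all"))
    edges <- as.matrix(graph@edges[, c("a", "b")])
  edges <- matrix(as.integer(edges), ncol = 2L)
  out <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges)))
    out[[k]] <- computeInteractionProfile(volume, graph, edges[k, ], shape,
                                          channels, nBins, fillEmptyBins)
  names(out) <- .edge_key(edges[, 1L], edges[, 2L])
  out
}

#' Heatmap / small-multiple matrices from interaction profiles
#'
#' `"perEdge"` returns, for each edge, a channels x bins matrix of
#' normalized intensities (rows = channels, columns = positions along the
#' edge). `"perChannel"` returns, for each channel, an edges x bins
#' matrix with all edges resampled to a common reference length by linear
#' interpolation.
#'
#' @param profiles list of [InteractionProfile-class] objects.
#' @param mode `"perEdge"` or `"perChannel"`.
#' @param referenceLength bin count for `"perChannel"` resampling
#'   (default: the first profile's bin count).
#' @return named list of labeled matrices.
#' @export
profileMatrix <- function(profiles, mode = c("perEdge", "perChannel"),
                          referenceLength = NULL) {
  mode <- match.arg(mode)
  if (!length(profiles)) stop("empty profile list")
  keys <- vapply(profiles, function(p) .edge_key(p@edge[1L], p@edge[2L]), "")
  if (mode == "perEdge") {
    out <- lapply(profiles, function(p) p@normalizedIntensity)
    names(out) <- keys
    return(out)
  }
  chans <- rownames(profiles[[1L]]@normalizedIntensity)
  same <- vapply(profiles, function(p)
    identical(rownames(p@normalizedIntensity), chans), TRUE)
  if (!all(same))
    stop("perChannel mode requires all profiles to share one channel set")
  L <- if (is.null(referenceLength)) profiles[[1L]]@nBins
       else as.integer(referenceLength)
  out <- lapply(chans, function(ch) {
    m <- t(vapply(profiles, function(p)
      resampleProfile(p@normalizedIntensity[ch, ], L), numeric(L)))
    rownames(m) <- keys
    colnames(m) <- seq_len(L)
    m
  })
  names(out) <- chans
  out
}

#' Order channels by profile similarity
#'
#' Sorts a profile's channels ascending by mean absolute difference
#' (profile distance at p = 1 on normalized intensities) to a reference
#' channel, so similar channels end up adjacent in heatmap displays. The
#' default reference is the channel with the largest raw profile sum.
#' Ties break by channel name.
#'
#' @param profile an [InteractionProfile-class].
#' @param referenceChannel optional channel name.
#' @return character vector: the channel names in similarity order
#'   (reference first).
#' @export
orderChannelsBySimilarity <- function(profile, referenceChannel = NULL) {
  chans <- rownames(profile@normalizedIntensity)
  if (is.null(referenceChannel)) {
    tot <- rowSums(profile@meanIntensity)
    referenceChannel <- chans[order(-tot, chans)][1L]
  } else if (!referenceChannel %in% chans)
    stop("unknown reference channel: ", referenceChannel)
  ref <- profile@normalizedIntensity[referenceChannel, ]
  d <- vapply(chans, function(ch)
    profileDistance(profile@normalizedIntensity[ch, ], ref, p = 1), 0)
  chans[order(d, chans)]
}
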