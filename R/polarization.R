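## Cell-centric polarization: voxels in a spherical shell around a cell
## are projected orthogonally onto a viewing plane and binned into
## clock-face sectors (sector 0 starts at "12 o'clock" = north, running
## clockwise when viewed along -planeNormal).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector where a direction is required")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# default "12 o'clock": screen-up under the y-down image convention,
# i.e. the projection of -y into the viewing plane (fallback -z, then -x)
.default_north <- function(u) {
  for (cand in list(c(0, -1, 0), c(0, 0, -1), c(-1, 0, 0))) {
    q <- cand - sum(cand * u) * u
    if (sum(q^2) > 1e-12) return(.unit(q))
  }
  stop("could not derive a north direction")  # unreachable
}

.view_frame <- function(planeNormal, north = NULL) {
  u <- .unit(as.numeric(planeNormal))
  nr <- if (is.null(north)) .default_north(u)
        else {
          q <- as.numeric(north)
          q <- q - sum(q * u) * u   # force into the plane
          .unit(q)
        }
  list(u = u, north = nr, east = .cross3(nr, u))
}

#' Compute a cell's polarization profile
#'
#' Every voxel center v with `innerRadius < |v - N| <= radius` (physical
#' units, N = the cell center) is projected orthogonally into the viewing
#' plane; its clock angle `theta = atan2(<q, east>, <q, north>)` (mapped
#' to [0, 360), clockwise when viewed along `-planeNormal`) assigns it to
#' sector `floor(theta / (360 / nSectors))`. Voxels whose in-plane
#' component is numerically zero (|q| < 1e-9 um) are excluded. Per sector
#' and channel, intensities are aggregated by mean (default, robust to
#' sector-to-sector voxel-count differences) or sum (conserves total
#' in-shell intensity); `normalized` divides each channel by its sector
#' maximum.
#'
#' @param volume a [MultiChannelVolume-class].
#' @param center cell center in voxel coordinates, numeric(3) `(x,y,z)`;
#'   must lie inside the volume.
#' @param radius shell outer radius.
#' @param planeNormal viewing-plane normal (default `c(0,0,1)`: the
#'   native xy section plane).
#' @param north in-plane "12 o'clock" direction; default is the
#'   projection of `-y` (screen-up for y-down image coordinates).
#' @param channels channel names (default: all).
#' @param innerRadius exclude the core `|v - N| <= innerRadius`
#'   (micrometers; e.g. to mask the nucleus). Default 0.
#' @param aggregator `"mean"` or `"sum"`.
#' @param nSectors number of angular sectors (default 12, 30 deg each).
#' @param radiusUnit `"um"` (default) or `"voxel"` (converted with the
#'   lateral voxel size).
#' @param nodeId optional node id recorded in the result.
#' @return a [PolarizationProfile-class].
#' @export
computePolarization <- function(volume, center, radius,
                                planeNormal = c(0, 0, 1), north = NULL,
                                channels = NULL, innerRadius = 0,
                                aggregator = c("mean", "sum"),
                                nSectors = 12L,
                                radiusUnit = c("um", "voxel"),
                                nodeId = NA_integer_) {
  stopifnot(is(volume, "MultiChannelVolume"))
  aggregator <- match.arg(aggregator)
  radiusUnit <- match.arg(radiusUnit)
  sp <- volume@spacing
  d <- dim(volume@intensities)
  dims <- c(d[4L], d[3L], d[2L])
  center <- as.numeric(center)
  if (any(center < 0) || any(center >= dims))
    stop("cell center lies outside the volume")
  if (radiusUnit == "voxel") radius <- radius * sp[1L]
  if (radius <= innerRadius || innerRadius < 0)
    stop("need radius > innerRadius >= 0")
  nSectors <- as.integer(nSectors)
  if (is.null(channels)) channels <- volume@channelNames
  chIdx <- match(channels, volume@channelNames)
  if (anyNA(chIdx)) stop("unknown channel(s): ",
                         paste(channels[is.na(chIdx)], collapse = ", "))
  fr <- .view_frame(planeNormal, north)
  N <- center * sp
  bb <- .clamp_bbox(N - radius, N + radius, sp, dims)
  if (is.null(bb)) stop("empty neighborhood: no voxel within radius")
  g <- .bbox_grid(bb$lo, bb$hi, sp)
  dx <- g$px - N[1L]; dy <- g$py - N[2L]; dz <- g$pz - N[3L]
  d2 <- dx^2 + dy^2 + dz^2
  along <- dx * fr$u[1L] + dy * fr$u[2L] + dz * fr$u[3L]
  qx <- dx - along * fr$u[1L]
  qy <- dy - along * fr$u[2L]
  qz <- dz - along * fr$u[3L]
  q2 <- qx^2 + qy^2 + qz^2
  incl <- d2 > innerRadius^2 & d2 <= radius^2 & q2 >= 1e-18
  sel <- which(incl)
  if (!length(sel))
    stop("empty neighborhood: no voxel within radius ", radius, " um")
  theta <- atan2(qx[sel] * fr$east[1L] + qy[sel] * fr$east[2L] + qz[sel] * fr$east[3L],
                 qx[sel] * fr$north[1L] + qy[sel] * fr$north[2L] + qz[sel] * fr$north[3L])
  deg <- (theta * 180 / pi) %% 360
  sector <- pmin(floor(deg / (360 / nSectors)), nSectors - 1L)
  counts <- tabulate(sector + 1L, nSectors)
  idxZ <- g$iz[sel] + 1L; idxY <- g$iy[sel] + 1L; idxX <- g$ix[sel] + 1L
  val <- matrix(0, length(chIdx), nSectors,
                dimnames = list(channels, NULL))
  for (i in seq_along(chIdx)) {
    s <- numeric(nSectors)
    vals <- volume@intensities[cbind(chIdx[i], idxZ, idxY, idxX)]
    agg <- rowsum(vals, sector)
    s[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    if (aggregator == "mean") {
      m <- numeric(nSectors)
      m[counts > 0] <- s[counts > 0] / counts[counts > 0]
      val[i, ] <- m
    } else val[i, ] <- s
  }
  norm <- t(apply(val, 1L, function(v) {
    mx <- max(v)
    if (mx > 0) v / mx else rep(0, length(v))
  }))
  dimnames(norm) <- dimnames(val)
  new("PolarizationProfile",
      nodeId = as.integer(nodeId), center = center,
      radius = radius, innerRadius = innerRadius,
      planeNormal = fr$u, north = fr$north,
      nSectors = nSectors, aggregator = aggregator,
      sectorValue = val, sectorCount = as.integer(counts),
      normalized = norm)
}

#' Recompute a polarization profile for a new viewing plane
#'
#' Full recomputation under the new frame (no sector assignments are
#' cached across frames); everything else (cell, radii, channels,
#' aggregator) is taken from the existing profile.
#'
#' @param volume the [MultiChannelVolume-class] the profile was computed
#'   from.
#' @param profile a [PolarizationProfile-class].
#' @param planeNormal new viewing-plane normal.
#' @param north new in-plane north (default: derived as in
#'   [computePolarization()]).
#' @return a new [PolarizationProfile-class].
#' @export
recomputeForView <- function(volume, profile, planeNormal, north = NULL) {
  computePolarization(volume, profile@center, profile@radius,
                      planeNormal = planeNormal, north = north,
                      channels = rownames(profile@sectorValue),
                      innerRadius = profile@innerRadius,
                      aggregator = profile@aggregator,
                      nSectors = profile@nSectors,
                      nodeId = profile@nodeId)
}

#' Polarization profiles for graph nodes
#'
#' @param volume a [MultiChannelVolume-class].
#' @param graph a [CellGraph-class].
#' @param nodes integer node ids, or `"all"`.
#' @param ... passed to [computePolarization()].
#' @return named list of [PolarizationProfile-class], keyed by node id.
#' @export
polarizeNodes <- function(volume, graph, nodes = "all", ...) {
  ids <- if (identical(nodes, "all")) graph@centers$id else as.integer(nodes)
  if (!all(ids %in% graph@centers$id))
    stop("unknown node id(s): ",
         paste(setdiff(ids, graph@centers$id), collapse = ", "))
  out <- lapply(ids, function(id) {
    ctr <- unlist(graph@centers[match(id, graph@centers$id), c("x", "y", "z")])
    computePolarization(volume, ctr, nodeId = id, ...)
  })
  names(out) <- as.character(ids)
  out
}

#' Unrolled clock-face heatmap matrices
#'
#' Conceptually unrolls each cell's sector circle into a straight line:
#' one channels x nSectors matrix of normalized sector values per cell,
#' column j = sector j (clock position 12 plus j * 30 degrees clockwise
#' for the default 12 sectors).
#'
#' @param profiles list of [PolarizationProfile-class] sharing one
#'   sector count.
#' @param channels channel names (default: first profile's channels);
#'   must be present in every profile.
#' @return named list of matrices, keyed by node id.
#' @export
unrollHeatmap <- function(profiles, channels = NULL) {
  if (!length(profiles)) stop("empty profile list")
  ns <- vapply(profiles, function(p) p@nSectors, 0L)
  if (length(unique(ns)) != 1L) stop("profiles must share nSectors")
  if (is.null(channels)) channels <- rownames(profiles[[1L]]@normalized)
  out <- lapply(profiles, function(p) {
    missing <- setdiff(channels, rownames(p@normalized))
    if (length(missing))
      stop("channel(s) missing from a profile: ",
           paste(missing, collapse = ", "))
    m <- p@normalized[channels, , drop = FALSE]
    colnames(m) <- seq_len(ncol(m)) - 1L
    m
  })
  names(out) <- vapply(profiles, function(p) as.character(p@nodeId), "")
  out
}

#' Ring data for a radial (clock-face) polarization chart
#'
#' Pure plotting data: one ring per channel (inner to outer follows the
#' given channel order), each ring holding the 12 (or nSectors) segment
#' widths proportional to the normalized sector values, plus segment
#' start/end angles in degrees clockwise from 12 o'clock.
#'
#' @param profile a [PolarizationProfile-class].
#' @param channels ordered channel names (radial charts read best with
#'   few channels, about 1-4).
#' @return list with `nodeId`, `nSectors`, and `rings`: per channel a
#'   list of `channel`, `widths` (normalized, in [0,1]), `thetaStart`,
#'   `thetaEnd`.
#' @export
radialChartData <- function(profile, channels) {
  if (!length(channels)) stop("empty channel list")
  missing <- setdiff(channels, rownames(profile@normalized))
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  k <- profile@nSectors
  step <- 360 / k
  rings <- lapply(channels, function(ch) list(
    channel = ch,
    widths = as.numeric(profile@normalized[ch, ]),
    thetaStart = (seq_len(k) - 1L) * step,
    thetaEnd = seq_len(k) * step
  ))
  list(nodeId = profile@nodeId, nSectors = k, rings = rings)
}
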