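## Synthetic multi-channel volumes with planted ground truth. Marker
## intensities are analytic functions evaluated at voxel centers (no
## rasterization ambiguity), so expectations like blob peak locations and
## planted polarization sectors hold exactly at zero noise.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rejection-sample cell centers (micrometers) with a minimum pairwise
# separation, keeping out of the supplied forbidden balls
.place_centers <- function(nNew, extent, margin, minSep, existing = NULL,
                           forbidden = list(), maxAttempts = 20000L) {
  pts <- existing
  placed <- 0L
  attempts <- 0L
  while (placed < nNew) {
    if (attempts >= maxAttempts)
      stop("could not place ", nNew, " cells after ", maxAttempts,
           " attempts; reduce the cell count or separation")
    attempts <- attempts + 1L
    cand <- margin + stats::runif(3) * (extent - 2 * margin)
    ok <- TRUE
    if (!is.null(pts) && nrow(pts) &&
        min(colSums((t(pts) - cand)^2)) < minSep^2) ok <- FALSE
    if (ok && length(forbidden))
      for (fb in forbidden)
        if (sum((cand - fb$center)^2) < fb$radius^2) { ok <- FALSE; break }
    if (ok) {
      pts <- rbind(pts, cand)
      placed <- placed + 1L
    }
  }
  pts
}

# additive primitives; each evaluates its field over a local bounding box
# and adds it into arr[ch, , , ]. Positions in micrometers, z-fastest grid.
.add_field <- function(arr, ch, spacing, dims, lo_um, hi_um, f) {
  bb <- .clamp_bbox(lo_um, hi_um, spacing, dims)
  if (is.null(bb)) return(arr)
  g <- .bbox_grid(bb$lo, bb$hi, spacing)
  v <- f(g$px, g$py, g$pz)
  zr <- (bb$lo[3L]:bb$hi[3L]) + 1L
  yr <- (bb$lo[2L]:bb$hi[2L]) + 1L
  xr <- (bb$lo[1L]:bb$hi[1L]) + 1L
  arr[ch, zr, yr, xr] <- arr[ch, zr, yr, xr] +
    array(v, c(length(zr), length(yr), length(xr)))
  arr
}

.nuclear_field <- function(center, amplitude, sigma) {
  function(px, py, pz) {
    d2 <- (px - center[1L])^2 + (py - center[2L])^2 + (pz - center[3L])^2
    amplitude * exp(-d2 / (2 * sigma^2))
  }
}

.membrane_field <- function(center, amplitude, radius, thickness) {
  function(px, py, pz) {
    d <- sqrt((px - center[1L])^2 + (py - center[2L])^2 + (pz - center[3L])^2)
    amplitude * exp(-(d - radius)^2 / (2 * thickness^2))
  }
}

# intensity inside the bicone between two centers, peaking at the midpoint
.interaction_field <- function(a, b, amplitude, radius) {
  ab <- b - a
  len2 <- sum(ab^2)
  tau <- radius / 2
  function(px, py, pz) {
    t <- ((px - a[1L]) * ab[1L] + (py - a[2L]) * ab[2L] +
          (pz - a[3L]) * ab[3L]) / len2
    d2 <- (px - (a[1L] + t * ab[1L]))^2 + (py - (a[2L] + t * ab[2L]))^2 +
          (pz - (a[3L] + t * ab[3L]))^2
    tri <- pmax(0, 1 - abs(2 * t - 1))   # 0 at the nodes, 1 at the midpoint
    amplitude * tri * exp(-d2 / (2 * tau^2)) * (t >= 0 & t <= 1)
  }
}

# membrane shell modulated by a von Mises angular density in the default
# viewing frame (planeNormal +z, north -y)
.polarized_field <- function(center, amplitude, radius, thickness,
                             thetaDeg, kappa) {
  fr <- .view_frame(c(0, 0, 1))
  th0 <- thetaDeg * pi / 180
  function(px, py, pz) {
    dx <- px - center[1L]; dy <- py - center[2L]; dz <- pz - center[3L]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    along <- dx * fr$u[1L] + dy * fr$u[2L] + dz * fr$u[3L]
    qx <- dx - along * fr$u[1L]; qy <- dy - along * fr$u[2L]
    qz <- dz - along * fr$u[3L]
    theta <- atan2(qx * fr$east[1L] + qy * fr$east[2L] + qz * fr$east[3L],
                   qx * fr$north[1L] + qy * fr$north[2L] + qz * fr$north[3L])
    amplitude * exp(-(d - radius)^2 / (2 * thickness^2)) *
      exp(kappa * (cos(theta - th0) - 1))
  }
}

#' Generate a synthetic multi-channel volume with known ground truth
#'
#' Emulates the structure of a multiplexed immunofluorescence volume:
#' spherical cells placed by seeded rejection sampling with a minimum
#' separation, channels composed of analytic marker primitives (nuclear
#' blobs, membrane shells, interaction signal concentrated in the bicone
#' between two cells, direction-polarized shells), plus additive Gaussian
#' background noise clipped at zero. Deterministic for a fixed seed.
#'
#' The marker plan is a list of primitives, each a list with fields
#' `channel`, `type` (`"nuclear"`, `"membrane"`, `"interaction"`,
#' `"polarized"`) and type-specific parameters:
#' \describe{
#'   \item{nuclear}{`cells` ("all" or ids), `amplitude`, `sigma` (um).}
#'   \item{membrane}{`cells`, `amplitude`, `radius`, `thickness` (um).}
#'   \item{interaction}{`a`, `b` (cell ids), `amplitude`, `radius` (um);
#'     plants a midpoint-peaked signal recorded in the truth.}
#'   \item{polarized}{`node`, `amplitude`, `radius`, `thickness`,
#'     `thetaDeg`, `kappa`; recorded in the truth with its expected
#'     sector `floor(thetaDeg / 30)`.}
#' }
#'
#' @param dims volume dimensions `(nx, ny, nz)` in voxels.
#' @param spacing voxel size `(x, y, z)` in micrometers; the default
#'   mirrors a typical anisotropic acquisition (220 nm lateral).
#' @param nCells number of cells.
#' @param cellRadius nominal cell radius in micrometers (placement margin
#'   and default marker geometry).
#' @param markers marker plan (see Details); `NULL` uses a default plan
#'   of one nuclear, one membrane, one interaction and one polarized
#'   channel.
#' @param background constant background intensity.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed (recorded in the truth).
#' @param minSeparation minimum center-to-center distance (default
#'   `2 * cellRadius`).
#' @param fixedCenters optional data.frame `id, x, y, z` (voxel units) of
#'   pre-placed cells (ids must precede random ones).
#' @param forbidden list of `list(center =, radius =)` balls (um) the
#'   randomly placed cells must avoid.
#' @return list with `volume` ([MultiChannelVolume-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
simulateVolume <- function(dims = c(256, 256, 64),
                           spacing = c(0.22, 0.22, 0.28),
                           nCells = 80, cellRadius = 3,
                           markers = NULL, background = 2, noiseSd = 1,
                           seed = 0, minSeparation = 2 * cellRadius,
                           fixedCenters = NULL, forbidden = list()) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  extent <- (dims - 1L) * spacing
  .with_seed(seed, {
    fixed <- NULL
    if (!is.null(fixedCenters))
      fixed <- sweep(as.matrix(fixedCenters[, c("x", "y", "z")]), 2L,
                     spacing, `*`)
    nRandom <- nCells - NROW(fixed)
    if (nRandom < 0) stop("more fixed centers than nCells")
    pts <- .place_centers(nRandom, extent, margin = cellRadius,
                          minSep = minSeparation, existing = fixed,
                          forbidden = forbidden)
    ids <- seq_len(nCells)
    if (!is.null(fixedCenters)) ids[seq_len(nrow(fixedCenters))] <- fixedCenters$id
    centers <- data.frame(id = as.integer(ids),
                          x = pts[, 1L] / spacing[1L],
                          y = pts[, 2L] / spacing[2L],
                          z = pts[, 3L] / spacing[3L])
    rownames(centers) <- NULL
    posUm <- function(id) pts[match(id, centers$id), ]
    if (is.null(markers)) {
      near <- as.matrix(stats::dist(pts))
      diag(near) <- Inf
      pairB <- which.min(near[1L, ])  # partner of cell 1 for the default plan
      markers <- list(
        list(channel = "NUC", type = "nuclear", cells = "all",
             amplitude = 100, sigma = cellRadius / 2.5),
        list(channel = "MEM", type = "membrane", cells = "all",
             amplitude = 100, radius = cellRadius, thickness = 0.4),
        list(channel = "INT", type = "interaction", a = 1L,
             b = as.integer(centers$id[pairB]), amplitude = 120,
             radius = cellRadius / 2),
        list(channel = "POL", type = "polarized",
             node = as.integer(centers$id[which.max(centers$id)]),
             amplitude = 120, radius = cellRadius, thickness = 0.4,
             thetaDeg = 75, kappa = 4)
      )
    }
    channels <- unique(vapply(markers, `[[`, "", "channel"))
    nc <- length(channels)
    arr <- array(0, c(nc, dims[3L], dims[2L], dims[1L]))
    interactions <- list()
    polarizations <- list()
    for (mk in markers) {
      ch <- match(mk$channel, channels)
      switch(mk$type,
        nuclear = {
          cells <- if (identical(mk$cells, "all")) centers$id else mk$cells
          sigma <- if (is.null(mk$sigma)) cellRadius / 2.5 else mk$sigma
          for (id in cells) {
            ctr <- posUm(id)
            arr <- .add_field(arr, ch, spacing, dims,
                              ctr - 4 * sigma, ctr + 4 * sigma,
                              .nuclear_field(ctr, mk$amplitude, sigma))
          }
        },
        membrane = {
          cells <- if (identical(mk$cells, "all")) centers$id else mk$cells
          rad <- if (is.null(mk$radius)) cellRadius else mk$radius
          thick <- if (is.null(mk$thickness)) 0.4 else mk$thickness
          for (id in cells) {
            ctr <- posUm(id)
            ext <- rad + 4 * thick
            arr <- .add_field(arr, ch, spacing, dims, ctr - ext, ctr + ext,
                              .membrane_field(ctr, mk$amplitude, rad, thick))
          }
        },
        interaction = {
          a <- posUm(mk$a); b <- posUm(mk$b)
          rad <- if (is.null(mk$radius)) cellRadius / 2 else mk$radius
          arr <- .add_field(arr, ch, spacing, dims,
                            pmin(a, b) - 2 * rad, pmax(a, b) + 2 * rad,
                            .interaction_field(a, b, mk$amplitude, rad))
          interactions[[length(interactions) + 1L]] <-
            data.frame(a = min(mk$a, mk$b), b = max(mk$a, mk$b),
                       channels = mk$channel, class = "midpoint-peak")
        },
        polarized = {
          ctr <- posUm(mk$node)
          rad <- if (is.null(mk$radius)) cellRadius else mk$radius
          thick <- if (is.null(mk$thickness)) 0.4 else mk$thickness
          kappa <- if (is.null(mk$kappa)) 4 else mk$kappa
          ext <- rad + 4 * thick
          arr <- .add_field(arr, ch, spacing, dims, ctr - ext, ctr + ext,
                            .polarized_field(ctr, mk$amplitude, rad, thick,
                                             mk$thetaDeg, kappa))
          polarizations[[length(polarizations) + 1L]] <-
            data.frame(node = mk$node, channel = mk$channel,
                       thetaDeg = mk$thetaDeg,
                       expectedSector = floor((mk$thetaDeg %% 360) / 30))
        },
        stop("unknown marker type: ", mk$type)
      )
    }
    arr <- arr + background
    if (noiseSd > 0)
      arr <- arr + stats::rnorm(length(arr), sd = noiseSd)
    arr <- pmax(arr, 0)
    volume <- MultiChannelVolume(arr, spacing, channels)
    truth <- new("SyntheticTruth",
      centers = centers,
      plantedInteractions = if (length(interactions))
        unique(do.call(rbind, interactions)) else
        data.frame(a = integer(), b = integer(), channels = character(),
                   class = character()),
      plantedPolarizations = if (length(polarizations))
        do.call(rbind, polarizations) else
        data.frame(node = integer(), channel = character(),
                   thetaDeg = numeric(), expectedSector = numeric()),
      noise = list(background = background, sd = noiseSd),
      seed = as.integer(seed))
    list(volume = volume, truth = truth)
  })
}

#' Scaled emulation of a multiplexed melanoma case-study volume
#'
#' A fixed scene for end-to-end validation, scaled down from a typical
#' acquisition (8 channels, 256 x 256 x 55 voxels, 20 cells, anisotropic
#' 0.22 x 0.22 x 0.28 um spacing). Channels carry immune-oncology marker
#' names. Planted phenomena, recorded in the truth:
#' \itemize{
#'   \item cells 1-2: PD1/PDL1 signal co-localized between the two cells
#'     (midpoint-peaked bicone signal in both channels);
#'   \item cells 3-4: clearly separated expression, PD1 in cell 3's
#'     center and PDL1 in cell 4's center;
#'   \item cell 5: CD8A polarized toward 75 degrees clockwise from 12
#'     o'clock (expected sector 2).
#' }
#' Filler cells are kept out of the planted pairs' diameter balls, so
#' both planted edges are guaranteed Gabriel edges of the built graph.
#'
#' @param seed integer RNG seed.
#' @return list with `volume` and `truth` as in [simulateVolume()].
#' @export
caseStudyFixture <- function(seed = 0) {
  dims <- c(256L, 256L, 55L)
  spacing <- c(0.22, 0.22, 0.28)
  cellRadius <- 2.2
  fixed_um <- rbind(
    c(18, 28, 7.5), c(24, 28, 7.5),   # co-localized pair 1-2
    c(36, 20, 7.5), c(42, 20, 7.5),   # separated pair 3-4
    c(14, 42, 7.5)                    # polarized CD8 cell 5
  )
  fixedCenters <- data.frame(id = 1:5,
                             x = fixed_um[, 1L] / spacing[1L],
                             y = fixed_um[, 2L] / spacing[2L],
                             z = fixed_um[, 3L] / spacing[3L])
  forbidden <- list(
    list(center = (fixed_um[1L, ] + fixed_um[2L, ]) / 2, radius = 3.5),
    list(center = (fixed_um[3L, ] + fixed_um[4L, ]) / 2, radius = 3.5)
  )
  markers <- list(
    list(channel = "DNA", type = "nuclear", cells = "all",
         amplitude = 120, sigma = 0.9),
    list(channel = "SOX10", type = "nuclear", cells = c(1L, 3L, 6L, 7L, 8L),
         amplitude = 100, sigma = 0.9),
    list(channel = "CD3D", type = "membrane", cells = c(2L, 4L, 5L, 11L, 12L),
         amplitude = 90, radius = cellRadius, thickness = 0.4),
    list(channel = "CD8A", type = "membrane", cells = c(2L, 12L),
         amplitude = 90, radius = cellRadius, thickness = 0.4),
    list(channel = "CD8A", type = "polarized", node = 5L, amplitude = 150,
         radius = cellRadius, thickness = 0.4, thetaDeg = 75, kappa = 4),
    list(channel = "PD1", type = "interaction", a = 1L, b = 2L,
         amplitude = 130, radius = 1.6),
    list(channel = "PD1", type = "nuclear", cells = 3L,
         amplitude = 130, sigma = 1.0),
    list(channel = "PDL1", type = "interaction", a = 1L, b = 2L,
         amplitude = 130, radius = 1.6),
    list(channel = "PDL1", type = "nuclear", cells = 4L,
         amplitude = 130, sigma = 1.0),
    list(channel = "CD163", type = "membrane", cells = c(14L, 15L, 16L),
         amplitude = 80, radius = cellRadius, thickness = 0.4),
    list(channel = "HLAA", type = "membrane", cells = "all",
         amplitude = 60, radius = cellRadius, thickness = 0.4)
  )
  out <- simulateVolume(dims = dims, spacing = spacing, nCells = 20,
                        cellRadius = cellRadius, markers = markers,
                        background = 2, noiseSd = 1, seed = seed,
                        minSeparation = 2 * cellRadius,
                        fixedCenters = fixedCenters, forbidden = forbidden)
  truth <- out$truth
  pi_ <- truth@plantedInteractions
  # collapse the two co-localized channel rows and add the separated pair
  pi_ <- data.frame(a = 1L, b = 2L, channels = "PD1,PDL1",
                    class = "co-localization")
  pi_ <- rbind(pi_, data.frame(a = 3L, b = 4L, channels = "PD1,PDL1",
                               class = "separated-centers"))
  out$truth <- new("SyntheticTruth",
                   centers = truth@centers,
                   plantedInteractions = pi_,
                   plantedPolarizations = truth@plantedPolarizations,
                   noise = truth@noise, seed = truth@seed)
  out
}

#' Planted-direction recovery experiment
#'
#' Repeatedly plants a direction-polarized marker on a synthetic cell
#' (von Mises concentration `kappa`, peak amplitude `snr` times the
#' noise standard deviation) and checks whether the argmax sector of the
#' computed polarization profile contains the planted angle. Each trial
#' draws its direction uniformly over the sectors but keeps a 3-degree
#' margin from sector boundaries: a direction on a boundary splits its
#' angular mass evenly between two sectors, so its "expected sector" is
#' not well defined under voxel discretization. Each trial uses its own
#' derived seed; the whole experiment is deterministic in `seed`.
#'
#' @param nTrials number of independent trials.
#' @param kappa von Mises concentration of the planted marker.
#' @param snr peak marker amplitude divided by the noise standard
#'   deviation; `Inf` for noise-free trials.
#' @param seed integer master seed.
#' @param aggregator sector aggregator, see [computePolarization()].
#' @return list with `rate` (fraction recovered), logical `recovered`,
#'   `thetaDeg`, `expectedSector` and `observedSector` per trial.
#' @export
polarizationRecovery <- function(nTrials = 100, kappa = 4, snr = 3,
                                 seed = 0, aggregator = "mean") {
  dims <- c(44L, 44L, 36L)
  spacing <- c(0.22, 0.22, 0.28)
  amplitude <- 90
  noiseSd <- if (is.finite(snr)) amplitude / snr else 0
  centerVox <- (dims - 1) / 2
  theta <- .with_seed(seed, {
    sector <- sample.int(12L, nTrials, replace = TRUE) - 1L
    sector * 30 + 3 + stats::runif(nTrials) * 24
  })
  expected <- floor(theta / 30)
  observed <- integer(nTrials)
  for (i in seq_len(nTrials)) {
    out <- simulateVolume(
      dims = dims, spacing = spacing, nCells = 1L, cellRadius = 2.5,
      markers = list(list(channel = "POL", type = "polarized", node = 1L,
                          amplitude = amplitude, radius = 2.5,
                          thickness = 0.4, thetaDeg = theta[i],
                          kappa = kappa)),
      background = 2, noiseSd = noiseSd,
      seed = (as.numeric(seed) * 1000 + i) %% 2147483647,
      fixedCenters = data.frame(id = 1L, x = centerVox[1L],
                                y = centerVox[2L], z = centerVox[3L]))
    p <- computePolarization(out$volume, centerVox, radius = 3.4,
                             aggregator = aggregator)
    observed[i] <- which.max(p@sectorValue[1L, ]) - 1L
  }
  recovered <- observed == expected
  list(rate = mean(recovered), recovered = recovered, thetaDeg = theta,
       expectedSector = expected, observedSector = observed)
}
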