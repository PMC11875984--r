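# Independent oracles and small fixture builders shared across tests.
# These deliberately use straightforward, separately-written code paths
# (plain loops / full-grid scans), never the package's internals.

# brute-force Gabriel test: keep {a,b} iff no third point lies strictly
# inside the open ball with diameter ab
oracle_gabriel <- function(positions, edges) {
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    a <- positions[i, ]; b <- positions[j, ]
    m <- (a + b) / 2
    r2 <- sum((b - a)^2) / 4
    ok <- TRUE
    for (c_ in seq_len(nrow(positions))) {
      if (c_ == i || c_ == j) next
      if (sum((positions[c_, ] - m)^2) < r2) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  edges[keep, , drop = FALSE]
}

# naive all-voxel interaction-profile oracle: scans every voxel of the
# volume (no bounding box), projects, tests shape membership, bins
oracle_profile <- function(vol, aUm, bUm, kind, rUm, nBins) {
  arr <- intensities(vol)
  sp <- voxelSpacing(vol)
  d <- dim(arr)
  nc <- d[1L]; nz <- d[2L]; ny <- d[3L]; nx <- d[4L]
  ab <- bUm - aUm
  len2 <- sum(ab^2)
  sums <- matrix(0, nc, nBins)
  cnt <- integer(nBins)
  for (ix in 0:(nx - 1L)) {
    px <- ix * sp[1L]
    for (iy in 0:(ny - 1L)) {
      py <- iy * sp[2L]
      for (iz in 0:(nz - 1L)) {
        pz <- iz * sp[3L]
        t <- ((px - aUm[1L]) * ab[1L] + (py - aUm[2L]) * ab[2L] +
              (pz - aUm[3L]) * ab[3L]) / len2
        if (t < 0 || t > 1) next
        cx <- px - (aUm[1L] + t * ab[1L])
        cy <- py - (aUm[2L] + t * ab[2L])
        cz <- pz - (aUm[3L] + t * ab[3L])
        dd <- sqrt(cx * cx + cy * cy + cz * cz)
        rmax <- if (kind == "cylinder") rUm else rUm * (1 - abs(2 * t - 1))
        if (dd > rmax) next
        b_ <- min(floor(t * nBins), nBins - 1L) + 1L
        cnt[b_] <- cnt[b_] + 1L
        sums[, b_] <- sums[, b_] + arr[, iz + 1L, iy + 1L, ix + 1L]
      }
    }
  }
  means <- sums
  for (b_ in seq_len(nBins))
    means[, b_] <- if (cnt[b_] > 0) sums[, b_] / cnt[b_] else 0
  list(mean = means, n = cnt)
}

# independent sector assignment for polarization checks: full-grid scan,
# angle from explicit 2D coordinates in the (north, east) basis
oracle_sectors <- function(vol, centerVox, radius, innerRadius = 0,
                           planeNormal = c(0, 0, 1), north = c(0, -1, 0),
                           nSectors = 12L) {
  arr <- intensities(vol)
  sp <- voxelSpacing(vol)
  d <- dim(arr)
  u <- planeNormal / sqrt(sum(planeNormal^2))
  nr <- north - sum(north * u) * u
  nr <- nr / sqrt(sum(nr^2))
  ea <- c(nr[2L] * u[3L] - nr[3L] * u[2L],
          nr[3L] * u[1L] - nr[1L] * u[3L],
          nr[1L] * u[2L] - nr[2L] * u[1L])
  N <- centerVox * sp
  sector <- integer(0)
  total <- numeric(dim(arr)[1L])
  count <- 0L
  sectorSums <- matrix(0, d[1L], nSectors)
  sectorCnt <- integer(nSectors)
  for (ix in 0:(d[4L] - 1L)) for (iy in 0:(d[3L] - 1L)) for (iz in 0:(d[2L] - 1L)) {
    v <- c(ix * sp[1L], iy * sp[2L], iz * sp[3L]) - N
    dist2 <- sum(v^2)
    if (dist2 <= innerRadius^2 || dist2 > radius^2) next
    q <- v - sum(v * u) * u
    if (sum(q^2) < 1e-18) next
    deg <- (atan2(sum(q * ea), sum(q * nr)) * 180 / pi) %% 360
    k <- min(floor(deg / (360 / nSectors)), nSectors - 1L) + 1L
    sectorSums[, k] <- sectorSums[, k] + arr[, iz + 1L, iy + 1L, ix + 1L]
    sectorCnt[k] <- sectorCnt[k] + 1L
    total <- total + arr[, iz + 1L, iy + 1L, ix + 1L]
    count <- count + 1L
  }
  list(sums = sectorSums, counts = sectorCnt, total = total, nIncluded = count)
}

# two cells in a small volume with a given channel array builder
make_two_cell_graph <- function(spacing = c(0.5, 0.5, 0.5),
                                a = c(5, 12, 6), b = c(20, 12, 6)) {
  centers <- data.frame(id = c(1L, 2L),
                        x = c(a[1L], b[1L]), y = c(a[2L], b[2L]),
                        z = c(a[3L], b[3L]))
  buildGraph(centers, spacing)
}

random_volume <- function(seed, dims = c(16, 16, 16), nChannels = 2L,
                          spacing = c(0.5, 0.5, 0.5)) {
  set.seed(seed)
  arr <- array(runif(nChannels * prod(dims)) * 100,
               c(nChannels, dims[3L], dims[2L], dims[1L]))
  MultiChannelVolume(arr, spacing, paste0("CH", seq_len(nChannels)))
}
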