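point_source_volume <- function(offsetVox, dims = c(21, 21, 21),
                                center = c(10, 10, 10), value = 10) {
  arr <- array(0, c(1, dims[3], dims[2], dims[1]))
  p <- center + offsetVox
  arr[1, p[3] + 1, p[2] + 1, p[1] + 1] <- value
  MultiChannelVolume(arr, c(1, 1, 1), "A")
}

test_that("point sources land in the sectors the clock convention dictates", {
  ctr <- c(10, 10, 10)
  # source along +north: sector 0
  v1 <- point_source_volume(c(0, 5, 0))
  p1 <- computePolarization(v1, ctr, radius = 8, north = c(0, 1, 0))
  expect_equal(which(p1@sectorValue[1, ] > 0) - 1L, 0L)
  # source at 90 degrees clockwise (+x with north = +y, normal = +z): sector 3
  v2 <- point_source_volume(c(5, 0, 0))
  p2 <- computePolarization(v2, ctr, radius = 8, north = c(0, 1, 0))
  expect_equal(which(p2@sectorValue[1, ] > 0) - 1L, 3L)
  # default frame (north = -y, image convention): +x is counterclockwise
  p3 <- computePolarization(v2, ctr, radius = 8)
  expect_equal(which(p3@sectorValue[1, ] > 0) - 1L, 9L)
})

test_that("sector geometry matches the brute-force oracle and partitions the shell", {
  vol <- random_volume(61, dims = c(24, 24, 20), nChannels = 2L,
                       spacing = c(0.4, 0.4, 0.6))
  ctr <- c(11, 12, 9)
  for (inner in c(0, 1.2)) {
    p <- computePolarization(vol, ctr, radius = 4, innerRadius = inner,
                             aggregator = "sum")
    o <- oracle_sectors(vol, ctr, radius = 4, innerRadius = inner)
    expect_equal(unname(p@sectorValue), o$sums, tolerance = 1e-12)
    expect_identical(p@sectorCount, o$counts)
    # partition: every included voxel maps to exactly one sector
    expect_equal(sum(p@sectorCount), o$nIncluded)
    # conservation under sum aggregation
    expect_equal(unname(rowSums(p@sectorValue)), o$total, tolerance = 1e-12)
  }
})

test_that("mean aggregation is the per-sector average and normalization peaks at 1", {
  vol <- random_volume(62, dims = c(20, 20, 16))
  ctr <- c(9, 9, 8)
  pm <- computePolarization(vol, ctr, radius = 3.5, aggregator = "mean")
  ps <- computePolarization(vol, ctr, radius = 3.5, aggregator = "sum")
  nz <- ps@sectorCount > 0
  expect_equal(pm@sectorValue[, nz],
               sweep(ps@sectorValue[, nz], 2, ps@sectorCount[nz], `/`))
  expect_equal(unname(apply(pm@normalized, 1, max)), rep(1, 2))
  # an all-zero channel normalizes to all zero
  arr <- intensities(vol); arr[2, , , ] <- 0
  vz <- MultiChannelVolume(arr, voxelSpacing(vol), channelNames(vol))
  pz <- computePolarization(vz, ctr, radius = 3.5)
  expect_true(all(pz@normalized[2, ] == 0))
})

test_that("a spherically symmetric shell gives near-equal sector means", {
  # constant intensity: discretization is the only source of asymmetry
  arr <- array(1, c(1, 41, 41, 41))
  vol <- MultiChannelVolume(arr, c(1, 1, 1), "A")
  p <- computePolarization(vol, c(20, 20, 20), radius = 12)
  expect_lt(diff(range(p@sectorValue)) / mean(p@sectorValue), 0.05)
})

test_that("rotating the frame by 30 degrees shifts point-source sectors by one", {
  ctr <- c(10, 10, 10)
  u <- c(0, 0, 1)
  north <- c(0, 1, 0); east <- c(1, 0, 0)
  offs <- list(c(4, 2, 0), c(-3, 3, 1), c(1, -5, -2), c(5, -1, 2))
  th <- 30 * pi / 180
  north2 <- cos(th) * north - sin(th) * east   # rotated against the clock
  for (off in offs) {
    v <- point_source_volume(off)
    p1 <- computePolarization(v, ctr, radius = 8, north = north)
    p2 <- computePolarization(v, ctr, radius = 8, north = north2)
    s1 <- which(p1@sectorValue[1, ] > 0) - 1L
    s2 <- which(p2@sectorValue[1, ] > 0) - 1L
    expect_equal(s2, (s1 + 1L) %% 12L)
  }
})

test_that("flipping the viewing direction reverses the sector order", {
  ctr <- c(10, 10, 10)
  for (off in list(c(4, 2, 0), c(-2, 4, 1), c(-4, -3, 0))) {
    v <- point_source_volume(off)
    p1 <- computePolarization(v, ctr, radius = 8, north = c(0, 1, 0))
    p2 <- computePolarization(v, ctr, radius = 8, north = c(0, 1, 0),
                              planeNormal = c(0, 0, -1))
    s1 <- which(p1@sectorValue[1, ] > 0) - 1L
    s2 <- which(p2@sectorValue[1, ] > 0) - 1L
    expect_equal(s2, 11L - s1)   # theta -> 360 - theta off sector boundaries
  }
})

test_that("view recomputation is a full, cache-free recompute", {
  vol <- random_volume(63, dims = c(20, 20, 16))
  ctr <- c(9, 9, 8)
  p <- computePolarization(vol, ctr, radius = 3.5, nodeId = 7L)
  same <- recomputeForView(vol, p, planeNormal = p@planeNormal, north = p@north)
  expect_equal(same@sectorValue, p@sectorValue)
  expect_identical(same@nodeId, 7L)
  tilted <- recomputeForView(vol, p, planeNormal = c(0, 1, 0))
  expect_false(isTRUE(all.equal(tilted@sectorValue, p@sectorValue)))
  expect_equal(tilted@planeNormal, c(0, 1, 0))
})

test_that("polarization validates geometry and reports empty neighborhoods", {
  vol <- random_volume(64, dims = c(12, 12, 10))
  expect_error(computePolarization(vol, c(20, 5, 5), 3), "outside")
  expect_error(computePolarization(vol, c(5, 5, 5), 3, innerRadius = 4),
               "radius > innerRadius")
  expect_error(computePolarization(vol, c(5, 5, 5), 0.05), "empty neighborhood")
  # radius in voxels converts via the lateral voxel size
  pv <- computePolarization(vol, c(5, 5, 5), 4, radiusUnit = "voxel")
  expect_equal(pv@radius, 4 * voxelSpacing(vol)[1])
})

test_that("unrolled heatmaps and radial charts mirror the normalized sectors", {
  vol <- random_volume(65, dims = c(20, 20, 16), nChannels = 3L)
  g <- buildGraph(data.frame(id = c(1L, 4L), x = c(6, 13), y = c(9, 9),
                             z = c(8, 8)), c(0.5, 0.5, 0.5))
  profs <- polarizeNodes(vol, g, "all", radius = 2.5)
  hm <- unrollHeatmap(profs)
  expect_identical(names(hm), c("1", "4"))
  expect_identical(dim(hm[["1"]]), c(3L, 12L))
  expect_equal(unname(hm[["4"]]), unname(profs[["4"]]@normalized))
  rc <- radialChartData(profs[["1"]], c("CH2", "CH1"))
  expect_length(rc$rings, 2L)
  expect_identical(rc$rings[[1]]$channel, "CH2")
  expect_equal(rc$rings[[2]]$widths, unname(profs[["1"]]@normalized["CH1", ]))
  expect_true(all(rc$rings[[1]]$widths >= 0 & rc$rings[[1]]$widths <= 1))
  expect_error(radialChartData(profs[["1"]], character()), "empty")
  expect_error(unrollHeatmap(profs, channels = "NOPE"), "missing")
  expect_error(polarizeNodes(vol, g, 9L, radius = 2.5), "unknown node")
})
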