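test_that("shape membership follows the projection formulas", {
  a <- c(0, 0, 0); b <- c(10, 0, 0)
  cyl <- shapeSpec("cylinder", 4)
  bic <- shapeSpec("bicone", 4)
  # midpoint, d = 2: inside both (bicone allows the full 4 at t = 0.5)
  m <- shapeMembership(c(5, 2, 0), a, b, cyl)
  expect_true(m$inside); expect_equal(m$t, 0.5)
  expect_true(shapeMembership(c(5, 2, 0), a, b, bic)$inside)
  # near the apex the bicone has shrunk below d = 2, the cylinder has not
  expect_true(shapeMembership(c(1, 2, 0), a, b, cyl)$inside)
  mb <- shapeMembership(c(1, 2, 0), a, b, bic)
  expect_false(mb$inside); expect_equal(mb$t, 0.1)
  # beyond the slab: outside both
  expect_false(shapeMembership(c(-1, 0, 0), a, b, cyl)$inside)
  expect_false(shapeMembership(c(-1, 0, 0), a, b, bic)$inside)
  # voxel-unit radii convert by the lateral voxel size
  rv <- shapeSpec("cylinder", 8, "voxel")
  expect_true(shapeMembership(c(5, 1.5, 0), a, b, rv, lateralSize = 0.22)$inside)
  expect_false(shapeMembership(c(5, 2.0, 0), a, b, rv, lateralSize = 0.22)$inside)
  expect_error(shapeMembership(c(5, 2, 0), a, b, rv), "lateralSize")
  expect_error(shapeSpec("cylinder", 0), "positive")
})

test_that("constant volumes give constant bin means and all-zero normalization", {
  g <- make_two_cell_graph()
  arr <- array(5, c(2, 12, 24, 26))
  vol <- MultiChannelVolume(arr, c(0.5, 0.5, 0.5), c("A", "B"))
  for (kind in c("cylinder", "bicone")) {
    p <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec(kind, 2),
                                   nBins = 12)
    expect_equal(unname(p@meanIntensity[, p@nVoxels > 0]),
                 matrix(5, 2, sum(p@nVoxels > 0)))
    expect_true(all(p@normalizedIntensity == 0))
  }
})

test_that("a single bright voxel is diluted by the arithmetic bin mean", {
  g <- make_two_cell_graph()
  arr <- array(0, c(1, 12, 24, 26))
  arr[1, 7, 13, 11] <- 10   # voxel (x=10, y=12, z=6): on the edge axis
  vol <- MultiChannelVolume(arr, c(0.5, 0.5, 0.5), "A")
  p <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec("cylinder", 1),
                                 nBins = 5)
  hot <- which(p@meanIntensity[1, ] > 0)
  expect_length(hot, 1L)
  expect_equal(unname(p@meanIntensity[1, hot]), 10 / p@nVoxels[hot])
  # normalization: max bin is 1, the rest 0
  expect_equal(max(p@normalizedIntensity), 1)
  expect_equal(sum(p@normalizedIntensity > 0), 1L)
})

test_that("profiles equal the naive all-voxel oracle on random volumes", {
  for (seed in c(5, 6)) {
    vol <- random_volume(seed)
    g <- make_two_cell_graph(a = c(3, 8, 4), b = c(13, 9, 10))
    pos <- nodePositions(g)
    for (kind in c("cylinder", "bicone")) {
      p <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec(kind, 2),
                                     nBins = 8)
      o <- oracle_profile(vol, pos["1", ], pos["2", ], kind, 2, 8)
      expect_equal(unname(p@meanIntensity), o$mean, tolerance = 1e-12)
      expect_identical(p@nVoxels, o$n)
    }
  }
})

test_that("bicone voxels nest inside cylinder voxels and radius growth is monotone", {
  vol <- random_volume(7)
  g <- make_two_cell_graph(a = c(2, 3, 2), b = c(14, 12, 12))
  nv <- function(kind, r) computeInteractionProfile(
    vol, g, c(1, 2), shapeSpec(kind, r), nBins = 10)@nVoxels
  for (r in c(1, 2, 3))
    expect_true(all(nv("bicone", r) <= nv("cylinder", r)))
  expect_true(all(nv("cylinder", 2) >= nv("cylinder", 1)))
  expect_true(all(nv("bicone", 3) >= nv("bicone", 2)))
})

test_that("edge reversal returns the exact bin-reversed profile", {
  vol <- random_volume(8)
  g <- make_two_cell_graph(a = c(3, 4, 3), b = c(12, 11, 11))
  for (kind in c("cylinder", "bicone")) {
    p <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec(kind, 2.5),
                                   nBins = 9)
    q <- computeInteractionProfile(vol, g, c(2, 1), shapeSpec(kind, 2.5),
                                   nBins = 9)
    expect_identical(unname(q@meanIntensity[, 9:1]), unname(p@meanIntensity))
    expect_identical(rev(q@nVoxels), p@nVoxels)
  }
})

test_that("empty bins report zero voxels and can be interpolated on request", {
  g <- make_two_cell_graph(a = c(4, 12, 6), b = c(21, 12, 6))
  arr <- array(1, c(1, 12, 24, 26))
  vol <- MultiChannelVolume(arr, c(0.5, 0.5, 0.5), "A")
  # very fine binning near the bicone apexes leaves empty bins
  p <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec("bicone", 0.6),
                                 nBins = 40)
  expect_true(any(p@nVoxels == 0))
  expect_true(all(p@meanIntensity[1, p@nVoxels == 0] == 0))
  pf <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec("bicone", 0.6),
                                  nBins = 40, fillEmptyBins = TRUE)
  expect_identical(pf@nVoxels, p@nVoxels)  # counts stay honest
  expect_true(all(pf@meanIntensity[1, ] == 1))  # constant field interpolates to 1
})

test_that("profile matrices have the contracted shapes and ranges", {
  vol <- random_volume(9, nChannels = 3L)
  g <- make_two_cell_graph(a = c(3, 5, 4), b = c(13, 10, 11))
  p20 <- computeInteractionProfile(vol, g, c(1, 2), shapeSpec("cylinder", 2),
                                   nBins = 20)
  p30 <- computeInteractionProfile(vol, g, c(2, 1), shapeSpec("cylinder", 2),
                                   nBins = 30)
  pe <- profileMatrix(list(p20), "perEdge")
  expect_identical(dim(pe[["1-2"]]), c(3L, 20L))
  expect_true(all(pe[["1-2"]] >= 0 & pe[["1-2"]] <= 1))
  pc <- profileMatrix(list(p20, p30), "perChannel", referenceLength = 20)
  expect_length(pc, 3L)
  expect_identical(dim(pc[[1]]), c(2L, 20L))
  expect_error(profileMatrix(list(), "perEdge"), "empty")
})

test_that("channels order by distance to the reference channel", {
  # hand-built 5-bin profiles with known mean-abs differences
  mk <- matrix(c(0, 0.5, 1, 0.5, 0,       # ref (largest raw sum)
                 0, 0.5, 1, 0.5, 0,       # identical: distance 0
                 1, 1, 1, 1, 1,           # mean |diff| = 0.6
                 0, 0, 0.5, 0, 0),        # mean |diff| = 0.3
               4, 5, byrow = TRUE,
               dimnames = list(c("REF", "SAME", "FLAT", "DIM"), NULL))
  raw <- mk * c(10, 5, 2, 1)
  p <- new("InteractionProfile", edge = c(1L, 2L),
           shape = list(kind = "cylinder", radius = 1), nBins = 5L,
           binPositions = (1:5 - 0.5), meanIntensity = raw,
           nVoxels = rep(3L, 5), normalizedIntensity = mk, edgeLength = 5)
  expect_identical(orderChannelsBySimilarity(p),
                   c("REF", "SAME", "DIM", "FLAT"))
  expect_identical(orderChannelsBySimilarity(p, "FLAT")[1], "FLAT")
  expect_error(orderChannelsBySimilarity(p, "NOPE"), "unknown")
})

test_that("profile requests validate edges, channels and bins", {
  vol <- random_volume(10)
  g <- make_two_cell_graph()
  expect_error(computeInteractionProfile(vol, g, c(1, 3)), "not in the graph")
  expect_error(computeInteractionProfile(vol, g, c(1, 2), channels = "X"),
               "unknown channel")
  expect_error(computeInteractionProfile(vol, g, c(1, 2), nBins = 1), "nBins")
})
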