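test_that("small configurations triangulate to the expected edge sets", {
  # tetrahedron: single simplex, all 6 pairs
  tet <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  e <- delaunayEdges(tet)
  expect_equal(nrow(e), 6L)
  expect_equal(unname(e), t(utils::combn(4L, 2L)))
  # two points: the single edge
  expect_equal(unname(delaunayEdges(rbind(c(0, 0, 0), c(1, 2, 3)))),
               matrix(c(1L, 2L), 1))
  # coincident points are rejected with the pair named
  expect_error(delaunayEdges(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
               "coincident")
})

test_that("degenerate point sets fall back to 2D / chain triangulations", {
  # collinear: chained consecutive edges only
  coll <- rbind(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3), c(2, 2, 2))
  e <- delaunayEdges(coll)
  expect_equal(unname(e), rbind(c(1L, 2L), c(2L, 4L), c(3L, 4L)))
  # exactly coplanar square + center: 2D triangulation, no long diagonals
  # between opposite corners once the center is in
  sq <- rbind(c(0, 0, 5), c(2, 0, 5), c(2, 2, 5), c(0, 2, 5), c(1, 1, 5))
  e2 <- delaunayEdges(sq)
  keys <- paste(e2[, 1], e2[, 2])
  expect_true(all(paste(1:4, 5) %in% keys))   # center connects to all corners
  expect_false("1 3" %in% keys)               # opposite corners blocked
  expect_false("2 4" %in% keys)
})

test_that("Gabriel disc criterion keeps and removes the right edges", {
  pos <- rbind(a = c(0, 0, 0), b = c(2, 0, 0), c = c(1, 0.1, 0))
  rownames(pos) <- NULL
  # c lies inside the diameter ball of {a,b}: removed
  expect_equal(nrow(gabrielFilter(pos, rbind(c(1L, 2L)))), 0L)
  # b is far outside the ball of {a,c}: kept
  expect_equal(nrow(gabrielFilter(pos, rbind(c(1L, 3L)))), 1L)
  # boundary contact keeps the edge (strict interior test)
  pos2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))  # |c-m| == |ab|/2 == 1
  expect_equal(nrow(gabrielFilter(pos2, rbind(c(1L, 2L)))), 1L)
})

test_that("built graphs match hand-derived structure", {
  # collinear a,b,c with b between: only the two short edges survive
  centers <- data.frame(id = 1:3, x = c(0, 5, 10), y = 0, z = 0)
  g <- buildGraph(centers, c(1, 1, 1))
  expect_equal(graphEdges(g)[, c("a", "b")],
               data.frame(a = c(1L, 2L), b = c(2L, 3L)))
  # acute triangle: all 3 edges kept (no vertex in any diameter ball)
  tri <- data.frame(id = 1:3, x = c(0, 4, 1.5), y = c(0, 0, 3), z = 1)
  g2 <- buildGraph(tri, c(1, 1, 1))
  expect_equal(nrow(graphEdges(g2)), 3L)
  # determinism: rebuilding from identical input gives the identical edge set
  set.seed(21)
  centers3 <- data.frame(id = 1:30, x = runif(30) * 50, y = runif(30) * 50,
                         z = runif(30) * 10)
  ga <- buildGraph(centers3, c(0.5, 0.5, 1))
  gb <- buildGraph(centers3, c(0.5, 0.5, 1))
  expect_identical(graphEdges(ga), graphEdges(gb))
})

test_that("Gabriel filter equals the brute-force oracle and is a Delaunay subset", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:60, 1)
    pos <- cbind(runif(n) * 40, runif(n) * 40, runif(n) * 12)
    del <- delaunayEdges(pos)
    gab <- gabrielFilter(pos, del)
    expect_identical(gab, oracle_gabriel(pos, del))
    expect_true(all(paste(gab[, 1], gab[, 2]) %in% paste(del[, 1], del[, 2])))
  }
})

test_that("the graph is invariant under rigid motion of all centers", {
  rot_z <- function(th) rbind(c(cos(th), -sin(th), 0),
                              c(sin(th), cos(th), 0),
                              c(0, 0, 1))
  for (seed in 1:5) {
    set.seed(seed + 100)
    pos <- cbind(runif(25) * 30, runif(25) * 30, runif(25) * 8)
    e1 <- gabrielFilter(pos, delaunayEdges(pos))
    moved <- pos %*% rot_z(0.7) + matrix(c(5, -3, 11), 25, 3, byrow = TRUE)
    e2 <- gabrielFilter(moved, delaunayEdges(moved))
    expect_identical(e1, e2)
  }
})

test_that("Delaunay edge union matches an independent scipy triangulation", {
  py <- Sys.which("python")
  skip_if(py == "", "no system python available")
  for (seed in c(7, 42)) {
    set.seed(seed)
    pos <- cbind(runif(40) * 30, runif(40) * 30, runif(40) * 30)
    ptsfile <- withr::local_tempfile(fileext = ".csv")
    outfile <- withr::local_tempfile(fileext = ".txt")
    utils::write.csv(pos, ptsfile, row.names = FALSE)
    code <- paste0(
      "import numpy as np, csv\n",
      "from scipy.spatial import Delaunay\n",
      "pts = np.loadtxt('", ptsfile, "', delimiter=',', skiprows=1)\n",
      "edges = set()\n",
      "for s in Delaunay(pts).simplices:\n",
      "    s = sorted(int(v) for v in s)\n",
      "    for i in range(4):\n",
      "        for j in range(i+1, 4):\n",
      "            edges.add((s[i]+1, s[j]+1))\n",
      "np.savetxt('", outfile, "', sorted(edges), fmt='%d')\n")
    status <- system2(py, "-", input = code)
    skip_if(status != 0, "scipy unavailable")
    ref <- as.matrix(utils::read.table(outfile))
    expect_equal(unname(delaunayEdges(pos)), unname(ref))
  }
})

test_that("node edits recompute the graph and preserve user edge flags", {
  set.seed(31)
  centers <- data.frame(id = 1:8, x = c(0, 10, 3, 8, 1, 9, 5, 2),
                        y = c(0, 0, 7, 6, 12, 11, 3, 9), z = runif(8))
  g <- buildGraph(centers, c(1, 1, 1))
  e0 <- graphEdges(g)
  # adding a node on the midpoint of a Gabriel edge splits it
  ab <- unlist(e0[1, c("a", "b")])
  mid <- colMeans(cellCenters(g)[match(ab, centers$id), c("x", "y", "z")])
  g2 <- editGraph(g, list(list(op = "add_node", id = 99L, pos = mid)))
  e2 <- graphEdges(g2)
  expect_false(any(e2$a == ab[1] & e2$b == ab[2]))
  expect_true(any(e2$a == ab[1] & e2$b == 99L))
  expect_true(any(e2$a == ab[2] & e2$b == 99L))
  # removing and re-adding the identical node restores the original graph
  g3 <- editGraph(g2, list(list(op = "remove_node", id = 99L)))
  expect_identical(graphEdges(g3), e0)
  # a user edge removal survives a later unrelated node addition
  g4 <- editGraph(g, list(list(op = "remove_edge", a = ab[1], b = ab[2])))
  expect_false(any(graphEdges(g4)$a == ab[1] & graphEdges(g4)$b == ab[2]))
  g5 <- editGraph(g4, list(list(op = "add_node", id = 50L,
                                pos = c(6, 9, 0.5))))
  expect_false(any(graphEdges(g5)$a == ab[1] & graphEdges(g5)$b == ab[2]))
  # a user-added edge persists while both endpoints exist
  far <- c(1L, 6L)
  g6 <- editGraph(g, list(list(op = "add_edge", a = far[1], b = far[2])))
  e6 <- graphEdges(g6)
  expect_true(any(e6$a == far[1] & e6$b == far[2] & e6$userAdded))
  g7 <- editGraph(g6, list(list(op = "remove_node", id = far[2])))
  expect_false(any(graphEdges(g7)$b == far[2]))
  # invalid edits fail loudly
  expect_error(editGraph(g, list(list(op = "remove_node", id = 77L))),
               "unknown id")
  expect_error(editGraph(g, list(list(op = "add_node", id = 1L,
                                      pos = c(1, 1, 1)))),
               "already exists")
})

test_that("graph JSON round-trips nodes, edges and user flags", {
  set.seed(41)
  centers <- data.frame(id = c(2L, 5L, 9L, 11L), x = runif(4) * 20,
                        y = runif(4) * 20, z = runif(4) * 5)
  g <- buildGraph(centers, c(0.22, 0.22, 0.28))
  e <- graphEdges(g)
  g <- editGraph(g, list(list(op = "remove_edge", a = e$a[1], b = e$b[1])))
  f <- withr::local_tempfile(fileext = ".json")
  writeGraph(g, f)
  back <- loadGraph(f)
  expect_equal(cellCenters(back), cellCenters(g))
  expect_equal(graphEdges(back), graphEdges(g))
  expect_equal(voxelSpacing(back), voxelSpacing(g))
  # the persisted removal still applies after a recompute on the loaded graph
  back2 <- editGraph(back, list(list(op = "add_node", id = 99L,
                                     pos = c(50, 50, 10))))
  expect_false(any(graphEdges(back2)$a == e$a[1] & graphEdges(back2)$b == e$b[1]))
})
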