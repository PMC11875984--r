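## Cell graph construction: 3D Delaunay triangulation of the labeled cell
## centers, trimmed to the Gabriel graph. All geometry is done in physical
## units (voxel index * spacing) because the imaging data are anisotropic.

.sorted_pairs <- function(e) {
  if (!nrow(e)) return(matrix(integer(), 0L, 2L))
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Delaunay edge set of a 3D point cloud
#'
#' Returns the union of edges over all tetrahedra of the 3D Delaunay
#' triangulation, computed by exhaustive empty-circumsphere testing
#' (exact and deterministic at the <= few hundred cell scale this package
#' targets). Degenerate inputs fall back gracefully: exactly coplanar
#' point sets are triangulated in 2D within their best-fit plane, and
#' collinear sets are chained along their axis; sets of 2 or 3 points use
#' the only sensible graph (the single edge, or the triangle unless
#' collinear).
#'
#' @param positions numeric matrix (n x 3) of point positions in physical
#'   units (micrometers); row names, if present, are node ids.
#' @return 2-column integer matrix of node-id pairs (`a < b`), in
#'   lexicographic order. Ids default to the row index.
#' @export
delaunayEdges <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 points")
  ids <- if (is.null(rownames(positions))) seq_len(n)
         else as.integer(rownames(positions))
  dd <- as.matrix(stats::dist(positions))
  diag(dd) <- Inf
  hit <- which(dd < 1e-12, arr.ind = TRUE)
  if (nrow(hit))
    stop("coincident points: ids ", ids[hit[1L, 1L]], " and ", ids[hit[1L, 2L]])
  ctr <- sweep(positions, 2L, colMeans(positions))
  sv <- svd(ctr, nu = 0L)
  rank3 <- n >= 4L && sv$d[3L] > 1e-9 * max(sv$d[1L], 1e-300)
  rank2 <- n >= 3L && sv$d[2L] > 1e-9 * max(sv$d[1L], 1e-300)
  if (n == 2L) {
    e <- matrix(c(1L, 2L), 1L, 2L)
  } else if (!rank2) {
    # collinear: chain consecutive points along the principal axis
    t <- ctr %*% sv$v[, 1L]
    o <- order(t)
    e <- cbind(o[-n], o[-1L])
  } else if (!rank3) {
    e <- .delaunayEdges2D(ctr %*% sv$v[, 1:2])
    if (nrow(e) == 0L && n == 3L) e <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  } else {
    e <- .delaunayEdges3D(positions)
    if (nrow(e) == 0L)  # numerically flat despite rank test
      e <- .delaunayEdges2D(ctr %*% sv$v[, 1:2])
  }
  out <- .sorted_pairs(e)
  out[] <- ids[out]
  .sorted_pairs(out)
}

#' Gabriel filter of a candidate edge set
#'
#' Keeps edge `{a, b}` iff no third point lies strictly inside the open
#' ball whose diameter is the segment ab (`|c - m| < |a - b| / 2` with m
#' the midpoint). Boundary contact keeps the edge.
#'
#' @param positions numeric matrix (n x 3), physical units; row names are
#'   node ids.
#' @param edges 2-column matrix of node-id pairs to test.
#' @return the kept subset of `edges`, as sorted pairs in lexicographic
#'   order.
#' @export
gabrielFilter <- function(positions, edges) {
  positions <- as.matrix(positions)
  ids <- if (is.null(rownames(positions))) seq_len(nrow(positions))
         else as.integer(rownames(positions))
  edges <- .sorted_pairs(as.matrix(edges))
  if (!nrow(edges)) return(edges)
  ia <- match(edges[, 1L], ids)
  ib <- match(edges[, 2L], ids)
  if (anyNA(ia) || anyNA(ib)) stop("edges reference unknown node ids")
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- positions[ia[k], ]
    b <- positions[ib[k], ]
    m <- (a + b) / 2
    r2 <- sum((b - a)^2) / 4
    d2 <- colSums((t(positions) - m)^2)
    d2[c(ia[k], ib[k])] <- Inf
    keep[k] <- all(d2 >= r2)   # strict interior test removes; ties keep
  }
  edges[keep, , drop = FALSE]
}

.edge_table <- function(gabriel, delaunay, userAdded = NULL) {
  keys <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L]) else character()
  e <- gabriel
  flags <- data.frame(a = as.integer(e[, 1L]), b = as.integer(e[, 2L]),
                      delaunay = keys(e) %in% keys(delaunay),
                      gabriel = TRUE, userAdded = FALSE)
  if (!is.null(userAdded) && nrow(userAdded)) {
    extra <- !(keys(userAdded) %in% keys(e))
    if (any(extra)) {
      ua <- userAdded[extra, , drop = FALSE]
      flags <- rbind(flags, data.frame(
        a = as.integer(ua[, 1L]), b = as.integer(ua[, 2L]),
        delaunay = keys(ua) %in% keys(delaunay),
        gabriel = FALSE, userAdded = TRUE))
    }
    flags$userAdded[keys(as.matrix(flags[, 1:2])) %in% keys(userAdded)] <- TRUE
  }
  flags <- flags[order(flags$a, flags$b), , drop = FALSE]
  rownames(flags) <- NULL
  flags
}

.recompute_edges <- function(centers, spacing, userAdded, userRemoved) {
  pos <- sweep(as.matrix(centers[, c("x", "y", "z")]), 2L, spacing, `*`)
  rownames(pos) <- as.character(centers$id)
  if (nrow(centers) >= 2L) {
    del <- delaunayEdges(pos)
    gab <- gabrielFilter(pos, del)
  } else {
    del <- gab <- matrix(integer(), 0L, 2L)
  }
  # persisted user edits: additions survive while both endpoints exist,
  # removals always survive
  if (nrow(userAdded)) {
    ok <- userAdded[, 1L] %in% centers$id & userAdded[, 2L] %in% centers$id
    userAdded <- userAdded[ok, , drop = FALSE]
  }
  ed <- .edge_table(gab, del, userAdded)
  if (nrow(userRemoved)) {
    drop <- paste(ed$a, ed$b) %in% paste(userRemoved[, 1L], userRemoved[, 2L])
    ed <- ed[!drop, , drop = FALSE]
    rownames(ed) <- NULL
  }
  list(edges = ed, userAdded = userAdded)
}

#' Build the cell interaction graph
#'
#' Computes the 3D Delaunay triangulation of the cell centers (in
#' physical units) and trims it to the Gabriel graph; the result is the
#' set of candidate cell-cell interactions. Deterministic for fixed
#' input.
#'
#' @param centers data.frame `id, x, y, z` in voxel coordinates (as from
#'   [loadCenters()]).
#' @param spacing numeric(3) voxel size `(x, y, z)` in micrometers.
#' @return a [CellGraph-class].
#' @export
buildGraph <- function(centers, spacing = c(1, 1, 1)) {
  centers <- centers[order(centers$id), c("id", "x", "y", "z")]
  rownames(centers) <- NULL
  empty <- matrix(integer(), 0L, 2L)
  rec <- .recompute_edges(centers, spacing, empty, empty)
  new("CellGraph", centers = centers, spacing = as.numeric(spacing),
      edges = rec$edges, userAdded = empty, userRemoved = empty)
}

#' Edit a cell graph with automatic recompute
#'
#' Applies a sequence of edits. Node edits (`add_node`, `remove_node`,
#' `move_node`) trigger a full Delaunay + Gabriel recompute; user edge
#' edits (`add_edge`, `remove_edge`) are persisted as flags and re-applied
#' after every recompute: removals persist indefinitely, additions persist
#' while both endpoints exist.
#'
#' @param graph a [CellGraph-class].
#' @param ops list of operations, each a list with an `op` field:
#'   `list(op="add_node", id=, pos=c(x,y,z))` (voxel coordinates),
#'   `list(op="remove_node", id=)`, `list(op="move_node", id=, pos=)`,
#'   `list(op="add_edge", a=, b=)`, `list(op="remove_edge", a=, b=)`.
#' @return the edited [CellGraph-class] (updated centers included).
#' @export
editGraph <- function(graph, ops) {
  stopifnot(is(graph, "CellGraph"))
  centers <- graph@centers
  userAdded <- graph@userAdded
  userRemoved <- graph@userRemoved
  need_recompute <- FALSE
  pair <- function(o) {
    p <- sort(as.integer(c(o$a, o$b)))
    if (length(p) != 2L || p[1L] == p[2L]) stop("edge edit needs two distinct ids")
    p
  }
  for (o in ops) {
    switch(o$op,
      add_node = {
        id <- as.integer(o$id)
        if (id %in% centers$id) stop("add_node: id ", id, " already exists")
        centers <- rbind(centers, data.frame(id = id, x = o$pos[1L],
                                             y = o$pos[2L], z = o$pos[3L]))
        need_recompute <- TRUE
      },
      remove_node = {
        id <- as.integer(o$id)
        if (!id %in% centers$id) stop("remove_node: unknown id ", id)
        centers <- centers[centers$id != id, , drop = FALSE]
        need_recompute <- TRUE
      },
      move_node = {
        id <- as.integer(o$id)
        i <- match(id, centers$id)
        if (is.na(i)) stop("move_node: unknown id ", id)
        centers[i, c("x", "y", "z")] <- as.list(as.numeric(o$pos))
        need_recompute <- TRUE
      },
      add_edge = {
        p <- pair(o)
        if (!all(p %in% centers$id)) stop("add_edge: unknown node id")
        key <- paste(p[1L], p[2L])
        if (key %in% paste(graph@edges$a, graph@edges$b) && !need_recompute)
          warning("add_edge: edge ", p[1L], "-", p[2L],
                  " already present (no-op)")
        userAdded <- .sorted_pairs(rbind(userAdded, p))
        userRemoved <- userRemoved[
          !(paste(userRemoved[, 1L], userRemoved[, 2L]) == key), ,
          drop = FALSE]
        need_recompute <- TRUE
      },
      remove_edge = {
        p <- pair(o)
        key <- paste(p[1L], p[2L])
        userRemoved <- .sorted_pairs(rbind(userRemoved, p))
        userAdded <- userAdded[
          !(paste(userAdded[, 1L], userAdded[, 2L]) == key), ,
          drop = FALSE]
        need_recompute <- TRUE
      },
      stop("unknown graph edit op: ", o$op)
    )
  }
  centers <- centers[order(centers$id), , drop = FALSE]
  rownames(centers) <- NULL
  rec <- .recompute_edges(centers, graph@spacing, userAdded, userRemoved)
  new("CellGraph", centers = centers, spacing = graph@spacing,
      edges = rec$edges, userAdded = rec$userAdded, userRemoved = userRemoved)
}

.edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))

.graph_has_edge <- function(graph, edge) {
  any(graph@edges$a == min(edge) & graph@edges$b == max(edge))
}

#' Write a cell graph to JSON
#'
#' Schema: `{nodes: [{id, x, y, z}], edges: [{a, b, delaunay, gabriel,
#' user_added}], spacing, coordinate_unit: "micrometer"}`. Node positions
#' are written in micrometers; voxel centers are recovered on load by
#' dividing by the spacing.
#'
#' @param graph a [CellGraph-class].
#' @param path output JSON path.
#' @export
writeGraph <- function(graph, path) {
  pos <- nodePositions(graph)
  nodes <- data.frame(id = graph@centers$id, x = pos[, 1L],
                      y = pos[, 2L], z = pos[, 3L])
  e <- graph@edges
  obj <- list(
    nodes = nodes,
    edges = data.frame(a = e$a, b = e$b, delaunay = e$delaunay,
                       gabriel = e$gabriel, user_added = e$userAdded),
    user_removed = if (nrow(graph@userRemoved))
      data.frame(a = graph@userRemoved[, 1L], b = graph@userRemoved[, 2L])
      else list(),
    spacing = graph@spacing,
    coordinate_unit = "micrometer"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a cell graph from JSON written by [writeGraph()]
#' @param path JSON path.
#' @return a [CellGraph-class].
#' @export
loadGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spacing <- as.numeric(obj$spacing)
  nd <- obj$nodes
  centers <- data.frame(id = as.integer(nd$id),
                        x = nd$x / spacing[1L],
                        y = nd$y / spacing[2L],
                        z = nd$z / spacing[3L])
  e <- obj$edges
  edges <- data.frame(a = as.integer(e$a), b = as.integer(e$b),
                      delaunay = as.logical(e$delaunay),
                      gabriel = as.logical(e$gabriel),
                      userAdded = as.logical(e$user_added))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  ur <- obj$user_removed
  userRemoved <- if (length(ur)) cbind(as.integer(ur$a), as.integer(ur$b))
                 else matrix(integer(), 0L, 2L)
  ua <- edges[edges$userAdded, c("a", "b"), drop = FALSE]
  new("CellGraph", centers = centers, spacing = spacing, edges = edges,
      userAdded = if (nrow(ua)) as.matrix(ua) else matrix(integer(), 0L, 2L),
      userRemoved = userRemoved)
}
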