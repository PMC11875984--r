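#' @rdname MultiChannelVolume-class
#' @param object,x a package object
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname MultiChannelVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname MultiChannelVolume-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname CellGraph-class
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname CellGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname CellGraph-class
#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))

setMethod("intensities", "MultiChannelVolume", function(x) x@intensities)
setMethod("voxelSpacing", "MultiChannelVolume", function(x) x@spacing)
setMethod("channelNames", "MultiChannelVolume", function(x) x@channelNames)

setMethod("voxelSpacing", "CellGraph", function(x) x@spacing)
setMethod("cellCenters", "CellGraph", function(x) x@centers)
setMethod("cellCenters", "SyntheticTruth", function(x) x@centers)

#' @describeIn CellGraph-class current edge table (columns `a`, `b` and
#'   provenance flags), in deterministic lexicographic order.
setMethod("graphEdges", "CellGraph", function(x) x@edges)

#' @describeIn CellGraph-class node positions in micrometers: a matrix
#'   with columns `x`, `y`, `z` and node ids as row names.
setMethod("nodePositions", "CellGraph", function(x) {
  pos <- as.matrix(x@centers[, c("x", "y", "z")])
  pos <- sweep(pos, 2L, x@spacing, `*`)
  rownames(pos) <- as.character(x@centers$id)
  pos
})

setMethod("dim", "MultiChannelVolume", function(x) dim(x@intensities))

setMethod("show", "MultiChannelVolume", function(object) {
  d <- dim(object@intensities)
  cat("MultiChannelVolume:", d[1L], "channel(s),",
      sprintf("%d x %d x %d (x,y,z) voxels\n", d[4L], d[3L], d[2L]))
  cat("  spacing (um):", paste(signif(object@spacing, 4), collapse = " x "),
      "\n  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "CellGraph", function(object) {
  cat("CellGraph:", nrow(object@centers), "nodes,",
      nrow(object@edges), "edges",
      sprintf("(%d user-added, %d user-removed)\n",
              nrow(object@userAdded), nrow(object@userRemoved)))
})

setMethod("show", "InteractionProfile", function(object) {
  cat(sprintf("InteractionProfile: edge %d-%d, %s r=%.3g um, %d bins, %d channel(s)\n",
              object@edge[1L], object@edge[2L], object@shape$kind,
              object@shape$radius, object@nBins,
              nrow(object@meanIntensity)))
  cat(sprintf("  edge length %.3g um, %d voxels in shape\n",
              object@edgeLength, sum(object@nVoxels)))
})

setMethod("show", "PolarizationProfile", function(object) {
  cat(sprintf("PolarizationProfile: node %s, r=%.3g um, %d sectors (%s), %d channel(s)\n",
              ifelse(is.na(object@nodeId), "<free>", object@nodeId),
              object@radius, object@nSectors, object@aggregator,
              nrow(object@sectorValue)))
})

setMethod("show", "RankingResult", function(object) {
  cat(sprintf("RankingResult: reference %d-%d, %d candidate(s), p=%s, metric=%s\n",
              object@referenceEdge[1L], object@referenceEdge[2L],
              nrow(object@entries), format(object@parameters$p),
              object@parameters$metric))
  print(utils::head(object@entries, 5L))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@centers), "cells,",
      nrow(object@plantedInteractions), "planted interaction(s),",
      nrow(object@plantedPolarizations), "planted polarization(s), seed",
      object@seed, "\n")
})
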