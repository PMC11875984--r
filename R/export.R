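## Export / import of analysis results. JSON round-trips are bit-exact
## (full double precision); CSV round-trips are exact to better than
## 1e-12 (17 significant digits).

.num_chr <- function(x) sprintf("%.17g", x)

.profile_frame <- function(p) {
  chans <- rownames(p@meanIntensity)
  nb <- p@nBins
  data.frame(
    edge_id = .edge_key(p@edge[1L], p@edge[2L]),
    channel = rep(chans, each = nb),
    bin_index = rep(seq_len(nb) - 1L, times = length(chans)),
    position_um = rep(p@binPositions, times = length(chans)),
    mean_intensity = as.vector(t(p@meanIntensity)),
    n_voxels = rep(p@nVoxels, times = length(chans)),
    normalized_intensity = as.vector(t(p@normalizedIntensity)),
    shape = p@shape$kind,
    radius_um = p@shape$radius,
    edge_length_um = p@edgeLength
  )
}

.profile_from_frame <- function(df) {
  ids <- as.integer(strsplit(df$edge_id[1L], "-", fixed = TRUE)[[1L]])
  chans <- unique(df$channel)
  nb <- max(df$bin_index) + 1L
  mi <- matrix(0, length(chans), nb, dimnames = list(chans, NULL))
  ni <- mi
  for (ch in chans) {
    sub <- df[df$channel == ch, ]
    sub <- sub[order(sub$bin_index), ]
    mi[ch, ] <- sub$mean_intensity
    ni[ch, ] <- sub$normalized_intensity
  }
  sub1 <- df[df$channel == chans[1L], ]
  sub1 <- sub1[order(sub1$bin_index), ]
  new("InteractionProfile", edge = ids,
      shape = list(kind = df$shape[1L], radius = df$radius_um[1L]),
      nBins = as.integer(nb), binPositions = sub1$position_um,
      meanIntensity = mi, nVoxels = as.integer(sub1$n_voxels),
      normalizedIntensity = ni, edgeLength = df$edge_length_um[1L])
}

.polar_list <- function(p) {
  list(node_id = p@nodeId, center_voxel = p@center, radius = p@radius,
       inner_radius = p@innerRadius, plane_normal = p@planeNormal,
       north = p@north, n_sectors = p@nSectors, aggregator = p@aggregator,
       sector_count = p@sectorCount,
       sectors = apply(p@sectorValue, 1L, identity, simplify = FALSE),
       normalized = apply(p@normalized, 1L, identity, simplify = FALSE))
}

.polar_from_list <- function(o) {
  chans <- names(o$sectors)
  val <- do.call(rbind, o$sectors)
  nrm <- do.call(rbind, o$normalized)
  rownames(val) <- rownames(nrm) <- chans
  new("PolarizationProfile",
      nodeId = as.integer(o$node_id), center = as.numeric(o$center_voxel),
      radius = as.numeric(o$radius), innerRadius = as.numeric(o$inner_radius),
      planeNormal = as.numeric(o$plane_normal), north = as.numeric(o$north),
      nSectors = as.integer(o$n_sectors), aggregator = o$aggregator,
      sectorValue = val, sectorCount = as.integer(o$sector_count),
      normalized = nrm)
}

#' Export analysis results to CSV or JSON
#'
#' Writes an [InteractionProfile-class] (or list of them), a
#' [PolarizationProfile-class] (or list), or a [RankingResult-class] so
#' that [importResults()] reconstructs the numeric content losslessly
#' (bit-exact for JSON, to better than 1e-12 for CSV).
#'
#' Profile CSV columns: `edge_id, channel, bin_index, position_um,
#' mean_intensity, n_voxels, normalized_intensity, shape, radius_um,
#' edge_length_um`. Polarization JSON: `node_id, radius, plane_normal,
#' north, sector_count, sectors[channel][nSectors], normalized[...]`.
#'
#' @param object the result object (or homogeneous list).
#' @param path output path.
#' @param format `"csv"` or `"json"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
exportResults <- function(object, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  items <- if (is.list(object) && !is(object, "RankingResult")) object
           else list(object)
  kind <- if (is(items[[1L]], "InteractionProfile")) "profiles"
          else if (is(items[[1L]], "PolarizationProfile")) "polarizations"
          else if (is(items[[1L]], "RankingResult")) "ranking"
          else stop("unsupported object type for export")
  if (format == "csv") {
    df <- switch(kind,
      profiles = do.call(rbind, lapply(items, .profile_frame)),
      polarizations = do.call(rbind, lapply(items, function(p) {
        chans <- rownames(p@sectorValue)
        k <- p@nSectors
        data.frame(node_id = p@nodeId,
                   channel = rep(chans, each = k),
                   sector = rep(seq_len(k) - 1L, length(chans)),
                   value = as.vector(t(p@sectorValue)),
                   n_voxels = rep(p@sectorCount, length(chans)),
                   normalized = as.vector(t(p@normalized)),
                   radius_um = p@radius, inner_radius_um = p@innerRadius,
                   aggregator = p@aggregator,
                   center_x = p@center[1L], center_y = p@center[2L],
                   center_z = p@center[3L],
                   normal_x = p@planeNormal[1L], normal_y = p@planeNormal[2L],
                   normal_z = p@planeNormal[3L],
                   north_x = p@north[1L], north_y = p@north[2L],
                   north_z = p@north[3L])
      })),
      ranking = {
        r <- items[[1L]]
        e <- r@entries
        data.frame(reference = .edge_key(r@referenceEdge[1L], r@referenceEdge[2L]),
                   edge = .edge_key(e$a, e$b), total = e$total,
                   r@perChannel, check.names = FALSE)
      })
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], .num_chr)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- switch(kind,
      profiles = list(type = "interaction_profiles",
                      profiles = lapply(items, function(p) {
                        list(edge = p@edge, shape = p@shape,
                             n_bins = p@nBins, bin_positions = p@binPositions,
                             edge_length = p@edgeLength,
                             n_voxels = p@nVoxels,
                             mean_intensity = apply(p@meanIntensity, 1L,
                                                    identity, simplify = FALSE),
                             normalized_intensity = apply(p@normalizedIntensity,
                                                          1L, identity,
                                                          simplify = FALSE))
                      })),
      polarizations = list(type = "polarization_profiles",
                           profiles = lapply(items, .polar_list)),
      ranking = {
        r <- items[[1L]]
        list(type = "ranking",
             reference = .edge_key(r@referenceEdge[1L], r@referenceEdge[2L]),
             parameters = r@parameters,
             entries = lapply(seq_len(nrow(r@entries)), function(i) list(
               edge = .edge_key(r@entries$a[i], r@entries$b[i]),
               total = r@entries$total[i],
               per_channel = as.list(r@perChannel[i, ]))))
      })
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Import results written by [exportResults()]
#'
#' @param path CSV or JSON file.
#' @return a named list of profiles, a named list of polarization
#'   profiles, or a [RankingResult-class], matching what was exported.
#' @export
importResults <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
    switch(o$type,
      interaction_profiles = {
        out <- lapply(o$profiles, function(p) {
          chans <- names(p$mean_intensity)
          mi <- do.call(rbind, p$mean_intensity)
          ni <- do.call(rbind, p$normalized_intensity)
          rownames(mi) <- rownames(ni) <- chans
          new("InteractionProfile", edge = as.integer(p$edge),
              shape = list(kind = p$shape$kind, radius = p$shape$radius),
              nBins = as.integer(p$n_bins),
              binPositions = as.numeric(p$bin_positions),
              meanIntensity = mi, nVoxels = as.integer(p$n_voxels),
              normalizedIntensity = ni,
              edgeLength = as.numeric(p$edge_length))
        })
        names(out) <- vapply(out, function(p)
          .edge_key(p@edge[1L], p@edge[2L]), "")
        out
      },
      polarization_profiles = {
        out <- lapply(o$profiles, .polar_from_list)
        names(out) <- vapply(out, function(p) as.character(p@nodeId), "")
        out
      },
      ranking = {
        ref <- as.integer(strsplit(o$reference, "-", fixed = TRUE)[[1L]])
        keys <- vapply(o$entries, `[[`, "", "edge")
        ab <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
        per <- do.call(rbind, lapply(o$entries, function(e)
          unlist(e$per_channel)))
        rownames(per) <- keys
        new("RankingResult", referenceEdge = ref,
            entries = data.frame(a = as.integer(ab[, 1L]),
                                 b = as.integer(ab[, 2L]),
                                 total = vapply(o$entries, `[[`, 0, "total")),
            perChannel = per,
            parameters = lapply(o$parameters, function(x)
              if (is.list(x)) unlist(x) else x))
      },
      stop("unknown result type: ", o$type))
  } else {
    df <- utils::read.csv(path)
    if ("edge_id" %in% names(df)) {
      out <- lapply(split(df, df$edge_id), .profile_from_frame)
      out[unique(df$edge_id)]
    } else if ("sector" %in% names(df)) {
      out <- lapply(split(df, df$node_id), function(sub) {
        chans <- unique(sub$channel)
        k <- max(sub$sector) + 1L
        val <- nrm <- matrix(0, length(chans), k,
                             dimnames = list(chans, NULL))
        for (ch in chans) {
          s <- sub[sub$channel == ch, ]
          s <- s[order(s$sector), ]
          val[ch, ] <- s$value
          nrm[ch, ] <- s$normalized
        }
        s1 <- sub[sub$channel == chans[1L], ]
        s1 <- s1[order(s1$sector), ]
        new("PolarizationProfile", nodeId = as.integer(sub$node_id[1L]),
            center = c(sub$center_x[1L], sub$center_y[1L], sub$center_z[1L]),
            radius = sub$radius_um[1L], innerRadius = sub$inner_radius_um[1L],
            planeNormal = c(sub$normal_x[1L], sub$normal_y[1L], sub$normal_z[1L]),
            north = c(sub$north_x[1L], sub$north_y[1L], sub$north_z[1L]),
            nSectors = as.integer(k), aggregator = sub$aggregator[1L],
            sectorValue = val, sectorCount = as.integer(s1$n_voxels),
            normalized = nrm)
      })
      out[as.character(unique(df$node_id))]
    } else if ("reference" %in% names(df)) {
      ref <- as.integer(strsplit(df$reference[1L], "-", fixed = TRUE)[[1L]])
      ab <- do.call(rbind, strsplit(df$edge, "-", fixed = TRUE))
      chans <- setdiff(names(df), c("reference", "edge", "total"))
      per <- as.matrix(df[chans])
      rownames(per) <- df$edge
      new("RankingResult", referenceEdge = ref,
          entries = data.frame(a = as.integer(ab[, 1L]),
                               b = as.integer(ab[, 2L]), total = df$total),
          perChannel = per,
          parameters = list(p = NA, metric = NA, channels = chans,
                            useNormalized = NA))
    } else stop("unrecognized result CSV schema: ", path)
  }
}
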