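#' Construct a MultiChannelVolume
#'
#' @param intensities 3-D array `(z, y, x)` for a single channel or 4-D
#'   array `(channel, z, y, x)`; all values must be non-negative.
#' @param spacing numeric(3), physical voxel size along `(x, y, z)` in
#'   micrometers.
#' @param channelNames optional character vector of unique channel names;
#'   defaults to `C0 .. C<n-1>`.
#' @return a [MultiChannelVolume-class] object.
#' @export
MultiChannelVolume <- function(intensities, spacing, channelNames = NULL) {
  if (length(dim(intensities)) == 3L)
    dim(intensities) <- c(1L, dim(intensities))
  if (is.null(channelNames))
    channelNames <- paste0("C", seq_len(dim(intensities)[1L]) - 1L)
  new("MultiChannelVolume",
      intensities = intensities,
      spacing = as.numeric(spacing),
      channelNames = as.character(channelNames))
}

.volume_sidecar <- function(path) paste0(path, ".json")

#' Write a volume to multi-page TIFF
#'
#' Pages are written channel-major (all z planes of channel 1, then
#' channel 2, ...). Samples are stored as 32-bit fixed point scaled by the
#' volume maximum; shape, spacing, channel names and the scale factor go
#' into a JSON sidecar (`<path>.json`) so [loadVolume()] can reconstruct
#' the volume. Shape, spacing and channel names round-trip exactly;
#' intensities round-trip to 32-bit storage precision (about 2^-31 of
#' the intensity range).
#'
#' @param volume a [MultiChannelVolume-class].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "MultiChannelVolume"))
  arr <- volume@intensities
  d <- dim(arr)
  mx <- max(arr)
  # power-of-two scale: re-writing a loaded volume reuses the same scale,
  # so the fixed-point quantization is idempotent after the first cycle
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      pages[[k]] <- matrix(arr[ch, z, , ] / scale, d[3L], d[4L])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(
    format = "cellContacts-volume", version = 1L,
    shape = d, spacing = volume@spacing,
    channel_names = volume@channelNames, scale = scale
  )
  jsonlite::write_json(meta, .volume_sidecar(path),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a volume from multi-page TIFF
#'
#' Files written by [writeVolume()] are reconstructed from their JSON
#' sidecar (shape, spacing, channel names, intensity scale). Plain
#' multi-page TIFF files without a sidecar are read page-by-page as
#' channel-major z-stacks; the channel count then comes from `nChannels`
#' and the spacing must be supplied via `spacingOverride`.
#'
#' @param path TIFF file path.
#' @param spacingOverride numeric(3) voxel size `(x, y, z)` in
#'   micrometers, overriding (or supplying, for plain TIFF) the metadata
#'   spacing.
#' @param nChannels number of channels for plain TIFF input (pages =
#'   `nChannels * nz`, channel-major). Default 1.
#' @param channelNames optional channel names for plain TIFF input.
#' @return a [MultiChannelVolume-class].
#' @export
loadVolume <- function(path, spacingOverride = NULL, nChannels = NULL,
                       channelNames = NULL) {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1L]])) > 2L)
    pages <- lapply(pages, function(p) p[, , 1L])
  side <- .volume_sidecar(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    scale <- as.numeric(meta$scale)
    spacing <- if (is.null(spacingOverride)) as.numeric(meta$spacing)
               else as.numeric(spacingOverride)
    channelNames <- as.character(meta$channel_names)
  } else {
    if (is.null(spacingOverride))
      stop("no voxel spacing available for ", path,
           ": plain TIFF carries none, pass spacingOverride")
    nc <- if (is.null(nChannels)) 1L else as.integer(nChannels)
    if (length(pages) %% nc != 0L)
      stop("page count ", length(pages), " is not a multiple of nChannels ", nc)
    d <- c(nc, length(pages) %/% nc, nrow(pages[[1L]]), ncol(pages[[1L]]))
    scale <- 1
    spacing <- as.numeric(spacingOverride)
  }
  if (d[2L] < 2L || d[3L] < 2L || d[4L] < 2L)
    stop("volume must have at least 3 spatial dimensions (z stack of 2D planes)")
  arr <- array(0, d)
  k <- 1L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      arr[ch, z, , ] <- pages[[k]] * scale
      k <- k + 1L
    }
  }
  MultiChannelVolume(arr, spacing, channelNames)
}

#' Load a cell-center table
#'
#' Reads a CSV with columns `id,x,y,z`. Positions are stored in voxel
#' coordinates (0-based, fractional allowed); micrometer input is divided
#' per axis by the voxel spacing.
#'
#' @param path CSV file path.
#' @param coordinateUnit `"voxel"` (default) or `"micrometer"`.
#' @param spacing numeric(3) voxel size, required for micrometer input.
#' @param dims optional volume dimensions `(nx, ny, nz)`; when given,
#'   positions outside `[0, dim)` raise an error listing offending rows.
#' @return data.frame with columns `id`, `x`, `y`, `z` (voxel units).
#' @export
loadCenters <- function(path, coordinateUnit = c("voxel", "micrometer"),
                        spacing = NULL, dims = NULL) {
  coordinateUnit <- match.arg(coordinateUnit)
  df <- utils::read.csv(path)
  req <- c("id", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("centers CSV must have columns id, x, y, z")
  df <- df[req]
  df$id <- as.integer(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate node ids in ", path, ": ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (coordinateUnit == "micrometer") {
    if (is.null(spacing))
      stop("spacing is required to convert micrometer coordinates to voxels")
    df$x <- df$x / spacing[1L]
    df$y <- df$y / spacing[2L]
    df$z <- df$z / spacing[3L]
  }
  if (!is.null(dims)) {
    bad <- df$x < 0 | df$x >= dims[1L] |
           df$y < 0 | df$y >= dims[2L] |
           df$z < 0 | df$z >= dims[3L]
    if (any(bad))
      stop("cell centers outside the volume bounds, rows: ",
           paste(which(bad), collapse = ", "),
           " (ids ", paste(df$id[bad], collapse = ", "), ")")
  }
  df
}

#' Write a cell-center table (voxel coordinates) to CSV
#' @param centers data.frame `id, x, y, z`.
#' @param path output CSV path.
#' @export
writeCenters <- function(centers, path) {
  utils::write.csv(centers[, c("id", "x", "y", "z")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a per-channel configuration (thresholds / value ranges)
#'
#' YAML or JSON with top-level `channels:`, each entry
#' `name: {threshold: t, range: [lo, hi], active: true}`. All fields are
#' optional; threshold defaults to 0 and active to TRUE.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of per-channel settings.
#' @export
loadChannelConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- cfg$channels
  if (is.null(ch)) stop("channel config must contain a 'channels' mapping")
  lapply(ch, function(x) {
    list(threshold = if (is.null(x$threshold)) 0 else as.numeric(x$threshold),
         range = if (is.null(x$range)) NULL else as.numeric(unlist(x$range)),
         active = if (is.null(x$active)) TRUE else isTRUE(x$active))
  })
}

#' Apply per-channel thresholds and value ranges
#'
#' For every configured, active channel: intensities below the threshold
#' are set to 0 (noise suppression), then values are clamped into the
#' channel's value range when one is given. The input volume is left
#' unmodified; the operation is idempotent for a fixed configuration.
#'
#' @param volume a [MultiChannelVolume-class].
#' @param config named list as returned by [loadChannelConfig()], or a
#'   list of the form `list(CH = list(threshold =, range =, active =))`.
#' @return a new [MultiChannelVolume-class].
#' @export
applyChannelConfig <- function(volume, config) {
  stopifnot(is(volume, "MultiChannelVolume"))
  arr <- volume@intensities
  for (nm in names(config)) {
    idx <- match(nm, volume@channelNames)
    if (is.na(idx))
      stop("channel config names unknown channel: ", nm)
    cc <- config[[nm]]
    if (!is.null(cc$active) && !isTRUE(cc$active)) next
    thr <- if (is.null(cc$threshold)) 0 else cc$threshold
    rng <- cc$range
    if (!is.null(rng) && length(rng) == 2L && thr > rng[2L])
      stop("threshold exceeds range maximum for channel ", nm)
    v <- arr[idx, , , ]
    if (thr > 0) v[v < thr] <- 0
    if (!is.null(rng) && length(rng) == 2L)
      v <- pmin(pmax(v, rng[1L]), rng[2L])
    arr[idx, , , ] <- v
  }
  MultiChannelVolume(arr, volume@spacing, volume@channelNames)
}
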