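## Presentation-only renderings of profile and polarization data.

#' Heatmap of an interaction profile (channels x edge position)
#'
#' Rows are channels (ordered by similarity unless `channelOrder` is
#' given), columns are positions along the edge; color encodes the
#' normalized intensity in [0, 1].
#'
#' @param profile an [InteractionProfile-class].
#' @param channelOrder optional character vector of channel names.
#' @param main plot title.
#' @return the channel order used, invisibly.
#' @export
plotProfileHeatmap <- function(profile, channelOrder = NULL, main = NULL) {
  if (is.null(channelOrder))
    channelOrder <- orderChannelsBySimilarity(profile)
  m <- profile@normalizedIntensity[rev(channelOrder), , drop = FALSE]
  if (is.null(main))
    main <- sprintf("edge %d-%d (%s, r=%.2g um)", profile@edge[1L],
                    profile@edge[2L], profile@shape$kind,
                    profile@shape$radius)
  graphics::image(x = profile@binPositions, z = t(m),
                  y = seq_len(nrow(m)), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "position along edge (um)", ylab = "", yaxt = "n",
                  main = main)
  graphics::axis(2L, at = seq_len(nrow(m)), labels = rownames(m),
                 las = 2L, cex.axis = 0.7)
  invisible(channelOrder)
}

#' Line chart of an interaction profile
#'
#' @param profile an [InteractionProfile-class].
#' @param channels channels to draw (default: all).
#' @param normalized draw normalized (default) or raw mean intensities.
#' @export
plotProfileLines <- function(profile, channels = NULL, normalized = TRUE) {
  m <- if (normalized) profile@normalizedIntensity else profile@meanIntensity
  if (!is.null(channels)) m <- m[channels, , drop = FALSE]
  cols <- grDevices::hcl.colors(nrow(m), "Dark 3")
  graphics::matplot(profile@binPositions, t(m), type = "l", lty = 1L,
                    col = cols, xlab = "position along edge (um)",
                    ylab = if (normalized) "normalized intensity"
                           else "mean intensity")
  graphics::legend("topright", legend = rownames(m), col = cols, lty = 1L,
                   cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Radial clock-face chart of a polarization profile
#'
#' One ring per channel (inner to outer); the radial extent of each of
#' the sector wedges encodes the normalized sector value. 12 o'clock is
#' the profile's north; sectors run clockwise.
#'
#' @param profile a [PolarizationProfile-class].
#' @param channels ordered channel names (about 1-4 read best).
#' @export
plotPolarization <- function(profile, channels) {
  rcd <- radialChartData(profile, channels)
  nring <- length(rcd$rings)
  graphics::plot(NA, xlim = c(-nring, nring) * 1.15,
                 ylim = c(-nring, nring) * 1.15, asp = 1, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("node %s polarization", profile@nodeId))
  cols <- grDevices::hcl.colors(nring, "Dark 3")
  for (i in seq_len(nring)) {
    ring <- rcd$rings[[i]]
    r0 <- i - 1
    for (k in seq_along(ring$widths)) {
      # clockwise from 12 o'clock: screen angle = 90 - theta
      a0 <- (90 - ring$thetaStart[k]) * pi / 180
      a1 <- (90 - ring$thetaEnd[k]) * pi / 180
      aa <- seq(a0, a1, length.out = 12L)
      r1 <- r0 + ring$widths[k]
      graphics::polygon(c(r0 * cos(aa), rev(r1 * cos(aa))),
                        c(r0 * sin(aa), rev(r1 * sin(aa))),
                        col = grDevices::adjustcolor(cols[i], 0.6),
                        border = cols[i])
    }
  }
  graphics::legend("topright", legend = vapply(rcd$rings, `[[`, "", "channel"),
                   fill = cols, bty = "n", cex = 0.7)
  invisible(NULL)
}
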