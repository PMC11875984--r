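#' Resample a profile to a new length by linear interpolation
#'
#' Endpoint-anchored: output index j samples the piecewise-linear
#' function through the input points at parameter `j / (targetN - 1)`,
#' so the first and last values are preserved exactly and resampling to
#' the input length is the identity (bit-identical). Used to normalize
#' profile lengths before comparison, and for common-length heatmaps.
#'
#' @param values numeric vector, length >= 2.
#' @param targetN output length, >= 2.
#' @return numeric vector of length `targetN`.
#' @export
resampleProfile <- function(values, targetN) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to resample")
  targetN <- as.integer(targetN)
  if (targetN < 2L) stop("targetN must be >= 2")
  if (targetN == n) return(values)
  stats::approx(x = seq(0, 1, length.out = n), y = values,
                xout = seq(0, 1, length.out = targetN))$y
}

#' Profile distance between two equal-length vectors
#'
#' The default `"pointwise"` metric is the mean Minkowski distance of the
#' aligned values, `(mean(|X_i - Y_i|^p))^(1/p)` - a true metric for
#' p >= 1 and, at p = 1, absolutely homogeneous of degree 1. The
#' alternative `"wasserstein"` metric treats the two vectors as mass
#' distributions over the bins (each normalized to total mass 1; an
#' all-zero vector counts as uniform) and computes the mean Minkowski
#' distance of the two empirical CDFs, which is insensitive to small
#' phase shifts of the signal along the edge.
#'
#' @param x,y numeric vectors of equal length (resample first if needed).
#' @param p Minkowski exponent, >= 1.
#' @param metric `"pointwise"` (default) or `"wasserstein"`.
#' @return scalar distance >= 0.
#' @export
profileDistance <- function(x, y, p = 1,
                            metric = c("pointwise", "wasserstein")) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    stop("length mismatch (", length(x), " vs ", length(y),
         "): resample before comparing")
  if (p < 1) stop("p must be >= 1")
  if (metric == "wasserstein") {
    mass <- function(v) {
      s <- sum(v)
      if (s > 0) v / s else rep(1 / length(v), length(v))
    }
    x <- cumsum(mass(x))
    y <- cumsum(mass(y))
  }
  mean(abs(x - y)^p)^(1 / p)
}

#' Distance between two interaction profiles
#'
#' Per-channel profile distances with the total as their sum. The second
#' profile is length-normalized to the first profile's bin count by
#' linear interpolation before comparing. By default the stored
#' normalized intensities are compared; set `useNormalized = FALSE` for a
#' magnitude-sensitive comparison on raw bin means.
#'
#' @param profileP,profileQ [InteractionProfile-class] objects.
#' @param channels channel names to include (default: profileP's
#'   channels).
#' @param p Minkowski exponent.
#' @param useNormalized compare normalized (default) or raw intensities.
#' @param metric see [profileDistance()].
#' @return list with `total` and named numeric `perChannel`.
#' @export
edgeDistance <- function(profileP, profileQ, channels = NULL, p = 1,
                         useNormalized = TRUE,
                         metric = c("pointwise", "wasserstein")) {
  metric <- match.arg(metric)
  mp <- if (useNormalized) profileP@normalizedIntensity else profileP@meanIntensity
  mq <- if (useNormalized) profileQ@normalizedIntensity else profileQ@meanIntensity
  if (is.null(channels)) channels <- rownames(mp)
  missing <- setdiff(channels, intersect(rownames(mp), rownames(mq)))
  if (length(missing))
    stop("channel(s) missing from a profile: ", paste(missing, collapse = ", "))
  nb <- profileP@nBins
  per <- vapply(channels, function(ch)
    profileDistance(mp[ch, ], resampleProfile(mq[ch, ], nb), p, metric), 0)
  list(total = sum(per), perChannel = per)
}

#' Rank candidate edges by profile similarity to a reference edge
#'
#' Each candidate profile is length-normalized to the reference's bin
#' count, per-channel distances are computed and summed, and candidates
#' are sorted ascending by total distance (most similar first). The
#' reference itself, if among the candidates, ranks first with distance
#' 0. Ties break by lexicographic edge key; the result is invariant to
#' candidate input order.
#'
#' @param reference reference edge: integer(2) node ids or an `"a-b"`
#'   key; its profile must be in `profiles`.
#' @param profiles named list of [InteractionProfile-class] objects keyed
#'   `"a-b"` (as from [computeProfiles()]).
#' @param candidates optional subset of keys or 2-column id matrix
#'   (default: all profiles).
#' @param channels,p,useNormalized,metric see [edgeDistance()].
#' @return a [RankingResult-class].
#' @export
rankEdges <- function(reference, profiles, candidates = NULL,
                      channels = NULL, p = 1, useNormalized = TRUE,
                      metric = c("pointwise", "wasserstein")) {
  metric <- match.arg(metric)
  refKey <- if (is.character(reference)) reference
            else .edge_key(reference[1L], reference[2L])
  if (!refKey %in% names(profiles))
    stop("no profile for reference edge ", refKey)
  keys <- if (is.null(candidates)) names(profiles)
          else if (is.character(candidates)) candidates
          else .edge_key(candidates[, 1L], candidates[, 2L])
  if (!length(keys)) stop("empty candidate list")
  if (!all(keys %in% names(profiles)))
    stop("no profile for candidate edge(s): ",
         paste(setdiff(keys, names(profiles)), collapse = ", "))
  ref <- profiles[[refKey]]
  if (is.null(channels))
    channels <- rownames(ref@normalizedIntensity)
  dists <- lapply(keys, function(k)
    edgeDistance(ref, profiles[[k]], channels, p, useNormalized, metric))
  total <- vapply(dists, `[[`, 0, "total")
  per <- do.call(rbind, lapply(dists, `[[`, "perChannel"))
  rownames(per) <- keys
  o <- order(total, keys)
  ab <- do.call(rbind, strsplit(keys[o], "-", fixed = TRUE))
  entries <- data.frame(a = as.integer(ab[, 1L]), b = as.integer(ab[, 2L]),
                        total = total[o])
  new("RankingResult",
      referenceEdge = {
        r <- as.integer(strsplit(refKey, "-", fixed = TRUE)[[1L]])
        r
      },
      entries = entries,
      perChannel = per[o, , drop = FALSE],
      parameters = list(p = p, metric = metric, channels = channels,
                        useNormalized = useNormalized))
}
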