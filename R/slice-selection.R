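#' Mean-intensity axial profile
#'
#' Per-slice mean MR intensity restricted to hand-mask voxels. Slices where
#' the mask is empty get value 0 and are flagged.
#'
#' @param volume a [wrist_volume] or array.
#' @param mask logical hand mask of the same shape.
#' @return numeric vector of length `nz` with attribute `empty` (logical
#'   vector flagging slices without mask voxels).
#' @export
axial_profile <- function(volume, mask) {
  arr <- as_volume_array(volume)
  check_same_shape(arr, mask)
  nz <- dim(arr)[3]
  sums <- apply(arr * mask, 3, sum)
  cnts <- apply(mask, 3, sum)
  if (all(cnts == 0)) stop("mask is empty on every slice")
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  structure(vals, empty = cnts == 0)
}

#' Representative radioulnar slice
#'
#' Scans local maxima of the (box-3 smoothed) axial mean-intensity profile
#' from the highest slice index (proximal end) downward and returns the first
#' maximum that has a sufficiently deep minimum on its distal side at a
#' sufficiently close distance: the relative depth
#' `(max - min) / (0.5 * (max + min))` must exceed `min_rel_depth` and the
#' separation must be below `max_dist_frac` of the axial extent. The minimum
#' corresponds to the joint gap distal to the radius and ulna; the returned
#' slice cuts through both bones.
#'
#' @param profile numeric profile from [axial_profile].
#' @param min_rel_depth minimum relative depth of the distal minimum (0.10).
#' @param max_dist_frac maximum max-to-min distance as a fraction of the
#'   axial extent (0.15).
#' @param smooth_box running-average width applied before peak detection
#'   (suppresses single-slice noise).
#' @return the selected slice index (1-based).
#' @export
select_radioulnar_slice <- function(profile, min_rel_depth = 0.10,
                                    max_dist_frac = 0.15, smooth_box = 3L) {
  p <- as.numeric(profile)
  L <- length(p)
  if (L < 5L) stop("profile too short")
  ps <- smooth_histogram(p, smooth_box)
  maxima <- local_extrema(ps, "max")
  win <- max_dist_frac * L
  for (i in rev(maxima)) {
    j_lo <- max(1L, i - as.integer(ceiling(win)) + 1L)
    js <- seq(j_lo, i - 1L)
    js <- js[(i - js) < win]
    if (length(js) == 0) next
    m <- js[which.min(ps[js])]
    depth <- (ps[i] - ps[m]) / (0.5 * (ps[i] + ps[m]))
    if (is.finite(depth) && depth > min_rel_depth) return(i)
  }
  stop("radioulnar slice classifier failed: no maximum with a qualifying distal minimum")
}

# Indices of local maxima/minima; plateaus collapse to their last index.
local_extrema <- function(p, which = c("max", "min")) {
  which <- match.arg(which)
  if (which == "min") p <- -p
  n <- length(p)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (p[i] > p[i - 1L]) {
      j <- i
      while (j < n && p[j + 1L] == p[j]) j <- j + 1L
      if (j < n && p[j + 1L] < p[j]) out <- c(out, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Per-cluster features for the metacarpal filter
#'
#' For every connected component: voxel count, axial extent `d` in slices,
#' and the axial coordinates `x_min`/`x_max` in the distal-positive frame
#' `x = (L_slices - z) * dz` (origin at the most proximal slice, increasing
#' toward the fingers; the anatomical origin at the styloid apex is
#' approximated by the field-of-view edge).
#'
#' @param components integer label array (from [connected_components]).
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm.
#' @return data frame with one row per component: `label`, `size`,
#'   `d_slices`, `z_min`, `z_max`, `x_min`, `x_max`.
#' @export
cluster_features <- function(components, spacing = c(0.75, 0.75, 0.7)) {
  d <- dim(components)
  nz <- d[3]; dz <- spacing[3]
  labs <- sort(unique(components[components > 0]))
  rows <- lapply(labs, function(l) {
    w <- which(components == l)
    z <- (w - 1L) %/% (d[1] * d[2]) + 1L
    zr <- range(z)
    data.frame(label = l, size = length(w), d_slices = zr[2] - zr[1] + 1L,
               z_min = zr[1], z_max = zr[2],
               x_min = (nz - zr[2]) * dz, x_max = (nz - zr[1]) * dz)
  })
  if (length(rows) == 0)
    return(data.frame(label = integer(0), size = integer(0),
                      d_slices = integer(0), z_min = integer(0),
                      z_max = integer(0), x_min = numeric(0), x_max = numeric(0)))
  do.call(rbind, rows)
}

#' Representative metacarpal slice
#'
#' Thresholds the volume at `TH_MCP = th_me + buffer`, labels the resulting
#' clusters, keeps at most `n_keep` clusters with the largest axial extent
#' among those whose `x_min` exceeds `x_th_frac` of the axial field-of-view
#' extent (this removes the carpals, which sit closer to the proximal
#' origin), and returns the axial slice with the highest mean of the
#' filtered binary image.
#'
#' @param volume a [wrist_volume] or array.
#' @param th_me maximum-entropy threshold of the volume
#'   ([max_entropy_threshold]).
#' @param buffer additive intensity margin separating bone clusters (200).
#' @param n_keep maximum number of clusters kept (10).
#' @param x_th_frac fraction of the axial extent for the `x_min` filter
#'   (0.35).
#' @return selected slice index (1-based), with attribute `clusters` (the
#'   retained cluster features).
#' @export
select_metacarpal_slice <- function(volume, th_me, buffer = 200, n_keep = 10L,
                                    x_th_frac = 0.35) {
  arr <- as_volume_array(volume)
  sp <- vol_spacing(volume)
  bin <- array(arr > th_me + buffer, dim = dim(arr))
  if (!any(bin)) stop("thresholded volume is empty")
  cc <- connected_components(bin)
  feats <- cluster_features(cc$labels, sp)
  L <- dim(arr)[3] * sp[3]
  ok <- feats[feats$x_min > x_th_frac * L, , drop = FALSE]
  if (nrow(ok) == 0) stop("no cluster passes the x_min filter")
  ok <- ok[order(-ok$d_slices, ok$label), , drop = FALSE]
  ok <- ok[seq_len(min(n_keep, nrow(ok))), , drop = FALSE]
  keep <- array(cc$labels %in% ok$label, dim = dim(arr))
  score <- apply(keep, 3, mean)
  z <- which.max(score)  # first (most distal) slice on ties
  structure(as.integer(z), clusters = ok)
}
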