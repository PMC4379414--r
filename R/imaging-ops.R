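#' Binary morphology with diamond or square structuring elements
#'
#' Minkowski erosion, dilation, opening (erode-then-dilate) and closing
#' (dilate-then-erode) on 2D or 3D logical masks. The `"diamond"` element is
#' the city-block ball (4-connected in 2D, 6-connected octahedron in 3D); the
#' `"square"` element is the Chebyshev ball (8/26-connected). A half-size
#' `half` element has full width `2 * half + 1`.
#'
#' For these elements the size-`n` operation equals `n` iterations of the
#' unit operation; `morph()` uses the iterated form by default and the direct
#' (single-pass, size-`n` kernel) form when `direct = TRUE`. Voxels outside
#' the grid count as background (`pad = 0`); `pad = 1` treats them as
#' foreground, which yields exact erosion/dilation duality at the borders.
#'
#' @param mask logical 2D or 3D array.
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`.
#' @param kind `"diamond"` or `"square"`.
#' @param half non-negative integer half-size.
#' @param per_slice apply the 2D element to every axial slice of a 3D mask.
#' @param direct use the single-pass size-`half` kernel instead of iterating
#'   the unit kernel.
#' @param pad value assumed outside the grid (0 or 1).
#' @return logical array of the same shape.
#' @examples
#' m <- array(FALSE, c(5, 5)); m[3, 3] <- TRUE
#' sum(morph(m, "dilate", "diamond", 1))  # the 5-pixel diamond
#' @export
morph <- function(mask, op = c("erode", "dilate", "open", "close"),
                  kind = c("diamond", "square"), half = 1L,
                  per_slice = FALSE, direct = FALSE, pad = 0L) {
  op <- match.arg(op)
  kind <- match.arg(kind)
  half <- as.integer(half)
  if (half < 0L) stop("'half' must be >= 0")
  dm <- mask_dims(mask)
  if (half == 0L) return(mask)
  if (op == "open")
    return(morph(morph(mask, "erode", kind, half, per_slice, direct, pad),
                 "dilate", kind, half, per_slice, direct, pad))
  if (op == "close")
    return(morph(morph(mask, "dilate", kind, half, per_slice, direct, pad),
                 "erode", kind, half, per_slice, direct, pad))
  erode <- op == "erode"
  twoD <- dm$is2d || per_slice
  v <- as.logical(mask)
  if (direct) {
    v <- cpp_morph_direct(v, dm$nx, dm$ny, dm$nz, erode,
                          if (kind == "diamond") 0L else 1L, half, twoD, pad)
  } else {
    for (i in seq_len(half))
      v <- cpp_morph_unit(v, dm$nx, dm$ny, dm$nz, erode,
                          if (kind == "diamond") 0L else 1L, twoD, pad)
  }
  array(v, dim = dim(mask))
}

mask_dims <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2D or 3D array")
  list(nx = d[1], ny = d[2], nz = if (length(d) == 3L) d[3] else 1L,
       is2d = length(d) == 2L)
}

#' Fill interior holes of a mask, slice by slice
#'
#' Background regions of an axial slice that are not connected (4-adjacency)
#' to the slice border become foreground. A 2D mask is treated as a single
#' slice; a 3D mask is processed independently per axial slice, matching the
#' strictly two-dimensional processing used for the hand mask.
#'
#' @param mask logical 2D or 3D array.
#' @return logical array of the same shape.
#' @export
fill_holes_2d <- function(mask) {
  dm <- mask_dims(mask)
  array(cpp_fill_holes_slices(as.logical(mask), dm$nx, dm$ny, dm$nz),
        dim = dim(mask))
}

#' Connected components of a binary mask
#'
#' Components are labelled 1..K in increasing order of each component's
#' smallest linear index (x fastest, then y, then z), which makes the
#' labelling deterministic. `"face"` connectivity (4 in 2D / 6 in 3D) is the
#' package default, consistent with the unit-diamond morphology; `"full"`
#' gives 8/26-connectivity.
#'
#' @param mask logical 2D or 3D array.
#' @param connectivity `"face"` or `"full"`.
#' @return list with `labels` (integer array) and `sizes` (integer vector,
#'   one entry per component).
#' @export
connected_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  dm <- mask_dims(mask)
  lab <- cpp_label(as.logical(mask), dm$nx, dm$ny, dm$nz, connectivity == "full")
  lab <- array(lab, dim = dim(mask))
  k <- max(lab, 0L)
  sizes <- if (k > 0L) tabulate(lab[lab > 0L], nbins = k) else integer(0)
  list(labels = lab, sizes = sizes)
}

#' Keep the k largest connected components
#'
#' Size ties are broken toward the component with the smaller lexicographic
#' anchor voxel (i.e. the smaller component label, since labels are assigned
#' in scan order).
#'
#' @param mask logical array.
#' @param k number of components to retain (all, if fewer exist).
#' @param connectivity passed to [connected_components].
#' @return logical array.
#' @export
keep_largest <- function(mask, k = 1L, connectivity = "face") {
  if (k < 1L) stop("'k' must be >= 1")
  cc <- connected_components(mask, connectivity)
  if (length(cc$sizes) <= k) return(mask)
  keep <- order(-cc$sizes, seq_along(cc$sizes))[seq_len(k)]
  array(cc$labels %in% keep, dim = dim(mask))
}

#' Gradient-magnitude relief of a volume
#'
#' The volume is blurred with a small Gaussian (3-tap kernel per axis,
#' half-size 1 voxel, sigma 0.5) and differentiated with Prewitt filters;
#' the per-axis components are combined as the Euclidean norm. This
#' non-negative field is the topographic relief flooded by the watershed.
#'
#' @param volume a [wrist_volume] or numeric array (2D or 3D; at least
#'   3 voxels per axis).
#' @return numeric array of gradient magnitudes, same shape as the input.
#' @export
gradient_magnitude <- function(volume) {
  arr <- as_volume_array_2d3d(volume)
  d <- dim(arr)
  if (any(d < 3L)) stop("gradient_magnitude needs at least 3 voxels per axis")
  dm <- mask_dims(arr)
  array(cpp_gradient_magnitude(as.numeric(arr), dm$nx, dm$ny, dm$nz), dim = d)
}

as_volume_array_2d3d <- function(x) {
  if (inherits(x, "wrist_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) %in% c(2L, 3L)) return(x)
  stop("expected a wrist_volume or a 2D/3D array")
}

#' Histogram of integer intensities
#'
#' Counts per intensity value from 0 to `max(x)` (dense bins); the
#' intensities are stored in the names.
#'
#' @param volume a [wrist_volume] or array of non-negative integers.
#' @return named numeric vector of counts.
#' @export
intensity_histogram <- function(volume) {
  arr <- as_volume_array_2d3d(volume)
  v <- as.integer(arr)
  if (any(v < 0L)) stop("intensities must be non-negative")
  h <- tabulate(v + 1L, nbins = max(v) + 1L)
  stats::setNames(as.numeric(h), 0:max(v))
}

hist_intensities <- function(h) {
  if (!is.null(names(h))) as.numeric(names(h)) else seq_along(h) - 1
}

#' Kapur maximum-entropy threshold
#'
#' Chooses the intensity cut `t` maximizing the sum of Shannon entropies of
#' the sub-histograms at intensities `<= t` (background) and `> t`
#' (foreground). Only cuts leaving mass on both sides are considered; ties go
#' to the lowest intensity. The result is invariant under scaling all counts
#' by a constant.
#'
#' @param histogram numeric vector of counts; names, if present, are the
#'   intensity values (defaults to 0-based bin indices).
#' @return the threshold intensity `TH_ME` (background is `<= TH_ME`).
#' @export
max_entropy_threshold <- function(histogram) {
  h <- as.numeric(histogram)
  if (length(h) < 2L || sum(h > 0) < 2L)
    stop("histogram must have at least two occupied bins")
  if (any(h < 0)) stop("histogram counts must be non-negative")
  ints <- hist_intensities(histogram)
  p <- h / sum(h)
  P1 <- cumsum(p)
  # entropy accumulators: S1(t) = -sum_{i<=t} p log p (0 log 0 := 0)
  plogp <- ifelse(p > 0, p * log(p), 0)
  S1 <- cumsum(plogp)
  Stot <- S1[length(S1)]
  n <- length(p)
  t_idx <- seq_len(n - 1L)
  ok <- P1[t_idx] > 0 & P1[t_idx] < 1
  if (!any(ok)) stop("no admissible cut point")
  Hb <- -S1[t_idx] / P1[t_idx] + log(P1[t_idx])
  Hf <- -(Stot - S1[t_idx]) / (1 - P1[t_idx]) + log(1 - P1[t_idx])
  crit <- Hb + Hf
  crit[!ok] <- -Inf
  ints[t_idx[which.max(crit)]]
}

#' Running-average smoothing of a histogram
#'
#' Centered moving average with an odd box width; edge bins are replicated so
#' the smoothed histogram has the same length. With `box = 1` this is the
#' identity.
#'
#' @param histogram numeric vector of counts (names preserved).
#' @param box odd positive integer window width (gray levels).
#' @return numeric vector of the same length.
#' @export
smooth_histogram <- function(histogram, box = 11L) {
  box <- as.integer(box)
  if (box < 1L || box %% 2L == 0L) stop("'box' must be an odd positive integer")
  h <- as.numeric(histogram)
  if (box == 1L) return(stats::setNames(h, names(histogram)))
  r <- (box - 1L) %/% 2L
  hp <- c(rep(h[1], r), h, rep(h[length(h)], r))
  out <- stats::filter(hp, rep(1 / box, box), sides = 2)
  stats::setNames(as.numeric(out[(r + 1):(r + length(h))]), names(histogram))
}
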