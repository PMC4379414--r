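#' Hand-mask parameters
#'
#' Defaults follow the low-field wrist protocol: the histogram valley between
#' the air/background mode and the tissue mode always falls between
#' `i_low = 200` and `i_high = 500`; the histogram is smoothed with an
#' 11-gray-level running average; slices are closed with a square element of
#' half-size `box = 5` pixels (full width 11 px, about 8 mm, wider than
#' cortical bone or tendons) and finally eroded with half-size `box %/% 2`
#' (about 1.5 mm, thinner than skin).
#'
#' @param i_low,i_high intensity bounds of the threshold search range.
#' @param smooth_box histogram smoothing window (odd, gray levels).
#' @param box closing half-size in pixels; the final erosion uses `box %/% 2`.
#' @return list of validated parameters.
#' @export
mask_params <- function(i_low = 200L, i_high = 500L, smooth_box = 11L, box = 5L) {
  if (i_low >= i_high) stop("'i_low' must be < 'i_high'")
  if (box < 1L) stop("'box' must be >= 1")
  list(i_low = as.integer(i_low), i_high = as.integer(i_high),
       smooth_box = as.integer(smooth_box), box = as.integer(box),
       erosion_half = as.integer(box) %/% 2L)
}

#' Automatic hand-mask threshold
#'
#' Smooths the intensity histogram with a running average and returns the
#' minimum of the smoothed histogram restricted to `[i_low, i_high]` -- the
#' valley to the right of the background mode. Ties go to the lowest
#' intensity.
#'
#' @param volume a [wrist_volume] or integer array.
#' @param params a [mask_params] list.
#' @return the threshold intensity `TH`.
#' @export
select_mask_threshold <- function(volume, params = mask_params()) {
  h <- intensity_histogram(volume)
  ints <- hist_intensities(h)
  if (max(ints) < params$i_low)
    stop(sprintf("intensity range ends below i_low = %d: threshold search range is empty",
                 params$i_low))
  hs <- smooth_histogram(h, params$smooth_box)
  inside <- ints >= params$i_low & ints <= min(params$i_high, max(ints))
  cand_i <- ints[inside]
  cand_v <- hs[inside]
  cand_i[which.min(cand_v)]  # which.min takes the first (lowest intensity) tie
}

#' Extract the hand mask
#'
#' Per axial slice (strictly 2D processing): threshold at `th`, morphological
#' closing with a square element (half-size `box`), 2D hole filling, then
#' erosion with a square element (half-size `box %/% 2`). The closing pulls
#' dark cortical bone and tendons into the mask; the final erosion keeps the
#' mask surface inside the skin so it can serve as a soft-tissue marker.
#'
#' @param volume a [wrist_volume] or array.
#' @param th intensity threshold (foreground is `>= th`).
#' @param params a [mask_params] list.
#' @return logical array, same shape as the volume.
#' @export
build_hand_mask <- function(volume, th, params = mask_params()) {
  arr <- as_volume_array_2d3d(volume)
  m <- array(arr >= th, dim = dim(arr))
  m <- morph(m, "close", "square", params$box, per_slice = TRUE)
  m <- fill_holes_2d(m)
  morph(m, "erode", "square", params$erosion_half, per_slice = TRUE)
}

#' Soft-tissue (background) marker from the hand-mask surface
#'
#' The one-voxel-thick internal boundary of the mask, computed in-plane per
#' axial slice: `mask & !erode(mask)` with the unit diamond. It lies within
#' the external regions of the hand, so it is guaranteed to be inside the
#' mask and outside the bones.
#'
#' @param mask logical hand mask (2D or 3D).
#' @return logical array of the same shape.
#' @export
background_marker <- function(mask) {
  if (!any(mask)) stop("hand mask is empty: cannot build a background marker")
  er <- morph(mask, "erode", "diamond", 1L, per_slice = TRUE)
  mask & !er
}
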