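#' Watershed from markers
#'
#' Floods the relief (gradient magnitude) from the marker regions in order
#' of increasing relief value, using a priority queue ordered by
#' (relief value, insertion order) and face connectivity. Every voxel
#' receives the label of the basin that reaches it first; marker voxels keep
#' their labels. With `lines = TRUE`, voxels whose already-labelled face
#' neighbours disagree at assignment time become label 0 (explicit watershed
#' lines) instead -- by default there are no line voxels, since the
#' downstream cortical dilation and the metrics need total labelings.
#'
#' @param relief numeric 2D/3D array (non-negative), or a [wrist_volume].
#' @param markers a `marker_set` from [assemble_markers], or an integer
#'   label array (0 = unset).
#' @param lines emit watershed lines as label 0.
#' @return integer label array; when `markers` is a `marker_set` the label
#'   table (including `background`) is attached as attribute `table`.
#' @export
watershed_from_markers <- function(relief, markers, lines = FALSE) {
  arr <- as_volume_array_2d3d(relief)
  if (inherits(markers, "marker_set")) {
    mlab <- as_marker_array(markers)
  } else if (is.array(markers)) {
    mlab <- markers
  } else stop("markers must be a marker_set or a label array")
  check_same_shape(arr, mlab)
  if (!any(mlab > 0L)) stop("marker set is empty")
  dm <- mask_dims(arr)
  out <- cpp_watershed(as.numeric(arr), as.integer(mlab),
                       dm$nx, dm$ny, dm$nz, lines)
  out <- array(out, dim = dim(arr))
  attr(out, "table") <- attr(mlab, "table")
  out
}

#' Cortical-compensation dilation
#'
#' The watershed captures the bright marrow; the dark cortical shell (about
#' one voxel, 0.7 mm) stays outside. Each bone region is therefore dilated
#' with the unit diamond element `half_size` times. A voxel contested by
#' several dilated bones goes to the bone offering the lowest relief along
#' the voxel's face neighbourhood (ties to the lower label); pre-dilation
#' bone voxels are never reassigned.
#'
#' @param labels integer label array of bone regions (0 = background).
#' @param relief numeric relief array used to resolve contested voxels; when
#'   `NULL`, contested voxels go to the lower label.
#' @param half_size number of unit dilations (1).
#' @return integer label array.
#' @export
cortical_dilation <- function(labels, relief = NULL, half_size = 1L) {
  d <- dim(labels)
  labs <- sort(unique(labels[labels > 0L]))
  if (length(labs) == 0L || half_size < 1L) return(labels)
  out <- labels
  rel <- if (is.null(relief)) NULL else as_volume_array_2d3d(relief)
  for (it in seq_len(half_size)) {
    grown <- lapply(labs, function(l)
      morph(array(out == l, dim = d), "dilate", "diamond", 1L))
    claim <- Reduce(`+`, lapply(grown, function(g) as.integer(g)))
    nw <- array(0L, dim = d)
    for (i in seq_along(labs)) {
      add <- grown[[i]] & out == 0L & array(claim == 1L, dim = d)
      nw[add] <- labs[i]
    }
    contested <- which(array(claim > 1L, dim = d) & out == 0L)
    if (length(contested) > 0) {
      for (v in contested) {
        cand <- labs[vapply(seq_along(labs), function(i) grown[[i]][v], logical(1))]
        nw[v] <- if (is.null(rel)) min(cand)
                 else cand[which.min(vapply(cand, function(l)
                   neighbour_min_relief(out, rel, v, l), numeric(1)))]
      }
    }
    out[nw > 0L] <- nw[nw > 0L]
  }
  out
}

# lowest relief among face neighbours of linear voxel v belonging to label l
neighbour_min_relief <- function(labels, relief, v, l) {
  d <- dim(labels)
  v0 <- v - 1L
  x <- v0 %% d[1]; y <- (v0 %/% d[1]) %% d[2]; z <- v0 %/% (d[1] * d[2])
  best <- Inf
  for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
    X <- x + off[1]; Y <- y + off[2]; Z <- z + off[3]
    if (X < 0 || X >= d[1] || Y < 0 || Y >= d[2] ||
        Z < 0 || (length(d) == 3 && Z >= d[3]) || (length(d) == 2 && Z > 0)) next
    j <- 1L + X + d[1] * (Y + d[2] * Z)
    if (labels[j] == l) best <- min(best, relief[j])
  }
  best
}

#' Run one watershed segmentation stage
#'
#' Computes the gradient-magnitude relief (unless supplied), floods it from
#' the given markers (optionally with the complement of a restriction
#' region acting as the background marker), drops the background label and
#' applies the cortical-compensation dilation to every bone.
#'
#' @param volume a [wrist_volume] or array.
#' @param markers a `marker_set` (its background marker is used unless
#'   `region` is given).
#' @param region optional logical array: the analysis region; all voxels
#'   outside it form the background marker (used by the carpal stage).
#' @param relief optional precomputed gradient magnitude.
#' @param dilation_half half-size of the final cortical dilation (1).
#' @return integer label array, labels 1..K in marker order, with attribute
#'   `bones` (the marker names).
#' @export
segment_stage <- function(volume, markers, region = NULL, relief = NULL,
                          dilation_half = 1L) {
  stopifnot(inherits(markers, "marker_set"))
  arr <- as_volume_array(volume)
  if (is.null(relief)) relief <- gradient_magnitude(arr)
  if (!is.null(region)) {
    check_same_shape(arr, region)
    bg <- !region
    for (nm in names(markers$objects))
      bg <- bg & !markers$objects[[nm]]
    markers <- assemble_markers(markers$objects, bg)
  }
  ws <- watershed_from_markers(relief, markers)
  k <- length(markers$objects)
  out <- array(0L, dim = dim(arr))
  sel <- ws >= 1L & ws <= k
  out[sel] <- ws[sel]
  out <- cortical_dilation(out, relief, dilation_half)
  attr(out, "bones") <- names(markers$objects)
  out
}
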