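#' Extend a seed into a 3D marker by intensity-ordered growth
#'
#' Best-first region growing from `seed`: voxels are merged in order of
#' decreasing MR intensity (equal intensities in first-in-first-out order,
#' i.e. breadth-first among ties), over face neighbours, restricted to the
#' axial slices on the chosen side of the seed (the seed slice included).
#' Growth stops at the first accepted voxel `V` whose axial distance from
#' the seed equals `depth_slices` (about 7 mm at 0.7 mm slices for the
#' default 10, the typical extent of the radioulnar joint). The marker is
#' the reconstructed predecessor path from `V` back to the seed -- a thin
#' string of bright voxels, stable input for the watershed.
#'
#' @param volume a [wrist_volume] or 3D array.
#' @param seed integer voxel `c(x, y, z)` (1-based).
#' @param depth_slices stopping distance in slices.
#' @param direction `"proximal"` (growth toward increasing z) or
#'   `"distal"`.
#' @return list with `marker` (logical array: the path voxels), `path`
#'   (n x 3 matrix of voxel coordinates, stop voxel first, seed last),
#'   `grown` (number of accepted voxels) and `truncated` (TRUE when the
#'   volume edge was reached before the requested depth; a warning is
#'   raised).
#' @export
grow_marker <- function(volume, seed, depth_slices = 10L,
                        direction = c("proximal", "distal")) {
  direction <- match.arg(direction)
  arr <- as_volume_array(volume)
  d <- dim(arr)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("'seed' must be an in-volume voxel c(x, y, z)")
  lin <- (seed[1] - 1L) + d[1] * ((seed[2] - 1L) + d[2] * (seed[3] - 1L))
  res <- cpp_grow_path(as.numeric(arr), d[1], d[2], d[3], lin,
                       as.integer(depth_slices),
                       if (direction == "proximal") 1L else -1L)
  if (res$truncated)
    warning("marker growth reached the volume edge before the requested depth; marker truncated")
  marker <- array(FALSE, dim = d)
  marker[res$path] <- TRUE
  path <- cbind(x = (res$path - 1L) %% d[1] + 1L,
                y = ((res$path - 1L) %/% d[1]) %% d[2] + 1L,
                z = (res$path - 1L) %/% (d[1] * d[2]) + 1L)
  list(marker = marker, path = path, grown = length(res$grown),
       truncated = res$truncated)
}

#' Central pixel of a 2D marker
#'
#' The foreground pixel at the largest city-block distance from the
#' background; ties resolve to the lexicographically smallest pixel. Used to
#' replace each metacarpal candidate marker, whose borders may overlap bone
#' boundaries, by a single interior point.
#'
#' @param marker_2d logical matrix.
#' @return integer vector `c(x, y)`.
#' @export
central_pixel <- function(marker_2d) {
  if (!is.matrix(marker_2d)) stop("'marker_2d' must be a 2D mask")
  if (!any(marker_2d)) stop("marker is empty")
  d <- dim(marker_2d)
  dt <- cpp_cityblock_dt_2d(as.logical(marker_2d), d[1], d[2])
  i <- which.max(dt)  # first maximum in column-major order = lexicographic tie-break
  c(x = (i - 1L) %% d[1] + 1L, y = (i - 1L) %/% d[1] + 1L)
}

# centre of mass of a 2D marker, snapped to the nearest marker pixel when
# the rounded centroid falls outside a concave marker
marker_com_pixel <- function(marker_2d) {
  w <- which(marker_2d, arr.ind = TRUE)
  cm <- round(colMeans(w))
  if (marker_2d[cm[1], cm[2]]) return(c(x = cm[1], y = cm[2]))
  dd <- abs(w[, 1] - cm[1]) + abs(w[, 2] - cm[2])
  c(x = w[which.min(dd), 1], y = w[which.min(dd), 2])
}

#' Construct the 3D carpal region
#'
#' The region between the distal envelope of the segmented ulna/radius and
#' the proximal envelope of the segmented metacarpal bases: for every
#' in-plane column the region spans the slices strictly between the
#' most-distal ulna/radius voxel and the most-proximal metacarpal voxel
#' (envelopes are extrapolated to columns without bone by nearest-neighbour
#' filling). It is then clipped by two lateral planes -- support lines in
#' the coronal (x, z) projection, one tangent to the ulna and the fifth
#' metacarpal base, the other tangent to the radius and the first metacarpal
#' base, extruded along the anteroposterior axis -- and by the hand mask;
#' the two earlier stage segmentations are excluded.
#'
#' @param ulna_radius integer label array (radius = 1, ulna = 2).
#' @param metacarpals integer label array (M1..M5 = 3..7).
#' @param mask logical hand mask.
#' @return logical region array with attribute `planes` (the two support
#'   lines as `list(normal, offset)` in (x, z) coordinates).
#' @export
carpal_region <- function(ulna_radius, metacarpals, mask) {
  check_same_shape(ulna_radius, metacarpals)
  check_same_shape(ulna_radius, mask)
  d <- dim(mask)
  ur <- ulna_radius > 0L; mc <- metacarpals > 0L
  if (!any(ur) || !any(mc)) stop("both stage segmentations must be nonempty")
  ur_env <- column_envelope(ur, "min")   # most distal ulna/radius slice
  mc_env <- column_envelope(mc, "max")   # most proximal metacarpal slice
  ur_env <- array(cpp_nearest_fill_2d(as.numeric(ur_env), d[1], d[2]), dim = d[1:2])
  mc_env <- array(cpp_nearest_fill_2d(as.numeric(mc_env), d[1], d[2]), dim = d[1:2])
  zs <- rep(seq_len(d[3]), each = d[1] * d[2])
  region <- array(zs > as.numeric(mc_env) & zs < as.numeric(ur_env), dim = d)
  region <- region & mask & !ur & !mc
  unclipped <- region
  planes <- list(
    left = support_line(project_xz(ulna_radius == 2L), project_xz(metacarpals == 7L),
                        region),
    right = support_line(project_xz(ulna_radius == 1L), project_xz(metacarpals == 3L),
                         region)
  )
  xs_plane <- rep(seq_len(d[1]), times = d[2] * d[3])
  zs_plane <- rep(seq_len(d[3]), each = d[1] * d[2])
  for (pl in planes) {
    if (is.null(pl)) next
    val <- pl$normal[1] * xs_plane + pl$normal[2] * zs_plane
    region <- region & array(val <= pl$offset + 1e-9, dim = d)
  }
  structure(region, planes = planes, unclipped = unclipped)
}

# per-(x, y) column extremum of slice index over foreground; NA if none
column_envelope <- function(mask, which = c("min", "max")) {
  which <- match.arg(which)
  d <- dim(mask)
  env <- matrix(NA_real_, d[1], d[2])
  zs <- if (which == "min") rev(seq_len(d[3])) else seq_len(d[3])
  for (z in zs) {
    sl <- mask[, , z]
    env[sl] <- z
  }
  env
}

project_xz <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  unique(w[, c(1, 3), drop = FALSE])
}

# Lateral support line of two convex point sets: the convex-hull edge of the
# union that bridges the two sets on their outer side, i.e. the common
# tangent whose body side also contains the region centroid. Returned as
# list(normal, offset) with normal . p <= offset on the kept (region + body)
# side, or NULL (with a warning) when no bridging edge qualifies.
support_line <- function(ptsA, ptsB, region) {
  if (nrow(ptsA) == 0 || nrow(ptsB) == 0) { warning("empty body for support line"); return(NULL) }
  w <- which(region, arr.ind = TRUE)
  if (nrow(w) == 0) { warning("empty region for support line"); return(NULL) }
  interior <- colMeans(w[, c(1, 3), drop = FALSE])
  P <- rbind(ptsA, ptsB)
  src <- rep(c(1L, 2L), c(nrow(ptsA), nrow(ptsB)))
  h <- grDevices::chull(P)
  best <- NULL; best_margin <- -Inf
  for (k in seq_along(h)) {
    i <- h[k]; j <- h[if (k == length(h)) 1L else k + 1L]
    if (src[i] == src[j]) next
    e <- P[j, ] - P[i, ]
    n <- c(-e[2], e[1])
    offs <- sum(n * P[i, ])
    # orient so every hull point satisfies n . p <= offs (tangent from outside)
    if (max(n[1] * P[, 1] + n[2] * P[, 2]) > offs + 1e-9 * max(abs(offs), 1)) {
      n <- -n; offs <- -offs
    }
    side <- offs - sum(n * interior)
    if (side < 0) next  # region centroid beyond the tangent: wrong side
    margin <- side / sqrt(sum(n^2))
    if (margin > best_margin) { best_margin <- margin; best <- list(normal = n, offset = offs) }
  }
  if (is.null(best)) warning("no common tangent separates the bodies from the region")
  best
}

#' Finalize the carpal markers
#'
#' Candidate voxels whose MR intensity is below `th_me + buffer` are
#' converted to background (markers must stay inside bright marrow); a
#' morphological closing (square element, half-size 1) and hole filling are
#' applied to every axial slice; the eight largest connected components
#' become the carpal markers.
#'
#' @param candidates logical candidate mask (from [binarize_candidates] at
#'   threshold 240).
#' @param volume a [wrist_volume] or array (original MR intensities).
#' @param th_me maximum-entropy threshold of the volume.
#' @param buffer intensity margin (200).
#' @param reference optional named list of gray marker images (one per
#'   carpal, in case space) used to name the components; defaults to names
#'   `C1..C8` in component order.
#' @param k number of carpal markers (8).
#' @return named list of `k` disjoint logical marker masks.
#' @export
finalize_carpal_markers <- function(candidates, volume, th_me, buffer = 200,
                                    reference = NULL, k = 8L) {
  arr <- as_volume_array_2d3d(volume)
  check_same_shape(candidates, arr)
  m <- candidates & array(arr >= th_me + buffer, dim = dim(arr))
  m <- morph(m, "close", "square", 1L, per_slice = TRUE)
  m <- fill_holes_2d(m)
  cc <- connected_components(m)
  if (length(cc$sizes) < k)
    stop(sprintf("only %d carpal marker components found (need %d); segmentation cannot proceed for all carpals",
                 length(cc$sizes), k))
  keep <- order(-cc$sizes, seq_along(cc$sizes))[seq_len(k)]
  comps <- lapply(keep, function(l) array(cc$labels == l, dim = dim(m)))
  if (!is.null(reference)) match_markers(comps, reference)
  else stats::setNames(comps, paste0("C", seq_len(k)))
}

# Name anonymous marker components after reference gray images by greatest
# total overlap (greedy, deterministic).
match_markers <- function(components, reference) {
  score <- sapply(reference, function(g)
    vapply(components, function(cm) sum(as.numeric(g)[as.logical(cm)]), numeric(1)))
  score <- matrix(score, nrow = length(components),
                  dimnames = list(NULL, names(reference)))
  out <- vector("list", length(components))
  names_left <- colnames(score); comps_left <- seq_along(components)
  nm <- character(length(components))
  while (length(comps_left) > 0 && length(names_left) > 0) {
    sub <- score[comps_left, names_left, drop = FALSE]
    b <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ci <- comps_left[b[1]]; ni <- names_left[b[2]]
    nm[ci] <- ni
    comps_left <- setdiff(comps_left, ci)
    names_left <- setdiff(names_left, ni)
  }
  # leftovers (no reference signal): keep deterministic placeholder names
  if (any(nm == ""))
    nm[nm == ""] <- paste0("X", seq_len(sum(nm == "")))
  stats::setNames(components, nm)
}

#' Assemble a validated marker set
#'
#' Object markers must be pairwise disjoint and nonempty; voxels where the
#' background marker overlaps an object marker are removed from the
#' background (with a warning).
#'
#' @param object_markers named list of logical marker masks.
#' @param background logical background marker mask.
#' @return object of class `marker_set`: list with `objects` and
#'   `background`.
#' @export
assemble_markers <- function(object_markers, background) {
  if (length(object_markers) == 0) stop("no object markers")
  if (is.null(names(object_markers)) || any(names(object_markers) == ""))
    stop("object markers must be named")
  for (nm in names(object_markers)) {
    if (!any(object_markers[[nm]]))
      stop("empty marker for object: ", nm)
    check_same_shape(object_markers[[nm]], background)
  }
  acc <- Reduce(`+`, lapply(object_markers, function(m) as.integer(as.logical(m))))
  if (any(acc > 1L))
    stop("object markers overlap: ambiguous seeds")
  ov <- array(acc > 0L, dim = dim(background)) & background
  if (any(ov)) {
    warning(sprintf("background marker overlapped object markers on %d voxels; trimmed", sum(ov)))
    background <- background & !ov
  }
  structure(list(objects = object_markers, background = background),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d object markers (+background)\n", length(x$objects)))
  for (nm in names(x$objects))
    cat(sprintf("  %-4s %d voxels\n", nm, sum(x$objects[[nm]])))
  cat(sprintf("  background: %d voxels\n", sum(x$background)))
  invisible(x)
}

#' Marker set as a label array
#'
#' Object markers become labels 1..K (list order), the background marker
#' K+1; unset voxels are 0. The label table is attached as attribute
#' `table`.
#'
#' @param markers a `marker_set`.
#' @return integer array.
#' @export
as_marker_array <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  d <- dim(markers$background)
  lab <- array(0L, dim = d)
  for (i in seq_along(markers$objects))
    lab[markers$objects[[i]]] <- i
  lab[markers$background] <- length(markers$objects) + 1L
  attr(lab, "table") <- stats::setNames(
    seq_len(length(markers$objects) + 1L),
    c(names(markers$objects), "background"))
  lab
}
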