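#' Pipeline configuration
#'
#' All stage parameters with their published defaults: mask threshold search
#' range 200..500 with an 11-gray-level smoothing box and closing half-size
#' 5 (erosion 5 %/% 2 = 2); marker growth depth D = 10 slices; cluster
#' filter buffer 200, N = 10 clusters, x threshold 0.35 of the axial
#' extent; radioulnar slice classifier depth 10% and distance 15%; marker
#' binarization thresholds 1 (radioulnar), 1 (metacarpal) and 240 (carpal)
#' with component caps 2/5/8; final diamond dilation half-size 1. Any
#' override is recorded in the run's provenance log.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `wrist_config`.
#' @export
wrist_config <- function(...) {
  cfg <- list(
    i_low = 200L, i_high = 500L, smooth_box = 11L, box = 5L,
    depth_slices = 10L, buffer = 200, n_keep = 10L, x_th_frac = 0.35,
    min_rel_depth = 0.10, max_dist_frac = 0.15,
    marker_threshold_ru = 1, marker_threshold_mc = 1,
    marker_threshold_carpal = 240,
    components_ru = 2L, components_mc = 5L, components_carpal = 8L,
    dilation_half = 1L,
    orientation = "right",
    registration = list(stages = c("rigid", "affine", "ffd_coarse", "ffd_fine"),
                        control = list()),
    marker_override = list()
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  attr(cfg, "overridden") <- names(ov)
  class(cfg) <- "wrist_config"
  cfg
}

stop_stage <- function(stage, e, partial) {
  cond <- structure(class = c("wrist_stage_error", "error", "condition"),
                    list(message = sprintf("stage '%s' failed: %s", stage,
                                           conditionMessage(e)),
                         call = NULL, stage = stage, partial = partial))
  stop(cond)
}

#' Segment the 15 wrist bones
#'
#' Runs the full pipeline: hand-mask extraction, radioulnar stage (slice
#' classifier, 2D atlas registration, region-growing 3D markers, watershed,
#' cortical dilation), metacarpal stage (max-entropy cluster filter slice
#' selection, 2D registration, central-pixel markers, growth, watershed),
#' carpal stage (carpal-region construction from the earlier stages, 3D
#' registration, marker finalization, region-restricted watershed), and the
#' merge into one 15-label map. When stages claim the same voxel after
#' dilation, the earlier stage wins (radius/ulna over metacarpals over
#' carpals).
#'
#' @param volume a [wrist_volume] (or 3D array) to segment.
#' @param atlas an `atlas_bundle`.
#' @param config a [wrist_config].
#' @param verbose print progress lines.
#' @return object of class `wrist_segmentation`: list with `labels`
#'   (merged 15-bone integer array, labels per [wrist_labels]), `stages`
#'   (per-stage intermediates), `log` (provenance character vector).
#' @export
wrist_segment <- function(volume, atlas, config = wrist_config(), verbose = FALSE) {
  arr <- as_volume_array(volume)
  sp <- vol_spacing(volume)
  if (!inherits(atlas, "atlas_bundle")) stop("'atlas' must be an atlas_bundle")
  logv <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logv <<- c(logv, line)
    if (verbose) message(line)
    invisible(NULL)
  }
  ov <- attr(config, "overridden")
  if (length(ov) > 0) say("config overrides: %s", paste(ov, collapse = ", "))
  wl <- wrist_labels()
  stages <- list()

  atlas <- tryCatch(orient_atlas(atlas, config$orientation),
                    error = function(e) stop_stage("atlas", e, stages))

  # ---- hand mask ----------------------------------------------------------
  stages$mask <- tryCatch({
    pm <- mask_params(config$i_low, config$i_high, config$smooth_box, config$box)
    th <- select_mask_threshold(arr, pm)
    say("mask: TH = %d", th)
    hmask <- build_hand_mask(arr, th, pm)
    list(th = th, mask = hmask, background = background_marker(hmask))
  }, error = function(e) stop_stage("mask", e, stages))

  relief <- gradient_magnitude(arr)
  th_me <- max_entropy_threshold(intensity_histogram(arr))
  say("global: TH_ME = %d", th_me)

  # ---- radius / ulna ------------------------------------------------------
  stages$radioulnar <- tryCatch({
    prof <- axial_profile(arr, stages$mask$mask)
    z_ru <- tryCatch(
      select_radioulnar_slice(prof, config$min_rel_depth, config$max_dist_frac),
      error = function(e) {
        say("radioulnar: classifier failed (%s); falling back to the global profile maximum",
            conditionMessage(e))
        which.max(as.numeric(prof))
      })
    say("radioulnar: slice z = %d", z_ru)
    ms <- config$marker_override$radioulnar
    if (is.null(ms)) {
      fixed <- arr[, , z_ru]
      chain <- register_images(fixed, atlas$ru$image,
                               stages = config$registration$stages,
                               control = config$registration$control)
      say("radioulnar: registration metric %s",
          paste(sprintf("%s=%.1f", names(chain$metrics), chain$metrics), collapse = " "))
      grays <- lapply(atlas$ru$markers, propagate_markers, chain = chain)
      cand <- binarize_candidates(Reduce(pmax, grays), config$marker_threshold_ru,
                                  config$components_ru)
      cc <- connected_components(cand)
      comps <- lapply(seq_along(cc$sizes), function(l) cc$labels == l)
      named <- match_markers(comps, grays)
      obj <- lapply(named, function(m2d) {
        seed <- marker_com_pixel(m2d)
        grow_marker(arr, c(seed, z_ru), config$depth_slices, "proximal")$marker
      })
      ms <- assemble_markers(obj, stages$mask$background)
    } else say("radioulnar: using user-supplied marker override")
    seg <- segment_stage(arr, ms, relief = relief,
                         dilation_half = config$dilation_half)
    glab <- relabel_global(seg, wl)
    say("radioulnar: segmented %s", paste(attr(seg, "bones"), collapse = ", "))
    list(slice = z_ru, markers = ms, labels = glab)
  }, error = function(e) stop_stage("radioulnar", e, stages))

  # ---- metacarpal bases ---------------------------------------------------
  stages$metacarpal <- tryCatch({
    z_mc <- select_metacarpal_slice(wrist_volume(arr, sp), th_me, config$buffer,
                                    config$n_keep, config$x_th_frac)
    say("metacarpal: slice z = %d (%d clusters kept)", z_mc,
        nrow(attr(z_mc, "clusters")))
    ms <- config$marker_override$metacarpal
    if (is.null(ms)) {
      fixed <- arr[, , z_mc]
      chain <- register_images(fixed, atlas$mc$image,
                               stages = config$registration$stages,
                               control = config$registration$control)
      say("metacarpal: registration metric %s",
          paste(sprintf("%s=%.1f", names(chain$metrics), chain$metrics), collapse = " "))
      grays <- lapply(atlas$mc$markers, propagate_markers, chain = chain)
      cand <- binarize_candidates(Reduce(pmax, grays), config$marker_threshold_mc,
                                  config$components_mc)
      cc <- connected_components(cand)
      comps <- lapply(seq_along(cc$sizes), function(l) cc$labels == l)
      named <- match_markers(comps, grays)
      obj <- lapply(named, function(m2d) {
        seed <- central_pixel(m2d)
        grow_marker(arr, c(seed, z_mc), config$depth_slices, "distal")$marker
      })
      ms <- assemble_markers(obj, stages$mask$background)
    } else say("metacarpal: using user-supplied marker override")
    seg <- segment_stage(arr, ms, relief = relief,
                         dilation_half = config$dilation_half)
    glab <- relabel_global(seg, wl)
    say("metacarpal: segmented %s", paste(attr(seg, "bones"), collapse = ", "))
    list(slice = as.integer(z_mc), markers = ms, labels = glab)
  }, error = function(e) stop_stage("metacarpal", e, stages))

  # ---- carpals ------------------------------------------------------------
  stages$carpal <- tryCatch({
    region <- carpal_region(stages$radioulnar$labels, stages$metacarpal$labels,
                            stages$mask$mask)
    say("carpal: region of %d voxels", sum(region))
    ms <- config$marker_override$carpal
    if (is.null(ms)) {
      reg_mask <- attr(region, "unclipped")
      if (is.null(reg_mask)) reg_mask <- region
      bb <- crop_box(reg_mask, dim(arr), margin = 2L)
      fixed <- (arr * reg_mask)[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
      chain <- register_images(fixed, atlas$carpal$image,
                               stages = config$registration$stages,
                               control = config$registration$control)
      say("carpal: registration metric %s",
          paste(sprintf("%s=%.1f", names(chain$metrics), chain$metrics), collapse = " "))
      grays_c <- lapply(atlas$carpal$markers, propagate_markers, chain = chain)
      grays <- lapply(grays_c, uncrop, dims = dim(arr), box = bb)
      cand <- binarize_candidates(Reduce(pmax, grays), config$marker_threshold_carpal,
                                  config$components_carpal)
      obj <- finalize_carpal_markers(cand, arr, th_me, config$buffer,
                                     reference = grays, k = config$components_carpal)
      ms <- assemble_markers(obj, background = !region & !Reduce(`|`, obj))
    } else say("carpal: using user-supplied marker override")
    seg <- segment_stage(arr, ms, region = region, relief = relief,
                         dilation_half = config$dilation_half)
    glab <- relabel_global(seg, wl)
    say("carpal: segmented %s", paste(attr(seg, "bones"), collapse = ", "))
    list(region = region, markers = ms, labels = glab)
  }, error = function(e) stop_stage("carpal", e, stages))

  # ---- merge --------------------------------------------------------------
  merged <- stages$radioulnar$labels
  for (st in list(stages$metacarpal$labels, stages$carpal$labels)) {
    conflict <- merged > 0L & st > 0L
    if (any(conflict))
      say("merge: %d voxels claimed by two stages; earlier stage kept", sum(conflict))
    free <- merged == 0L & st > 0L
    merged[free] <- st[free]
  }
  say("merge: %d bone labels present", length(unique(merged[merged > 0L])))
  structure(list(labels = merged, stages = stages, log = logv,
                 spacing = sp, config = config),
            class = "wrist_segmentation")
}

# map a stage label array (1..K in marker order, names in attr 'bones')
# onto the global 15-bone labels
relabel_global <- function(seg, wl) {
  bones <- attr(seg, "bones")
  out <- array(0L, dim = dim(seg))
  for (i in seq_along(bones)) {
    g <- wl$label[wl$code == bones[i]]
    if (length(g) == 1L) out[seg == i] <- g
  }
  out
}

crop_box <- function(mask, dims, margin = 2L) {
  bb <- bbox_union(mask, mask)
  lapply(seq_along(bb), function(i) {
    r <- range(bb[[i]])
    max(1L, r[1] - margin):min(dims[i], r[2] + margin)
  })
}

uncrop <- function(a, dims, box) {
  out <- array(0, dim = dims)
  out[box[[1]], box[[2]], box[[3]]] <- a
  out
}

#' @export
print.wrist_segmentation <- function(x, ...) {
  wl <- wrist_labels()
  present <- wl$code[wl$label %in% unique(x$labels[x$labels > 0L])]
  cat(sprintf("<wrist_segmentation> %s voxels; %d/15 bones: %s\n",
              paste(dim(x$labels), collapse = "x"), length(present),
              paste(present, collapse = " ")))
  invisible(x)
}

#' @export
summary.wrist_segmentation <- function(object, ...) {
  wl <- wrist_labels()
  sizes <- vapply(wl$label, function(l) sum(object$labels == l), numeric(1))
  df <- data.frame(label = wl$label, code = wl$code, group = wl$group,
                   voxels = as.integer(sizes))
  cat("Bone sizes (voxels):\n")
  print(df, row.names = FALSE)
  invisible(df)
}
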