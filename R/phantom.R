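#' Synthetic wrist-phantom specification
#'
#' The phantom emulates the structures the segmentation pipeline depends on
#' in a low-field T1-weighted wrist volume: a dark air background, an
#' elliptic soft-tissue "hand" wrapped in a bright skin shell, and 15 bone
#' bodies -- two proximal rods with ellipsoidal distal caps (radius, ulna)
#' separated from the carpal cluster by a dark joint gap of about 10 slices,
#' eight carpal ellipsoids in two in-plane rows, and five distal metacarpal
#' bars -- each made of a bright marrow core wrapped in a one-voxel dark
#' cortical shell. Skin and marrow deliberately share an intensity band:
#' soft tissues imaged in the same range as bone interiors are the central
#' difficulty of low-field wrist MR, so the phantom reproduces it.
#'
#' Intensity means/sds (16-bit units) are calibrated once so that (a) the
#' background/tissue histogram valley falls inside the mask-threshold search
#' range [200, 500], and (b) the maximum-entropy threshold plus the 200-unit
#' buffer separates soft tissue from marrow.
#'
#' @param shape grid size `c(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param seed integer random seed (geometry jitter + noise).
#' @param intensities named list of `c(mean, sd)` pairs for `background`,
#'   `cortical`, `soft`, `skin`, `marrow`.
#' @param handedness `"right"` or `"left"` (left mirrors the x axis).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160L, 160L, 120L),
                         spacing = c(0.75, 0.75, 0.7),
                         seed = 1L,
                         intensities = list(background = c(100, 25),
                                            cortical = c(250, 25),
                                            soft = c(450, 30),
                                            skin = c(880, 45),
                                            marrow = c(900, 45)),
                         handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 48L))
  mu <- vapply(intensities, `[`, numeric(1), 1)
  if (!(mu["background"] < mu["cortical"] && mu["cortical"] < mu["soft"] &&
        mu["soft"] < mu["marrow"]))
    stop("intensity means must be ordered background < cortical < soft < marrow")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 seed = as.integer(seed), intensities = intensities,
                 handedness = handedness),
            class = "phantom_spec")
}

#' Generate a synthetic wrist phantom
#'
#' Deterministic given the spec's seed. Returns the noisy 16-bit volume and
#' the ground-truth 15-bone label map (marrow plus cortical shell per bone;
#' labels follow [wrist_labels]).
#'
#' @param spec a [phantom_spec].
#' @return list of class `wrist_phantom`: `volume` (a [wrist_volume]),
#'   `labels` (integer array), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  geo <- phantom_geometry(nx, ny, nz)
  N <- nx * ny * nz
  idx <- seq_len(N) - 1L
  X <- idx %% nx + 1L
  Y <- (idx %/% nx) %% ny + 1L
  Z <- idx %/% (nx * ny) + 1L

  # hand and skin
  r2 <- ((X - geo$cx) / geo$hand_ax)^2 + ((Y - geo$cy) / geo$hand_ay)^2
  hand <- r2 <= 1
  r2i <- ((X - geo$cx) / (geo$hand_ax - geo$skin_th))^2 +
         ((Y - geo$cy) / (geo$hand_ay - geo$skin_th))^2
  skin <- hand & r2i > 1

  # Each bone is built as a marrow core (the stated size minus one voxel)
  # plus its unit-diamond dilation ring as the cortical shell, so the shell
  # is exactly one voxel thick in the city-block metric everywhere.
  labels <- array(0L, dim = spec$shape)
  marrow <- array(FALSE, dim = spec$shape)
  for (b in geo$bones) {
    core <- switch(b$type,
      rod = {
        rz <- pmax(b$radius_of_z - 1, 0)  # per-slice body radius minus shell
        rz_ok <- b$radius_of_z > 0
        (X - b$x)^2 + (Y - b$y)^2 <= rz[Z]^2 & rz_ok[Z]
      },
      blob = ((X - b$x) / max(b$ax - 1, 0.5))^2 +
             ((Y - b$y) / max(b$ay - 1, 0.5))^2 +
             ((Z - b$z) / max(b$az - 1, 0.5))^2 <= 1
    )
    core <- array(core, dim = spec$shape)
    body <- morph(core, "dilate", "diamond", 1L)
    if (any(labels[body] != 0L))
      stop("phantom bone bodies overlap under this spec")
    labels[body] <- b$label
    marrow <- marrow | core
  }
  fg <- labels > 0L
  if (length(connected_components(fg, "full")$sizes) != length(geo$bones))
    stop("phantom bone bodies are not separated by at least one voxel")

  ints <- spec$intensities
  mean_map <- array(ints$background[1], dim = spec$shape)
  sd_map <- array(ints$background[2], dim = spec$shape)
  assign_tissue <- function(sel, p) { mean_map[sel] <<- p[1]; sd_map[sel] <<- p[2] }
  assign_tissue(array(hand, dim = spec$shape), ints$soft)
  assign_tissue(array(skin, dim = spec$shape), ints$skin)
  assign_tissue(fg, ints$cortical)
  assign_tissue(marrow, ints$marrow)

  vol <- mean_map + sd_map * stats::rnorm(N)
  vol <- array(pmin(pmax(round(vol), 0), 65535), dim = spec$shape)
  storage.mode(vol) <- "integer"

  if (spec$handedness == "left") {
    vol <- vol[nx:1, , , drop = FALSE]
    labels <- labels[nx:1, , , drop = FALSE]
  }
  structure(list(volume = wrist_volume(vol, spec$spacing),
                 labels = labels, spec = spec),
            class = "wrist_phantom")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.wrist_phantom <- function(x, ...) {
  cat(sprintf("<wrist_phantom> %s voxels, seed %d, %s hand, %d bones\n",
              paste(x$spec$shape, collapse = "x"), x$spec$seed,
              x$spec$handedness, length(unique(x$labels[x$labels > 0]))))
  invisible(x)
}

# Bone layout in voxel units; fractions of the grid keep the layout
# consistent across phantom sizes. Jitter (positions about +-1 voxel,
# sizes +-4%) uses the current RNG stream.
phantom_geometry <- function(nx, ny, nz) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  jit <- function(s = 1) stats::runif(1, -s, s)
  jsz <- function() stats::runif(1, 0.96, 1.04)
  z_mc <- round(0.30 * nz)            # metacarpal bars: slices 1..z_mc
  z_ru <- round(0.80 * nz)            # radius/ulna: z_ru..nz
  z_pk <- round(0.84 * nz)            # largest radioulnar cross section
  bones <- list()
  rod <- function(label, x, y, rmax) {
    rz <- numeric(nz)
    for (z in seq(z_ru, nz)) {
      rz[z] <- if (z < z_pk)
        rmax * sqrt(max(0, 1 - ((z_pk - z) / (z_pk - z_ru + 0.5))^2))
      else rmax * (1 - 0.20 * (z - z_pk) / max(nz - z_pk, 1))
    }
    list(type = "rod", label = label, x = x, y = y, radius_of_z = rz)
  }
  bar <- function(label, x, y, r0) {
    rz <- numeric(nz)
    for (z in seq_len(z_mc)) rz[z] <- r0 * (0.85 + 0.30 * z / z_mc)
    list(type = "rod", label = label, x = x, y = y, radius_of_z = rz)
  }
  bones[[1]] <- rod(1L, cx - 0.125 * nx + jit(), cy + jit(), 0.105 * nx * jsz())
  bones[[2]] <- rod(2L, cx + 0.125 * nx + jit(), cy + jit(), 0.093 * nx * jsz())
  mc_dx <- c(-0.285, -0.1425, 0, 0.1425, 0.285) * nx
  mc_dy <- c(-0.02, 0.01, 0.02, 0.01, -0.02) * ny
  for (i in 1:5)
    bones[[2L + i]] <- bar(2L + i, cx + mc_dx[i] + jit(0.8), cy + mc_dy[i] + jit(),
                           0.048 * nx * stats::runif(1, 0.97, 1.03))
  # outer carpal columns sit closer in (and slightly smaller, like the
  # pisiform/trapezium) so the whole carpus stays medial to the lateral
  # tangent planes through ulna+M5 and radius+M1
  carp_dx <- c(-0.20, -0.07, 0.07, 0.20) * nx
  carp_ax <- c(0.052, 0.058, 0.058, 0.052) * nx
  for (i in 1:4)  # proximal row: scaphoid, lunate, triquetrum, pisiform
    bones[[7L + i]] <- list(type = "blob", label = 7L + i,
                            x = cx + carp_dx[i] + jit(0.5), y = cy - 0.085 * ny + jit(0.8),
                            ax = carp_ax[i] * jsz(), ay = 0.062 * ny * jsz(),
                            az = 0.068 * nz * jsz(), z = 0.62 * nz + jit(0.8))
  for (i in 1:4)  # distal row: trapezium, trapezoid, capitate, hamate
    bones[[11L + i]] <- list(type = "blob", label = 11L + i,
                             x = cx + carp_dx[i] + jit(0.5), y = cy + 0.085 * ny + jit(0.8),
                             ax = carp_ax[i] * jsz(), ay = 0.062 * ny * jsz(),
                             az = 0.100 * nz * jsz(), z = 0.585 * nz + jit(0.8))
  list(cx = cx, cy = cy, hand_ax = 0.40 * nx, hand_ay = 0.32 * ny,
       skin_th = 3, z_mc = z_mc, z_ru = z_ru, z_pk = z_pk, bones = bones)
}

#' Derive an atlas bundle from a phantom
#'
#' Applies a smooth random free-form warp (control-grid displacements,
#' multilinear interpolation) plus a small intensity gain jitter to a
#' phantom, then extracts the pieces an atlas bundle needs: the radioulnar
#' and metacarpal axial cross sections at the slices of largest bone
#' cross-sectional area, the 3D carpal region (masked outside the region,
#' cropped to its bounding box), and binary marker images (ground-truth
#' labels eroded inward, foreground value 255, the 8-bit convention that
#' makes the carpal gray threshold of 240 meaningful).
#'
#' @param phantom a `wrist_phantom`.
#' @param warp_amplitude control-point displacement sd in voxels.
#' @param seed RNG seed for the warp and jitter.
#' @return list of class `atlas_bundle` with elements `ru`, `mc`, `carpal`,
#'   `orientation`, `spacing`.
#' @export
derive_atlas <- function(phantom, warp_amplitude = 2, seed = 1L) {
  stopifnot(inherits(phantom, "wrist_phantom"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  shp <- dim(phantom$labels)
  d3 <- as.integer(shp)
  gdim <- c(5L, 5L, 5L)
  ctrl <- array(stats::rnorm(prod(gdim) * 3, 0, warp_amplitude), dim = c(gdim, 3L))
  check_warp_jacobian(ctrl, gdim, d3)
  A <- diag(3); tv <- c(0, 0, 0); ctr <- (d3 - 1) / 2
  warp_img <- function(img, nearest) {
    array(cpp_warp(as.numeric(img), d3, d3, as.numeric(A), tv, ctr,
                   as.numeric(ctrl), gdim, nearest), dim = shp)
  }
  vol_w <- warp_img(phantom$volume$data, 0L)
  gain <- 1 + stats::rnorm(1, 0, 0.02)
  vol_w <- vol_w * gain + stats::rnorm(length(vol_w), 0, 10)
  vol_w <- array(pmin(pmax(round(vol_w), 0), 65535), dim = shp)
  storage.mode(vol_w) <- "integer"
  lab_w <- array(as.integer(round(warp_img(phantom$labels, 1L))), dim = shp)

  wl <- wrist_labels()
  slice_markers <- function(z, labs, half) {
    out <- list()
    for (l in labs) {
      m <- lab_w[, , z] == l
      h <- half
      er <- morph(m, "erode", "diamond", h)
      while (!any(er) && h > 0) { h <- h - 1L; er <- morph(m, "erode", "diamond", h) }
      out[[wl$code[wl$label == l]]] <- array(255 * er, dim = dim(m))
    }
    out
  }
  area <- function(labs) vapply(seq_len(shp[3]), function(z)
    sum(lab_w[, , z] %in% labs), numeric(1))
  z_ru <- which.max(area(1:2))
  z_mc <- which.max(area(3:7))
  ru <- list(image = vol_w[, , z_ru], markers = slice_markers(z_ru, 1:2, 2L), z = z_ru)
  mc <- list(image = vol_w[, , z_mc], markers = slice_markers(z_mc, 3:7, 1L), z = z_mc)

  # carpal region of the warped phantom, from its own (warped) ground truth
  th <- select_mask_threshold(vol_w)
  hmask <- build_hand_mask(vol_w, th)
  ur_lab <- array(ifelse(lab_w %in% 1:2, lab_w, 0L), dim = shp)
  mc_lab <- array(ifelse(lab_w %in% 3:7, lab_w, 0L), dim = shp)
  region <- carpal_region(ur_lab, mc_lab, hmask)
  reg_mask <- attr(region, "unclipped")
  if (is.null(reg_mask)) reg_mask <- region
  bb <- bbox_union(reg_mask, reg_mask)
  bb <- lapply(seq_along(bb), function(i) {
    r <- range(bb[[i]]); max(1L, r[1] - 2L):min(shp[i], r[2] + 2L)
  })
  carp_img <- vol_w * reg_mask
  carp_img <- carp_img[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  carp_markers <- list()
  for (l in 8:15) {
    m <- lab_w == l
    er <- morph(m, "erode", "diamond", 1L)
    if (!any(er)) er <- m
    carp_markers[[wl$code[wl$label == l]]] <-
      array(255 * er, dim = shp)[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  }
  structure(list(
    ru = ru, mc = mc,
    carpal = list(image = carp_img, markers = carp_markers,
                  offset = vapply(bb, function(r) r[1], integer(1)),
                  region = region),
    orientation = phantom$spec$handedness,
    spacing = phantom$spec$spacing, shape = shp
  ), class = "atlas_bundle")
}

# sampled finite-difference Jacobian of x + U(x); folding (det <= 0) aborts
check_warp_jacobian <- function(ctrl, gdim, d3) {
  gs <- (d3 - 1) / (gdim - 1)
  xs <- seq(1, d3[1] - 1, by = max(1, floor(gs[1] / 2)))
  ys <- seq(1, d3[2] - 1, by = max(1, floor(gs[2] / 2)))
  zs <- seq(1, d3[3] - 1, by = max(1, floor(gs[3] / 2)))
  U <- function(p) vapply(1:3, function(comp)
    interp_lin(as.numeric(ctrl[, , , comp]), gdim, p[1] / gs[1], p[2] / gs[2],
               p[3] / gs[3]), numeric(1))
  for (x in xs) for (y in ys) for (z in zs) {
    p <- c(x, y, z)
    J <- diag(3)
    for (a in 1:3) {
      e <- c(0, 0, 0); e[a] <- 1
      J[, a] <- J[, a] + (U(p + e) - U(p - e)) / 2
    }
    if (det(J) <= 0)
      stop("warp folds the grid (non-positive Jacobian); lower warp_amplitude")
  }
  invisible(TRUE)
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s hand; radioulnar slice z=%d, metacarpal slice z=%d\n",
              x$orientation, x$ru$z, x$mc$z))
  cat(sprintf("  carpal region %s voxels at offset (%s)\n",
              paste(dim(x$carpal$image), collapse = "x"),
              paste(x$carpal$offset, collapse = ", ")))
  invisible(x)
}

#' Flip an atlas bundle to match the case orientation
#'
#' When the case and atlas handedness differ, all atlas and marker images
#' are mirrored along x; otherwise the bundle is returned unchanged.
#'
#' @param bundle an `atlas_bundle`.
#' @param case_orientation `"right"` or `"left"`.
#' @return the (possibly flipped) bundle.
#' @export
orient_atlas <- function(bundle, case_orientation) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (!case_orientation %in% c("right", "left"))
    stop("unknown case orientation: ", case_orientation)
  if (is.null(bundle$orientation) || !bundle$orientation %in% c("right", "left"))
    stop("atlas bundle has an unknown orientation tag")
  if (bundle$orientation == case_orientation) return(bundle)
  fx <- function(a) {
    if (is.matrix(a)) a[nrow(a):1, , drop = FALSE]
    else a[dim(a)[1]:1, , , drop = FALSE]
  }
  bundle$ru$image <- fx(bundle$ru$image)
  bundle$ru$markers <- lapply(bundle$ru$markers, fx)
  bundle$mc$image <- fx(bundle$mc$image)
  bundle$mc$markers <- lapply(bundle$mc$markers, fx)
  bundle$carpal$image <- fx(bundle$carpal$image)
  bundle$carpal$markers <- lapply(bundle$carpal$markers, fx)
  if (!is.null(bundle$carpal$region)) bundle$carpal$region <- fx(bundle$carpal$region)
  # mirrored crop offset relative to the (mirrored) full grid
  bundle$carpal$offset[1] <-
    bundle$shape[1] - (bundle$carpal$offset[1] + dim(bundle$carpal$image)[1] - 1L) + 1L
  bundle$orientation <- case_orientation
  bundle
}

#' Write / read an atlas bundle
#'
#' The bundle directory holds NIfTI images for the atlas slices, the carpal
#' volume and every marker image, plus a `manifest.json` with orientation,
#' spacing, slice indices and the marker label table.
#'
#' @param bundle an `atlas_bundle`.
#' @param dir directory (created if needed).
#' @return `dir` (write) or the restored bundle (read).
#' @export
write_atlas <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as3 <- function(a) if (is.matrix(a)) array(a, dim = c(dim(a), 1L)) else a
  wv <- function(a, nm) {
    img <- RNifti::asNifti(array(as.numeric(as3(a)), dim = dim(as3(a))))
    RNifti::pixdim(img) <- bundle$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  wv(bundle$ru$image, "ru_image"); wv(bundle$mc$image, "mc_image")
  wv(bundle$carpal$image, "carpal_image")
  wv(bundle$carpal$region * 1L, "carpal_region")
  for (nm in names(bundle$ru$markers)) wv(bundle$ru$markers[[nm]], paste0("ru_marker_", nm))
  for (nm in names(bundle$mc$markers)) wv(bundle$mc$markers[[nm]], paste0("mc_marker_", nm))
  for (nm in names(bundle$carpal$markers)) wv(bundle$carpal$markers[[nm]], paste0("carpal_marker_", nm))
  jsonlite::write_json(list(orientation = bundle$orientation,
                            spacing = bundle$spacing, shape = bundle$shape,
                            ru_z = bundle$ru$z, mc_z = bundle$mc$z,
                            carpal_offset = bundle$carpal$offset,
                            ru_markers = names(bundle$ru$markers),
                            mc_markers = names(bundle$mc$markers),
                            carpal_markers = names(bundle$carpal$markers)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not an atlas bundle: missing manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("orientation", "spacing", "shape", "ru_z", "mc_z", "carpal_offset")
  if (!all(need %in% names(man)))
    stop("corrupted atlas manifest: missing fields ",
         paste(setdiff(need, names(man)), collapse = ", "))
  rv <- function(nm, as2d = FALSE) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    d3 <- dim(img)
    if (length(d3) == 2L) d3 <- c(d3, 1L)
    a <- array(as.integer(round(as.vector(img))), dim = d3[1:3])
    if (as2d) a[, , 1] else a
  }
  rl <- function(prefix, nms, as2d) {
    out <- lapply(nms, function(nm) rv(paste0(prefix, nm), as2d))
    stats::setNames(out, nms)
  }
  structure(list(
    ru = list(image = rv("ru_image", TRUE),
              markers = rl("ru_marker_", man$ru_markers, TRUE), z = man$ru_z),
    mc = list(image = rv("mc_image", TRUE),
              markers = rl("mc_marker_", man$mc_markers, TRUE), z = man$mc_z),
    carpal = list(image = rv("carpal_image"),
                  markers = rl("carpal_marker_", man$carpal_markers, FALSE),
                  offset = as.integer(man$carpal_offset),
                  region = rv("carpal_region") > 0),
    orientation = man$orientation, spacing = as.numeric(man$spacing),
    shape = as.integer(man$shape)
  ), class = "atlas_bundle")
}
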