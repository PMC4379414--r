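#' Register a moving image onto a fixed image
#'
#' Stagewise intensity-based registration driven by the mean-squared
#' image-to-image metric with linear interpolation, in the spirit of the ITK
#' registration framework: a rigid transform (rotation + translation, about
#' the fixed-image centre, initialized by centre-of-mass alignment), then a
#' full affine transform, then a coarse-grid and a fine-grid free-form
#' deformation (multilinear displacement interpolation from a control-point
#' grid spanning the fixed domain; the fine grid is initialized by
#' upsampling the coarse one). Each stage starts from the previous stage's
#' result. Rigid and affine stages use derivative-free / quasi-Newton
#' optimization; the deformation stages use regular-step gradient descent
#' with an analytic metric gradient.
#'
#' The resulting chain maps fixed-image voxel coordinates to moving-image
#' coordinates, which is the direction needed to resample the moving image
#' (or its marker images) onto the fixed grid.
#'
#' @param fixed,moving numeric 2D matrices or 3D arrays of the same rank.
#' @param stages character vector, a subset of
#'   `c("rigid", "affine", "ffd_coarse", "ffd_fine")` in that order.
#' @param control list of settings: `coarse_grid` and `fine_grid`
#'   (control points per axis; defaults 4 and 8), `max_iter` (per-stage
#'   iteration cap, default 200), `tol` (relative metric tolerance, 1e-4),
#'   `pyramid` (number of resolution levels for the rigid/affine stages;
#'   default 2 for 3D, 1 for 2D; 1 disables the pyramid), `step` (initial
#'   FFD step in voxels, default 1).
#' @return object of class `transform_chain`: list with the affine part
#'   (`A`, `t`, `center`), optional control-grid displacements (`ctrl`,
#'   `gdim`), the fixed/moving dims, and the per-stage metric values
#'   (`metrics`, including `identity`).
#' @export
register_images <- function(fixed, moving,
                            stages = c("rigid", "affine", "ffd_coarse", "ffd_fine"),
                            control = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  f <- as_reg_array(fixed); m <- as_reg_array(moving)
  if (length(dim(f)) != length(dim(m)))
    stop("fixed and moving images must have the same rank (2D-2D or 3D-3D)")
  if (stats::sd(f) == 0 || stats::sd(m) == 0)
    stop("degenerate (constant) image: registration metric is uninformative")
  d <- if (is.matrix(f)) 2L else 3L
  ctl <- reg_control(control, d)
  center <- (dims3(f)[1:d] - 1) / 2
  # centre-of-mass initialization of the translation
  t0 <- com(m)[1:d] - com(f)[1:d]
  A <- diag(d); tv <- t0
  metrics <- c(identity = mse_of(f, m, diag(d), rep(0, d), center))
  if ("rigid" %in% stages) {
    res <- fit_rigid(f, m, center, tv, ctl)
    A <- res$A; tv <- res$t
    metrics["rigid"] <- res$mse
  }
  if ("affine" %in% stages) {
    res <- fit_affine(f, m, center, A, tv, ctl)
    A <- res$A; tv <- res$t
    metrics["affine"] <- res$mse
  }
  ctrl <- NULL; gdim <- NULL
  if ("ffd_coarse" %in% stages) {
    gdim <- rep(ctl$coarse_grid, d)
    ctrl <- array(0, dim = c(gdim, d))
    res <- fit_ffd(f, m, center, A, tv, ctrl, gdim, ctl)
    ctrl <- res$ctrl
    metrics["ffd_coarse"] <- res$mse
  }
  if ("ffd_fine" %in% stages) {
    gdim_f <- rep(ctl$fine_grid, d)
    ctrl <- if (is.null(ctrl)) array(0, dim = c(gdim_f, d))
            else upsample_grid(ctrl, gdim, gdim_f, d)
    gdim <- gdim_f
    res <- fit_ffd(f, m, center, A, tv, ctrl, gdim, ctl)
    ctrl <- res$ctrl
    metrics["ffd_fine"] <- res$mse
  }
  structure(list(dim = d, A = A, t = tv, center = center,
                 ctrl = ctrl, gdim = gdim,
                 fdim = dim(f), mdim = dim(m), metrics = metrics),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %dD, stages: %s\n", x$dim,
              paste(setdiff(names(x$metrics), "identity"), collapse = " -> ")))
  cat("  mean-squares metric by stage:\n")
  print(signif(x$metrics, 5))
  invisible(x)
}

as_reg_array <- function(x) {
  a <- as_volume_array_2d3d(x)
  storage.mode(a) <- "double"
  a
}

dims3 <- function(a) {
  d <- dim(a)
  as.integer(if (length(d) == 2L) c(d, 1L) else d)
}

com <- function(a) {
  d3 <- dims3(a)
  w <- as.numeric(a); s <- sum(w)
  if (s <= 0) return((d3 - 1) / 2)
  idx <- seq_along(w) - 1L
  x <- idx %% d3[1]; y <- (idx %/% d3[1]) %% d3[2]; z <- idx %/% (d3[1] * d3[2])
  c(sum(w * x), sum(w * y), sum(w * z)) / s
}

reg_control <- function(control, d) {
  defaults <- list(coarse_grid = 4L, fine_grid = 8L, max_iter = 200L,
                   tol = 1e-4, pyramid = if (d == 3L) 2L else 1L,
                   step = 1.0, min_step = 0.01,
                   stride = if (d == 3L) 2L else 1L,
                   affine_maxit = 60L)
  defaults[names(control)] <- control
  defaults
}

mse_of <- function(f, m, A, tv, center, ctrl = NULL, gdim = NULL, stride = 1L) {
  cpp_mse(as.numeric(f), as.numeric(m), dims3(m), dims3(f),
          as.numeric(A), as.numeric(tv), as.numeric(center),
          if (is.null(ctrl)) numeric(0) else as.numeric(ctrl),
          if (is.null(gdim)) integer(0) else as.integer(gdim),
          as.integer(stride))
}

rot_matrix <- function(angles, d) {
  if (d == 2L) {
    th <- angles[1]
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else {
    cx <- cos(angles[1]); sx <- sin(angles[1])
    cy <- cos(angles[2]); sy <- sin(angles[2])
    cz <- cos(angles[3]); sz <- sin(angles[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
}

# block-mean downsampling by 2 along every axis (odd tails folded in)
downsample2 <- function(a) {
  d3 <- dims3(a)
  n <- pmax(d3 %/% 2L, 1L)
  out <- array(0, dim = n); cnt <- array(0, dim = n)
  idx <- which(array(TRUE, dim = d3), arr.ind = TRUE)
  tgt <- pmin((idx - 1L) %/% 2L + 1L, matrix(n, nrow(idx), 3, byrow = TRUE))
  lin <- tgt[, 1] + n[1] * (tgt[, 2] - 1L) + n[1] * n[2] * (tgt[, 3] - 1L)
  sums <- rowsum(as.numeric(a), lin)
  cnts <- rowsum(rep(1, length(a)), lin)
  out[as.integer(rownames(sums))] <- sums / cnts
  if (d3[3] == 1L) matrix(out, n[1], n[2]) else array(out, dim = n)
}

fit_rigid <- function(f, m, center, t0, ctl) {
  d <- if (is.matrix(f)) 2L else 3L
  nang <- if (d == 2L) 1L else 3L
  levels <- max(1L, ctl$pyramid)
  # resolution pyramids, coarsest first
  fs <- list(); ms <- list(); fc <- f; mc <- m
  for (l in seq_len(levels)) { fs[[levels - l + 1L]] <- fc; ms[[levels - l + 1L]] <- mc
                               if (l < levels) { fc <- downsample2(fc); mc <- downsample2(mc) } }
  par <- c(rep(0, nang), t0 / 2^(levels - 1L))
  for (l in seq_len(levels)) {
    fl <- fs[[l]]; ml <- ms[[l]]
    cl <- center / 2^(levels - l)
    obj <- function(p) {
      A <- rot_matrix(p[seq_len(nang)], d)
      mse_of(fl, ml, A, p[nang + seq_len(d)], cl, stride = ctl$stride)
    }
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 150L * length(par),
                                       reltol = 1e-9,
                                       parscale = c(rep(0.02, nang), rep(1, d))))
    par <- opt$par
    if (l < levels) par[nang + seq_len(d)] <- par[nang + seq_len(d)] * 2
  }
  A <- rot_matrix(par[seq_len(nang)], d)
  tv <- par[nang + seq_len(d)]
  list(A = A, t = tv, mse = mse_of(f, m, A, tv, center))
}

fit_affine <- function(f, m, center, A0, t0, ctl) {
  d <- if (is.matrix(f)) 2L else 3L
  par <- c(as.numeric(A0), t0)
  obj <- function(p) {
    A <- matrix(p[seq_len(d * d)], d, d)
    mse_of(f, m, A, p[d * d + seq_len(d)], center, stride = ctl$stride)
  }
  opt <- stats::optim(par, obj, method = "BFGS",
                      control = list(maxit = ctl$affine_maxit, reltol = 1e-9,
                                     parscale = c(rep(0.01, d * d), rep(1, d))))
  A <- matrix(opt$par[seq_len(d * d)], d, d)
  tv <- opt$par[d * d + seq_len(d)]
  m0 <- mse_of(f, m, A0, t0, center, stride = ctl$stride)
  if (opt$value <= m0) list(A = A, t = tv, mse = mse_of(f, m, A, tv, center))
  else list(A = A0, t = t0, mse = mse_of(f, m, A0, t0, center))  # keep the better stage
}

# regular-step gradient descent on the control displacements
fit_ffd <- function(f, m, center, A, tv, ctrl, gdim, ctl) {
  fv <- as.numeric(f); mv <- as.numeric(m)
  md <- dims3(m); fd <- dims3(f)
  cur <- as.numeric(ctrl)
  g <- cpp_ffd_mse_grad(fv, mv, md, fd, as.numeric(A), as.numeric(tv),
                        as.numeric(center), cur, as.integer(gdim),
                        as.integer(ctl$stride))
  mse <- g$mse
  step <- ctl$step
  for (it in seq_len(ctl$max_iter)) {
    gn <- g$grad
    gmax <- max(abs(gn))
    if (gmax == 0) break
    cand <- cur - step * gn / gmax
    mse_new <- cpp_mse(fv, mv, md, fd, as.numeric(A), as.numeric(tv),
                       as.numeric(center), cand, as.integer(gdim),
                       as.integer(ctl$stride))
    if (mse_new < mse) {
      improved <- (mse - mse_new) / max(mse, .Machine$double.eps)
      cur <- cand
      g <- cpp_ffd_mse_grad(fv, mv, md, fd, as.numeric(A), as.numeric(tv),
                            as.numeric(center), cur, as.integer(gdim),
                            as.integer(ctl$stride))
      mse <- g$mse
      if (improved < ctl$tol) break
    } else {
      step <- step / 2
      if (step < ctl$min_step) break
    }
  }
  list(ctrl = array(cur, dim = c(gdim, length(tv))),
       mse = cpp_mse(fv, mv, md, fd, as.numeric(A), as.numeric(tv),
                     as.numeric(center), cur, as.integer(gdim), 1L))
}

# evaluate a coarse control grid at the node positions of a finer grid
upsample_grid <- function(ctrl, gdim, gdim_f, d) {
  out <- array(0, dim = c(gdim_f, d))
  g3 <- c(gdim, rep(1L, 3 - d)); gf3 <- c(gdim_f, rep(1L, 3 - d))
  for (comp in seq_len(d)) {
    src <- as.numeric(if (d == 2L) ctrl[, , comp] else ctrl[, , , comp])
    nodes <- which(array(TRUE, dim = gf3), arr.ind = TRUE) - 1L
    # fine node position in coarse-grid index units
    pos <- sweep(nodes, 2, pmax(gf3 - 1L, 1L), "/")
    pos <- sweep(pos, 2, g3 - 1L, "*")
    vals <- vapply(seq_len(nrow(nodes)), function(i) {
      interp_lin(src, g3, pos[i, 1], pos[i, 2], pos[i, 3])
    }, numeric(1))
    if (d == 2L) out[, , comp] <- vals else out[, , , comp] <- vals
  }
  out
}

# scalar multilinear interpolation, R-side (small grids only)
interp_lin <- function(v, d3, x, y, z) {
  cl <- function(t, n) min(max(t, 0), n - 1)
  x <- cl(x, d3[1]); y <- cl(y, d3[2]); z <- cl(z, d3[3])
  x0 <- min(floor(x), max(d3[1] - 2, 0)); y0 <- min(floor(y), max(d3[2] - 2, 0))
  z0 <- min(floor(z), max(d3[3] - 2, 0))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(X, Y, Z)
    v[1 + min(X, d3[1] - 1) + d3[1] * (min(Y, d3[2] - 1) + d3[2] * min(Z, d3[3] - 1))]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx
  c10 <- at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx
  c01 <- at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx
  c11 <- at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

#' Map an image through a transform chain onto the fixed grid
#'
#' Resamples a moving-space image into the fixed-image space of the chain.
#' Linear interpolation (default) produces gray-valued output from binary
#' marker images, exactly as a resampled marker should be before
#' thresholding; `"nearest"` keeps values discrete.
#'
#' @param image 2D/3D array aligned with the chain's moving image.
#' @param chain a `transform_chain` from [register_images].
#' @param method `"linear"` or `"nearest"`.
#' @return array on the fixed grid.
#' @export
propagate_markers <- function(image, chain, method = c("linear", "nearest")) {
  method <- match.arg(method)
  arr <- as_reg_array(image)
  if (length(dim(arr)) != chain$dim)
    stop("marker image rank does not match the transform chain")
  if (any(dim(arr) != chain$mdim))
    stop("marker image must be aligned voxelwise with the moving image")
  out <- cpp_warp(as.numeric(arr), dims3(arr), as.integer(c(chain$fdim, rep(1L, 3 - chain$dim))),
                  as.numeric(chain$A), as.numeric(chain$t), as.numeric(chain$center),
                  if (is.null(chain$ctrl)) numeric(0) else as.numeric(chain$ctrl),
                  if (is.null(chain$gdim)) integer(0) else as.integer(chain$gdim),
                  if (method == "nearest") 1L else 0L)
  array(out, dim = chain$fdim)
}

#' Threshold propagated markers into candidate masks
#'
#' Foreground is every voxel with gray value at or above `threshold`
#' (`threshold = 1` keeps all nonzero values of an 8-bit marker; 240 keeps
#' only near-full-support regions), after which only the `k` largest
#' connected components are retained.
#'
#' @param gray_markers numeric array of propagated marker values.
#' @param threshold gray threshold.
#' @param k_components number of components to keep (2 radioulnar,
#'   5 metacarpal, 8 carpal).
#' @return logical candidate-marker mask.
#' @export
binarize_candidates <- function(gray_markers, threshold, k_components) {
  m <- array(gray_markers >= threshold, dim = dim(gray_markers))
  if (!any(m)) stop("no marker voxel survives the threshold")
  keep_largest(m, k_components)
}

#' Serialize / restore a transform chain
#'
#' @param chain a `transform_chain`.
#' @param path JSON file.
#' @return `path` (write) or the restored chain (read).
#' @export
write_transform <- function(chain, path) {
  obj <- unclass(chain)
  obj$ctrl <- if (!is.null(obj$ctrl)) list(values = as.numeric(obj$ctrl),
                                           dim = dim(obj$ctrl))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dim
  chain <- list(dim = d, A = matrix(obj$A, d, d), t = obj$t, center = obj$center,
                ctrl = NULL, gdim = obj$gdim, fdim = obj$fdim, mdim = obj$mdim,
                metrics = unlist(obj$metrics))
  if (!is.null(obj$ctrl) && length(obj$ctrl) > 0)
    chain$ctrl <- array(obj$ctrl$values, dim = obj$ctrl$dim)
  structure(chain, class = "transform_chain")
}
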