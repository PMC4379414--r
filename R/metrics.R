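#' Voxelwise confusion counts between two binary masks
#'
#' @param ground_truth,segmentation logical arrays of identical shape.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` (voxel counts summing to the mask size).
#' @export
confusion_counts <- function(ground_truth, segmentation) {
  check_same_shape(ground_truth, segmentation)
  g <- as.logical(ground_truth)
  s <- as.logical(segmentation)
  structure(list(
    tp = sum(g & s), fp = sum(!g & s), tn = sum(!g & !s), fn = sum(g & !s)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da) || is.null(db) || length(da) != length(db) || any(da != db))
    stop("masks must share the same shape")
  invisible(TRUE)
}

#' Three-point ROC area
#'
#' Area under the ROC polyline through (0,0), (FPR, TPR), (1,1):
#' `AUC = FPR*TPR/2 + (1 - FPR)*(1 + TPR)/2`. 1 is an ideal classifier; any
#' point on the diagonal (FPR = TPR) gives 0.5.
#'
#' @param counts a [confusion_counts] object; both classes must be non-empty
#'   so the rates are defined. Alternatively pass `fpr` and `tpr` directly.
#' @param fpr,tpr optional rates in `[0, 1]`, used when `counts` is missing.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_roc3(fpr = 0, tpr = 1)    # ideal
#' auc_roc3(fpr = 0.3, tpr = 0.3)  # chance level
#' @export
auc_roc3 <- function(counts = NULL, fpr = NULL, tpr = NULL) {
  if (!is.null(counts)) {
    if (!inherits(counts, "confusion_counts"))
      stop("'counts' must be a confusion_counts object")
    if (counts$fp + counts$tn == 0)
      stop("negative class is empty: FPR undefined")
    if (counts$tp + counts$fn == 0)
      stop("positive class is empty: TPR undefined")
    fpr <- counts$fp / (counts$fp + counts$tn)
    tpr <- counts$tp / (counts$tp + counts$fn)
  }
  if (is.null(fpr) || is.null(tpr)) stop("supply 'counts' or both 'fpr' and 'tpr'")
  stopifnot(fpr >= 0, fpr <= 1, tpr >= 0, tpr <= 1)
  fpr * tpr / 2 + (1 - fpr) * (1 + tpr) / 2
}

#' Mean similarity (Jaccard index) of two masks
#'
#' `|A intersect B| / |A union B|`; symmetric in its arguments.
#'
#' @inheritParams confusion_counts
#' @return value in `[0, 1]`.
#' @export
mean_similarity <- function(ground_truth, segmentation) {
  check_same_shape(ground_truth, segmentation)
  g <- as.logical(ground_truth); s <- as.logical(segmentation)
  u <- sum(g | s)
  if (u == 0) stop("both masks are empty: similarity undefined")
  sum(g & s) / u
}

#' Symmetric difference of two masks
#'
#' @inheritParams confusion_counts
#' @return logical array: `(A & !B) | (B & !A)`.
#' @export
xor_mask <- function(ground_truth, segmentation) {
  check_same_shape(ground_truth, segmentation)
  array(xor(as.logical(ground_truth), as.logical(segmentation)),
        dim = dim(ground_truth))
}

#' Granulometric pattern spectrum
#'
#' Successive morphological openings with the unit diamond element (size-n
#' opening = n-fold unit element): `PS(n) = |opening_{n-1}| - |opening_n|`,
#' starting at n = 1 with opening_0 the identity, until the opened mask is
#' empty. The spectrum masses sum to the pixel count of the mask. 3D masks
#' use the 6-connected octahedron; `per_slice = TRUE` computes 2D spectra on
#' every axial slice and pools them.
#'
#' @param mask logical 2D or 3D array.
#' @param per_slice pool 2D slice-wise spectra instead of a 3D granulometry.
#' @return object of class `pattern_spectrum`: named integer vector, names
#'   are the opening sizes n.
#' @examples
#' m <- array(FALSE, c(8, 8)); m[3:5, 3:5] <- TRUE
#' pattern_spectrum(m)  # 3x3 square: {1: 4, 2: 5}
#' @export
pattern_spectrum <- function(mask, per_slice = FALSE) {
  dm <- mask_dims(mask)
  ps <- numeric(0)
  eroded <- mask
  prev_count <- sum(mask)
  n <- 0L
  while (prev_count > 0L) {
    n <- n + 1L
    eroded <- morph(eroded, "erode", "diamond", 1L, per_slice = per_slice)
    opened <- eroded
    for (i in seq_len(n))
      opened <- morph(opened, "dilate", "diamond", 1L, per_slice = per_slice)
    cnt <- sum(opened)
    ps[as.character(n)] <- prev_count - cnt
    prev_count <- cnt
  }
  structure(ps, class = "pattern_spectrum")
}

#' @export
print.pattern_spectrum <- function(x, ...) {
  if (length(x) == 0) cat("pattern spectrum: (empty)\n")
  else {
    cat("pattern spectrum (n: mass):\n")
    print(stats::setNames(as.numeric(x), names(x)))
  }
  invisible(x)
}

#' Granulometric mean absolute distance (MAD)
#'
#' Size-weighted mean of the pattern spectrum of the symmetric difference of
#' the two masks: `sum(n * PS(n)) / sum(PS(n))`. Identical masks have an
#' empty XOR, for which MAD is defined as 0 (perfect accuracy). Symmetric in
#' its arguments.
#'
#' @inheritParams confusion_counts
#' @param per_slice compute the granulometry slice-wise in 2D and pool
#'   (default: 3D on 3D masks).
#' @return non-negative real.
#' @export
granulometric_mad <- function(ground_truth, segmentation, per_slice = FALSE) {
  x <- xor_mask(ground_truth, segmentation)
  ps <- pattern_spectrum(x, per_slice = per_slice)
  if (length(ps) == 0 || sum(ps) == 0) return(0)
  n <- as.numeric(names(ps))
  sum(n * as.numeric(ps)) / sum(as.numeric(ps))
}

#' Majority-vote consensus of binary masks
#'
#' A voxel is foreground when more than half of the input masks mark it.
#'
#' @param masks list of >= 1 logical arrays of identical shape (an odd count
#'   avoids ties; with an even count, exactly half votes is background).
#' @return logical array.
#' @export
majority_vote <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) stop("'masks' must be a non-empty list")
  for (m in masks[-1]) check_same_shape(masks[[1]], m)
  acc <- Reduce(`+`, lapply(masks, function(m) as.integer(as.logical(m))))
  array(acc > length(masks) / 2, dim = dim(masks[[1]]))
}

#' Per-bone segmentation quality report
#'
#' Compares two label maps label by label (one-vs-rest): three-point ROC
#' area (with the true-negative count restricted to the bounding box of the
#' union of the two masks, padded by one voxel so both classes stay
#' non-empty), Jaccard mean similarity, and granulometric MAD.
#' Labels present in only one map are reported as missing entries rather
#' than raising. Aggregates (mean and standard deviation of the per-bone
#' values) are computed per group and overall.
#'
#' @param ground_truth,segmentation integer label arrays of identical shape.
#' @param labels integer vector of labels to evaluate; defaults to the
#'   union of nonzero labels in both maps.
#' @param groups named list mapping group names to label vectors; defaults
#'   to the wrist grouping (radius/ulna, metacarpals, carpals) when the
#'   labels fit inside 1..15.
#' @param per_slice passed to [granulometric_mad].
#' @return object of class `wrist_metrics`: data frame with columns `label`,
#'   `code`, `group`, `auc`, `ms`, `mad`, `missing`; aggregate table in
#'   `attr(, "aggregate")`.
#' @export
evaluate_labels <- function(ground_truth, segmentation, labels = NULL,
                            groups = NULL, per_slice = FALSE) {
  check_same_shape(ground_truth, segmentation)
  g <- ground_truth; s <- segmentation
  if (is.null(labels))
    labels <- sort(union(unique(g[g > 0]), unique(s[s > 0])))
  labels <- as.integer(labels)
  wl <- wrist_labels()
  if (is.null(groups) && all(labels %in% wl$label))
    groups <- split(wl$label, wl$group)[unique(wl$group)]
  rows <- lapply(labels, function(l) {
    gm <- g == l; sm <- s == l
    code <- if (l %in% wl$label) wl$code[wl$label == l] else as.character(l)
    grp <- group_of(l, groups)
    if (!any(gm) || !any(sm))
      return(data.frame(label = l, code = code, group = grp, auc = NA_real_,
                        ms = NA_real_, mad = NA_real_, missing = TRUE,
                        stringsAsFactors = FALSE))
    bb <- bbox_union(gm, sm, pad = 1L)  # one-voxel margin keeps the rates defined
    cc <- confusion_counts(do.call(`[`, c(list(gm), bb, list(drop = FALSE))),
                           do.call(`[`, c(list(sm), bb, list(drop = FALSE))))
    data.frame(label = l, code = code, group = grp,
               auc = auc_roc3(cc),
               ms = mean_similarity(gm, sm),
               mad = granulometric_mad(gm, sm, per_slice = per_slice),
               missing = FALSE, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  agg_groups <- c(groups, list(overall = labels))
  agg <- do.call(rbind, lapply(names(agg_groups), function(gn) {
    sub <- rep[rep$label %in% agg_groups[[gn]] & !rep$missing, , drop = FALSE]
    data.frame(group = gn, n = nrow(sub),
               auc_mean = mean(sub$auc), auc_sd = stats::sd(sub$auc),
               ms_mean = mean(sub$ms), ms_sd = stats::sd(sub$ms),
               mad_mean = mean(sub$mad), mad_sd = stats::sd(sub$mad),
               stringsAsFactors = FALSE)
  }))
  structure(rep, aggregate = agg, class = c("wrist_metrics", "data.frame"))
}

group_of <- function(label, groups) {
  if (is.null(groups)) return(NA_character_)
  for (gn in names(groups)) if (label %in% groups[[gn]]) return(gn)
  NA_character_
}

bbox_union <- function(a, b, pad = 0L) {
  u <- a | b
  d <- dim(u)
  lapply(seq_along(d), function(ax) {
    pr <- apply(u, ax, any)
    r <- range(which(pr))
    max(1L, r[1] - pad):min(d[ax], r[2] + pad)
  })
}

#' @export
print.wrist_metrics <- function(x, digits = 3, ...) {
  cat("Per-bone segmentation metrics:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("\nAggregates (mean over bones):\n")
  print.data.frame(attr(x, "aggregate"), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Export a metrics report
#'
#' Writes the per-label rows (label, code, group, auc, ms, mad) as CSV or
#' JSON; the JSON form also carries the aggregates.
#'
#' @param report a `wrist_metrics` object from [evaluate_labels].
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_label = report,
                              aggregate = attr(report, "aggregate")),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
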