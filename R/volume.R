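#' 3D MR volume container
#'
#' A `wrist_volume` wraps a 3D scalar intensity grid (16-bit unsigned MR
#' intensities or real-valued derived fields) together with its voxel spacing.
#' Axis 3 is the axial stack index `z`; `z` increases from distal
#' (metacarpals) toward proximal (radius/ulna).
#'
#' @param data 3D numeric/integer array (every dimension must be at least 2).
#' @param spacing voxel spacing `c(dx, dy, dz)` in millimetres, all positive.
#'   The defaults match a coronal turbo 3D T1 gradient-echo acquisition on a
#'   0.2T extremity scanner (0.75 mm in-plane, 0.7 mm slice thickness).
#' @return An object of class `wrist_volume`: a list with elements `data`
#'   and `spacing`.
#' @examples
#' v <- wrist_volume(array(0L, c(4, 4, 4)))
#' dim(v$data)
#' @export
wrist_volume <- function(data, spacing = c(0.75, 0.75, 0.7)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("every volume dimension must be >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers")
  structure(list(data = data, spacing = spacing), class = "wrist_volume")
}

#' @export
print.wrist_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wrist_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

# Accept a wrist_volume or bare array wherever a volume is expected.
as_volume_array <- function(x) {
  if (inherits(x, "wrist_volume")) return(x$data)
  if (is.array(x)) return(x)
  stop("expected a wrist_volume or an array")
}

vol_spacing <- function(x, default = c(0.75, 0.75, 0.7)) {
  if (inherits(x, "wrist_volume")) x$spacing else default
}

#' Read a volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via the RNifti package and raw 16-bit
#' unsigned binary with a JSON sidecar describing the geometry. The sidecar
#' (`<path>.json`) must contain `dim` (three integers), and may contain
#' `spacing` (mm) and `endian` (`"little"` or `"big"`, default little).
#' Explicit `dims`/`spacing`/`endian` arguments override the sidecar.
#'
#' @param path file to read.
#' @param dims integer vector of length 3 (raw files only).
#' @param spacing voxel spacing in mm.
#' @param endian byte order for raw files.
#' @return A [wrist_volume].
#' @export
load_volume <- function(path, dims = NULL, spacing = NULL, endian = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.integer(round(as.vector(img))), dim = dim(img)[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    if (!is.null(spacing)) sp <- spacing
    return(wrist_volume(arr, sp))
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (is.null(dims)) dims <- meta$dim
  if (is.null(dims)) stop("raw volumes need 'dims' or a JSON sidecar with 'dim'")
  dims <- as.integer(dims)
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing)) spacing <- c(0.75, 0.75, 0.7)
  if (is.null(endian)) endian <- meta$endian
  if (is.null(endian)) endian <- "little"
  n <- prod(dims)
  sz <- file.info(path)$size
  if (sz != 2 * n)
    stop(sprintf("file length %d does not match geometry %s (expected %d bytes)",
                 sz, paste(dims, collapse = "x"), 2 * n))
  v <- readBin(path, what = "integer", n = n, size = 2L, signed = FALSE,
               endian = endian)
  wrist_volume(array(v, dim = dims), spacing)
}

#' Write a volume to disk
#'
#' NIfTI output for `.nii`/`.nii.gz` paths; otherwise raw 16-bit unsigned
#' binary plus a JSON geometry sidecar (`<path>.json`). Raw round trips are
#' lossless for integer volumes in `[0, 65535]`.
#'
#' @param volume a [wrist_volume] or 3D array.
#' @param path destination file.
#' @param endian byte order for raw output.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, endian = "little") {
  arr <- as_volume_array(volume)
  sp <- vol_spacing(volume)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  v <- as.integer(round(arr))
  if (any(v < 0L | v > 65535L)) stop("raw 16-bit output requires values in [0, 65535]")
  writeBin(v, path, size = 2L, endian = endian)
  jsonlite::write_json(list(dim = dim(arr), spacing = sp, endian = endian,
                            dtype = "uint16"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a label map with its label table
#'
#' The label volume is stored like any other volume; the label table (a named
#' integer vector mapping bone codes to label values) goes into a JSON file
#' `<path>.labels.json`.
#'
#' @param labels integer array of labels (0 = background).
#' @param path destination file.
#' @param table named integer vector of label codes; defaults to the
#'   15-bone wrist table ([wrist_labels]).
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labels, path, table = NULL) {
  if (is.null(table)) {
    wl <- wrist_labels()
    table <- stats::setNames(wl$label, wl$code)
  }
  write_volume(wrist_volume(labels), path)
  jsonlite::write_json(as.list(table), paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  v <- load_volume(path)
  lab <- array(as.integer(v$data), dim = dim(v$data))
  tf <- paste0(path, ".labels.json")
  if (file.exists(tf))
    attr(lab, "table") <- unlist(jsonlite::read_json(tf, simplifyVector = TRUE))
  lab
}

#' The 15-bone wrist label table
#'
#' Labels 1..15: distal radius (R) and ulna (U), the five metacarpal bases
#' (M1..M5, M1 on the radial/thumb side) and the eight carpals, coded A..H
#' (scaphoid, lunate, triquetrum, pisiform, trapezium, trapezoid, capitate,
#' hamate).
#'
#' @return data frame with columns `label`, `code`, `group`.
#' @export
wrist_labels <- function() {
  data.frame(
    label = 1:15,
    code = c("R", "U", paste0("M", 1:5), LETTERS[1:8]),
    group = c(rep("radius_ulna", 2), rep("metacarpals", 5), rep("carpals", 8)),
    stringsAsFactors = FALSE
  )
}
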