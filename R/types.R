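#' @useDynLib dirgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D image volume in Hounsfield units
#'
#' A `dirgan_volume` holds a 3D scalar grid of HU values together with its
#' voxel spacing and physical origin. Indexing is 0-based in all coordinate
#' arithmetic: voxel `(i, j, k)` sits at `origin + c(i, j, k) * spacing`
#' millimetres.
#'
#' @param data 3D numeric array of HU values (all finite).
#' @param spacing Numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `dirgan_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite numbers")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (any(dim(data) < 1)) stop("all volume dimensions must be >= 1")
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "dirgan_volume")
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array")
  d <- dim(x)
  if (length(d) != 3) stop("expected a 3D array, got ", length(d), " dims")
  storage.mode(x) <- "double"
  x
}

#' @export
print.dirgan_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dirgan_volume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, HU [%.0f, %.0f]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Dense displacement vector field (DVF)
#'
#' Displacements are stored in voxel units of the field's own grid with the
#' backward-mapping convention: a volume warped by `u` takes its value at
#' `x + u(x)`. The 4th array dimension holds the (x, y, z) components.
#'
#' @param u 4D numeric array `dims x 3` of displacements in voxel units.
#' @param spacing Numeric length-3, grid spacing in mm.
#' @return An object of class `dirgan_dvf` with fields `u`, `spacing`.
#' @export
dvf <- function(u, spacing = c(1, 1, 1)) {
  d <- dim(u)
  if (is.null(d) || length(d) != 4 || d[4] != 3)
    stop("u must be a 4D array with 3 components in the last dimension")
  storage.mode(u) <- "double"
  if (any(!is.finite(u))) stop("displacements must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  structure(list(u = u, spacing = spacing), class = "dirgan_dvf")
}

#' Zero displacement field on a grid
#' @param dims Integer length-3 grid size.
#' @param spacing Grid spacing in mm.
#' @return A `dirgan_dvf` with all displacements zero.
#' @export
zero_dvf <- function(dims, spacing = c(1, 1, 1)) {
  dvf(array(0, c(dims, 3)), spacing)
}

#' @export
print.dirgan_dvf <- function(x, ...) {
  d <- dim(x$u)
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<dirgan_dvf %dx%dx%d, max |u| = %.3g voxels>\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

dvf_dims <- function(d) dim(d$u)[1:3]

#' Named landmark set in physical (mm) coordinates
#'
#' @param labels Character vector of unique labels.
#' @param coords Numeric matrix with one row per landmark and columns
#'   `x_mm`, `y_mm`, `z_mm`.
#' @return A `dirgan_landmarks` object.
#' @export
landmark_set <- function(labels = character(), coords = matrix(0, 0, 3)) {
  labels <- as.character(labels)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(labels) != nrow(coords))
    stop("labels and coordinate rows must match")
  if (anyDuplicated(labels)) stop("landmark labels must be unique")
  if (length(coords) && any(!is.finite(coords)))
    stop("landmark coordinates must be finite")
  colnames(coords) <- c("x_mm", "y_mm", "z_mm")
  rownames(coords) <- labels
  structure(list(labels = labels, coords = coords), class = "dirgan_landmarks")
}

#' @export
print.dirgan_landmarks <- function(x, ...) {
  cat(sprintf("<dirgan_landmarks, %d points>\n", length(x$labels)))
  if (length(x$labels)) print(utils::head(x$coords, 10))
  invisible(x)
}

#' @export
length.dirgan_landmarks <- function(x) length(x$labels)

#' Binary mask over a voxel grid
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @return A `dirgan_mask` object whose `data` is a logical 3D array.
#' @export
mask <- function(data) {
  data <- if (is.logical(data)) data else {
    d <- as_array3d(data)
    if (!all(d %in% c(0, 1))) stop("mask values must be 0 or 1")
    array(d != 0, dim(d))
  }
  if (length(dim(data)) != 3) stop("mask must be 3D")
  structure(list(data = data), class = "dirgan_mask")
}

#' @export
print.dirgan_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dirgan_mask %dx%dx%d, %d voxels set>\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Body mask by HU thresholding
#'
#' Marks every voxel strictly above `threshold_hu`. The default of -300 HU
#' selects all tissue/organ voxels and excludes air, the mask used to
#' restrict the MAE and NCC image metrics.
#'
#' @param v A [volume()].
#' @param threshold_hu HU threshold; voxels with HU > threshold are in the
#'   mask.
#' @return A [mask()] with the same dimensions as `v`.
#' @export
body_mask <- function(v, threshold_hu = -300) {
  stopifnot(inherits(v, "dirgan_volume"))
  mask(array(v$data > threshold_hu, dim(v$data)))
}

#' Bone mask by HU thresholding
#'
#' Marks voxels strictly above 300 HU (bony structures), the mask pair used
#' by the Dice overlap metric.
#'
#' @inheritParams body_mask
#' @return A [mask()].
#' @export
bone_mask <- function(v, threshold_hu = 300) {
  body_mask(v, threshold_hu)
}

#' Physical coordinates of landmark voxels
#'
#' @param idx 0-based voxel index matrix (m x 3).
#' @param v Volume supplying spacing/origin.
#' @return m x 3 matrix of mm coordinates.
#' @keywords internal
voxel_to_mm <- function(idx, v) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' @rdname voxel_to_mm
#' @param mm mm coordinate matrix (m x 3).
#' @keywords internal
mm_to_voxel <- function(mm, v) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  sweep(sweep(mm, 2, v$origin, "-"), 2, v$spacing, "/")
}
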