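#' Warp a volume with a displacement field
#'
#' Backward-mapping spatial transform: the output at voxel `x` takes the
#' moving volume's value at `x + u(x)` (displacements in voxel units),
#' interpolated trilinearly. Sample points outside the grid are edge-clamped
#' so no artificial zero-HU gradients appear at the body edge.
#'
#' @param v A [volume()].
#' @param d A [dvf()] on the same grid as `v`.
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return The deformed [volume()].
#' @export
warp <- function(v, d, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "dirgan_volume"), inherits(d, "dirgan_dvf"))
  dims <- dim(v$data)
  if (!all(dvf_dims(d) == dims))
    stop("DVF grid dims must match the volume dims")
  y <- cpp_warp(as.numeric(v$data), as.integer(dims), as.numeric(d$u),
                if (mode == "nearest") 1L else 0L)
  volume(array(y, dims), spacing = v$spacing, origin = v$origin)
}

# Warp each channel of a plain (dims x C) array with displacement array u.
warp_field <- function(arr, u) {
  d <- dim(arr)
  dims <- d[1:3]
  nc <- if (length(d) == 4) d[4] else 1L
  out <- array(0, c(dims, nc))
  for (ch in seq_len(nc)) {
    x <- if (length(d) == 4) arr[, , , ch] else arr
    out[, , , ch] <- array(cpp_warp(as.numeric(x), as.integer(dims),
                                    as.numeric(u), 0L), dims)
  }
  if (length(d) == 4) out else array(out, dims)
}

#' Compose two displacement fields
#'
#' Returns the field of the map "apply `global`, then `local`":
#' `composed(x) = local(x) + global(x + local(x))`, with `global` sampled
#' trilinearly, so that `warp(v, composed)` approximates
#' `warp(warp(v, global), local)` with a single interpolation.
#'
#' @param global_dvf,local_dvf [dvf()]s on the same grid.
#' @return The composed [dvf()].
#' @export
compose_dvf <- function(global_dvf, local_dvf) {
  stopifnot(inherits(global_dvf, "dirgan_dvf"), inherits(local_dvf, "dirgan_dvf"))
  if (!all(dvf_dims(global_dvf) == dvf_dims(local_dvf)))
    stop("DVF grids must match for composition")
  g_at <- warp_field(global_dvf$u, local_dvf$u)
  dvf(local_dvf$u + g_at, spacing = local_dvf$spacing)
}

#' Upsample a displacement field to a finer grid
#'
#' Each component is interpolated trilinearly to `target_shape` and then
#' rescaled by the per-axis grid ratio so displacements stay in voxel units
#' of the new grid.
#'
#' @param d A [dvf()].
#' @param target_shape Integer length-3, componentwise >= the current grid.
#' @param target_spacing Spacing of the new grid in mm (default: scaled from
#'   the source so physical extent is preserved).
#' @return The upsampled [dvf()].
#' @export
upsample_dvf <- function(d, target_shape, target_spacing = NULL) {
  stopifnot(inherits(d, "dirgan_dvf"))
  src <- dvf_dims(d)
  target_shape <- as.integer(target_shape)
  if (any(target_shape < src))
    stop("target_shape must be >= the source grid componentwise")
  scale <- target_shape / src
  if (is.null(target_spacing)) target_spacing <- d$spacing / scale
  if (all(target_shape == src)) return(dvf(d$u, target_spacing))
  y <- cpp_resize3d(as.numeric(d$u), as.integer(src), 3L,
                    as.integer(target_shape))
  u <- array(y, c(target_shape, 3))
  for (ax in 1:3) u[, , , ax] <- u[, , , ax] * scale[ax]
  dvf(u, spacing = target_spacing)
}

# Trilinear resample of a volume's intensity array to new dims (used for the
# global-stage downsampling).
resample_volume <- function(v, target_shape) {
  stopifnot(inherits(v, "dirgan_volume"))
  dims <- dim(v$data)
  target_shape <- as.integer(target_shape)
  if (all(target_shape == dims)) return(v)
  y <- cpp_resize3d(as.numeric(v$data), as.integer(dims), 1L, target_shape)
  volume(array(y, target_shape),
         spacing = v$spacing * dims / target_shape, origin = v$origin)
}

#' Plan an overlapping patch tiling of a volume
#'
#' Patch start corners advance by `patch_shape - overlap`; if the final
#' patch would not end flush with the volume a clamped start is appended so
#' coverage is complete. Defaults follow the 64^3 patches with 32x32x48
#' overlap used for the local registration stage.
#'
#' @param volume_shape Integer length-3.
#' @param patch_shape Integer length-3 patch size.
#' @param overlap Integer length-3 overlap between successive patches.
#' @return A `dirgan_patchgrid`: list with `patch_shape`, `stride` and the
#'   0-based `starts` matrix (lexicographically ordered).
#' @export
plan_patches <- function(volume_shape, patch_shape = c(64, 64, 64),
                         overlap = c(32, 32, 48)) {
  volume_shape <- as.integer(volume_shape)
  patch_shape <- as.integer(patch_shape)
  overlap <- as.integer(overlap)
  if (any(patch_shape > volume_shape))
    stop("patch_shape must not exceed volume_shape")
  if (any(overlap >= patch_shape) || any(overlap < 0))
    stop("overlap must be in [0, patch_shape)")
  stride <- patch_shape - overlap
  axis_starts <- function(ax) {
    last <- volume_shape[ax] - patch_shape[ax]
    s <- seq(0L, last, by = stride[ax])
    if (s[length(s)] != last) s <- c(s, last)
    s
  }
  sx <- axis_starts(1); sy <- axis_starts(2); sz <- axis_starts(3)
  starts <- as.matrix(expand.grid(x = sx, y = sy, z = sz,
                                  KEEP.OUT.ATTRS = FALSE))
  # lexicographic order (x fastest within y within z -> reorder to x,y,z major)
  starts <- starts[order(starts[, 1], starts[, 2], starts[, 3]), , drop = FALSE]
  dimnames(starts) <- NULL
  structure(list(patch_shape = patch_shape, stride = stride,
                 volume_shape = volume_shape, starts = starts),
            class = "dirgan_patchgrid")
}

#' @export
print.dirgan_patchgrid <- function(x, ...) {
  cat(sprintf("<dirgan_patchgrid %d patches of %s, stride %s>\n",
              nrow(x$starts), paste(x$patch_shape, collapse = "x"),
              paste(x$stride, collapse = "x")))
  invisible(x)
}

#' Extract the patches of a patch grid from a field
#'
#' @param arr 3D array or 4D (multi-channel) array.
#' @param grid A [plan_patches()] grid.
#' @return List of patch arrays in grid order.
#' @export
extract_patches <- function(arr, grid) {
  stopifnot(inherits(grid, "dirgan_patchgrid"))
  d <- dim(arr)
  ps <- grid$patch_shape
  lapply(seq_len(nrow(grid$starts)), function(p) {
    s <- grid$starts[p, ]
    ix <- (s[1] + 1):(s[1] + ps[1])
    iy <- (s[2] + 1):(s[2] + ps[2])
    iz <- (s[3] + 1):(s[3] + ps[3])
    if (length(d) == 4) arr[ix, iy, iz, , drop = FALSE]
    else arr[ix, iy, iz, drop = FALSE]
  })
}

#' Fuse per-patch displacement fields into a whole-volume field
#'
#' Patch DVFs are tiled back at their grid corners and voxels covered by
#' several patches take the unweighted mean of all covering patches.
#'
#' @param patch_dvfs List of [dvf()]s (or raw 4D arrays), one per grid start.
#' @param grid A [plan_patches()] grid.
#' @param volume_shape Full grid dims; defaults to the grid's.
#' @param spacing Spacing for the fused field.
#' @return The fused whole-volume [dvf()].
#' @export
fuse_patches <- function(patch_dvfs, grid, volume_shape = grid$volume_shape,
                         spacing = c(1, 1, 1)) {
  stopifnot(inherits(grid, "dirgan_patchgrid"))
  if (length(patch_dvfs) != nrow(grid$starts))
    stop("need exactly one patch DVF per grid start (",
         nrow(grid$starts), "), got ", length(patch_dvfs))
  ps <- grid$patch_shape
  acc <- array(0, c(volume_shape, 3))
  cnt <- array(0, volume_shape)
  for (p in seq_along(patch_dvfs)) {
    u <- patch_dvfs[[p]]
    if (inherits(u, "dirgan_dvf")) u <- u$u
    if (!all(dim(u) == c(ps, 3)))
      stop("patch ", p, " has wrong shape")
    s <- grid$starts[p, ]
    ix <- (s[1] + 1):(s[1] + ps[1])
    iy <- (s[2] + 1):(s[2] + ps[2])
    iz <- (s[3] + 1):(s[3] + ps[3])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + u
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  if (any(cnt == 0)) stop("patch grid does not cover the volume")
  for (ax in 1:3) acc[, , , ax] <- acc[, , , ax] / cnt
  dvf(acc, spacing = spacing)
}

# Finite difference of a 3D or multi-channel 4D array along one spatial
# axis. order 1: central differences interior, one-sided at borders.
# order 2: second difference interior, zero at border planes. adjoint gives
# the exact transpose of the same linear operator.
axis_diff <- function(arr, ax, order = 1, adjoint = FALSE) {
  d <- dim(arr)
  dims <- d[1:3]
  nc <- as.integer(prod(d) / prod(dims))
  y <- cpp_axis_diff(arr, as.integer(dims), nc,
                     as.integer(ax - 1L), as.integer(order),
                     as.integer(adjoint))
  dim(y) <- d
  y
}

# Spatial gradient of a scalar 3D array: central differences interior,
# one-sided at borders; returns list of 3 arrays.
grad3 <- function(arr) lapply(1:3, function(ax) axis_diff(arr, ax))

#' Jacobian determinant of the deformation map
#'
#' At every voxel, `det(I + grad(u))` with the displacement gradient taken
#' by central differences (one-sided at the grid borders), in voxel units.
#' Values <= 0 flag locally folded (non-diffeomorphic) deformation.
#'
#' @param d A [dvf()] with all grid dims >= 2.
#' @return 3D numeric array of determinants.
#' @export
jacobian_determinant <- function(d) {
  stopifnot(inherits(d, "dirgan_dvf"))
  dims <- dvf_dims(d)
  if (any(dims < 2)) stop("jacobian needs >= 2 voxels along every axis")
  J <- vector("list", 9)
  for (comp in 1:3) {
    g <- grad3(d$u[, , , comp])
    for (ax in 1:3) J[[(comp - 1) * 3 + ax]] <- g[[ax]]
  }
  # rows = components, cols = axes; det(I + J)
  a11 <- 1 + J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- 1 + J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- 1 + J[[9]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Fraction of mask voxels with non-positive Jacobian determinant
#'
#' The %N regularity figure: the fraction of body voxels where the
#' deformation folds (det <= 0); lower is better.
#'
#' @param d A [dvf()].
#' @param m A [mask()] on the same grid (non-empty).
#' @return A number in \[0, 1\].
#' @export
nonpositive_jacobian_ratio <- function(d, m) {
  stopifnot(inherits(d, "dirgan_dvf"), inherits(m, "dirgan_mask"))
  if (!all(dim(m$data) == dvf_dims(d)))
    stop("mask dims must match the DVF grid")
  nmask <- sum(m$data)
  if (nmask == 0) stop("empty mask: nonpositive_jacobian_ratio is undefined")
  jd <- jacobian_determinant(d)
  sum(jd[m$data] <= 0) / nmask
}
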