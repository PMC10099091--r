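#' Default 6-connected MIND offset set
#'
#' One offset per face neighbour (+/-1 along each axis), the most common
#' search neighbourhood for the descriptor.
#'
#' @return 6 x 3 integer matrix of voxel offsets.
#' @export
mind_offsets_6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0),
        c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

#' Modality-independent neighbourhood descriptor (MIND)
#'
#' For each voxel `x` and search offset `r` the channel value is
#' `exp(-D(x, r) / V(x))`, where `D` is the mean squared intensity
#' difference between the cubic patches of radius `patch_radius` centred at
#' `x` and `x + r` (patches clipped at the volume edge), and `V(x)` is the
#' mean of `D` over the offset set, floored at `epsilon_rel` times the
#' volume's intensity variance. Each voxel's channel vector is finally
#' divided by its own maximum, so the largest channel is exactly 1. The
#' descriptor is invariant under affine intensity maps `a*I + b` (a > 0),
#' which is what makes it robust to inter-fraction HU inconsistency.
#'
#' @param v A [volume()] or 3D array.
#' @param patch_radius Cubic patch radius in voxels (default 1).
#' @param offsets Integer matrix of search offsets (rows), no zero row.
#' @param epsilon_rel Relative floor for the variance estimate `V`.
#' @return A `dirgan_mind` object: 4D array `dims x n_offsets` of values in
#'   (0, 1] plus the parameters used.
#' @export
mind <- function(v, patch_radius = 1L, offsets = mind_offsets_6(),
                 epsilon_rel = 1e-6) {
  arr <- if (inherits(v, "dirgan_volume")) v$data else as_array3d(v)
  f <- mind_forward(arr, patch_radius, offsets, epsilon_rel)
  structure(list(values = f$N, patch_radius = patch_radius,
                 offsets = offsets, epsilon_rel = epsilon_rel),
            class = "dirgan_mind")
}

#' @export
print.dirgan_mind <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dirgan_mind %dx%dx%d, %d channels, range [%.3g, %.3g]>\n",
              d[1], d[2], d[3], d[4], min(x$values), max(x$values)))
  invisible(x)
}

# Forward pass keeping every intermediate needed by mind_backward.
mind_forward <- function(arr, patch_radius = 1L, offsets = mind_offsets_6(),
                         epsilon_rel = 1e-6) {
  dims <- dim(arr)
  if (any(dims < 2 * patch_radius + 1))
    stop("volume smaller than the MIND patch (", 2 * patch_radius + 1,
         ") along some axis")
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (nrow(offsets) == 0) stop("offset set must be non-empty")
  if (any(rowSums(abs(offsets)) == 0)) stop("offsets must be non-zero")
  R <- nrow(offsets)
  n <- prod(dims)
  x <- as.numeric(arr)
  idims <- as.integer(dims)
  cnt <- cpp_boxsum(rep(1, n), idims, as.integer(patch_radius))
  D <- matrix(0, n, R)
  E <- matrix(0, n, R)   # I - shift_r(I), kept for the backward pass
  for (r in seq_len(R)) {
    sh <- cpp_shift_clamp(x, idims, offsets[r, ])
    e <- x - sh
    E[, r] <- e
    D[, r] <- cpp_boxsum(e * e, idims, as.integer(patch_radius)) / cnt
  }
  Vraw <- rowMeans(D)
  vfloor <- epsilon_rel * max(stats::var(x), .Machine$double.xmin)
  V <- pmax(Vraw, vfloor)
  C <- exp(-D / V)
  amax <- max.col(C, ties.method = "first")
  M <- C[cbind(seq_len(n), amax)]
  N <- C / M
  list(N = array(N, c(dims, R)), C = C, D = D, V = V,
       floored = Vraw < vfloor, amax = amax, E = E, cnt = cnt,
       dims = dims, offsets = offsets, patch_radius = patch_radius)
}

# Gradient of a scalar loss with respect to the input image, given the
# gradient gN with respect to the descriptor channels. The small coupling
# through the variance floor's dependence on var(I) is neglected (the floor
# is epsilon-scaled and inactive away from constant regions).
mind_backward <- function(fwd, gN) {
  dims <- fwd$dims
  n <- prod(dims)
  R <- nrow(fwd$offsets)
  idims <- as.integer(dims)
  gN <- matrix(as.numeric(gN), n, R)
  C <- fwd$C; D <- fwd$D; V <- fwd$V
  amax <- fwd$amax
  M <- C[cbind(seq_len(n), amax)]
  # N = C / M ; dL/dC_r = gN_r / M - [r == amax] * sum_s gN_s C_s / M^2
  sumgC <- rowSums(gN * C)
  gC <- gN / M
  gC[cbind(seq_len(n), amax)] <- gC[cbind(seq_len(n), amax)] - sumgC / M^2
  # C = exp(-D/V): dL/dD_r = -C_r gC_r / V + (1/R) [not floored] *
  #   sum_s gC_s C_s D_s / V^2
  through_V <- ifelse(fwd$floored, 0, 1) * rowSums(gC * C * D) / (V^2 * R)
  gD <- -gC * C / V + through_V
  # D_r = boxsum(E_r^2)/cnt: adjoint is elementwise 2 E_r boxsum(gD_r/cnt)
  gI <- numeric(n)
  for (r in seq_len(R)) {
    q <- cpp_boxsum(gD[, r] / fwd$cnt, idims, as.integer(fwd$patch_radius))
    ge <- 2 * fwd$E[, r] * q
    gI <- gI + ge - cpp_shift_clamp_adjoint(ge, idims, fwd$offsets[r, ])
  }
  array(gI, dims)
}
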