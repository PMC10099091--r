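# Shared fixtures and independent brute-force oracles used across tests.

rand_volume <- function(dims, lo = -500, hi = 500, seed = 1) {
  set.seed(seed)
  volume(array(stats::runif(prod(dims), lo, hi), dims))
}

rand_dvf <- function(dims, amp = 1.5, seed = 1) {
  set.seed(seed)
  dvf(array(stats::runif(prod(dims) * 3, -amp, amp), c(dims, 3)))
}

# Per-voxel trilinear interpolation oracle for the backward-mapping warp,
# written independently of the package kernel (plain R loops).
brute_warp <- function(v, d) {
  dims <- dim(v$data)
  u <- d$u
  out <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      s <- c(i - 1 + u[i, j, k, 1], j - 1 + u[i, j, k, 2], k - 1 + u[i, j, k, 3])
      s <- pmin(pmax(s, 0), dims - 1)
      f0 <- floor(s)
      fr <- s - f0
      acc <- 0
      for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
        idx <- pmin(f0 + c(cx, cy, cz), dims - 1)
        wt <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
        acc <- acc + wt * v$data[idx[1] + 1, idx[2] + 1, idx[3] + 1]
      }
      out[i, j, k] <- acc
    }
  out
}

# Brute-force MIND oracle: per-voxel, per-offset double loop over clipped
# patches with edge-clamped shifted samples.
brute_mind <- function(arr, patch_radius = 1, offsets = mind_offsets_6(),
                       epsilon_rel = 1e-6) {
  dims <- dim(arr)
  R <- nrow(offsets)
  clampi <- function(v, n) pmin(pmax(v, 1), n)
  Dmat <- array(0, c(dims, R))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      for (r in seq_len(R)) {
        acc <- 0; cnt <- 0
        for (pz in -patch_radius:patch_radius)
          for (py in -patch_radius:patch_radius)
            for (px in -patch_radius:patch_radius) {
              yi <- c(i + px, j + py, k + pz)
              if (any(yi < 1) || any(yi > dims)) next
              si <- clampi(yi + offsets[r, ], dims)
              e <- arr[yi[1], yi[2], yi[3]] - arr[si[1], si[2], si[3]]
              acc <- acc + e^2
              cnt <- cnt + 1
            }
        Dmat[i, j, k, r] <- acc / cnt
      }
    }
  vfloor <- epsilon_rel * max(stats::var(as.numeric(arr)),
                              .Machine$double.xmin)
  out <- array(0, c(dims, R))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      dv <- Dmat[i, j, k, ]
      V <- max(mean(dv), vfloor)
      cv <- exp(-dv / V)
      out[i, j, k, ] <- cv / max(cv)
    }
  out
}

# A small, fast scaled-down train configuration for smoke tests.
tiny_train_config <- function(iters = 3, seed = 1) {
  train_config(iterations_global = iters, iterations_local = iters,
               global_downsample_shape = c(16, 16, 16),
               patch_shape = c(8, 8, 8), overlap = c(4, 4, 4),
               gen_filters = 2, disc_filters = 2,
               learning_rate = 1e-3, seed = seed)
}
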