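test_that("trilinear warp matches the brute-force oracle exactly", {
  for (seed in 1:3) {
    dims <- list(c(6, 5, 4), c(8, 8, 8), c(5, 7, 6))[[seed]]
    v <- rand_volume(dims, seed = seed)
    d <- rand_dvf(dims, amp = 1.5, seed = seed + 10)
    expect_equal(warp(v, d)$data, brute_warp(v, d), tolerance = 1e-12)
  }
})

test_that("zero-DVF warp is the identity and integer shifts clamp at edges", {
  v <- rand_volume(c(8, 8, 8), seed = 4)
  expect_identical(warp(v, zero_dvf(c(8, 8, 8)))$data, v$data)
  # +1 voxel shift along x of a ramp: shifted copy with clamped edge
  ramp <- volume(array(rep(0:7 * 10, 64), c(8, 8, 8)))
  u <- array(0, c(8, 8, 8, 3)); u[, , , 1] <- 1
  w <- warp(ramp, dvf(u))
  expected <- ramp$data[c(2:8, 8), , ]
  expect_equal(w$data, expected, tolerance = 1e-12)
})

test_that("composition has the right identities and consistency", {
  dims <- c(16, 16, 16)
  g <- make_smooth_dvf(dims, 2, 4, seed = 1)
  l <- make_smooth_dvf(dims, 2, 4, seed = 2)
  z <- zero_dvf(dims)
  dimsc <- c(48, 48, 32)
  expect_identical(compose_dvf(g, z)$u, g$u)
  expect_identical(compose_dvf(z, l)$u, l$u)
  # constant translations add
  a <- dvf(array(rep(c(0.5, -1, 2), each = prod(dims)), c(dims, 3)))
  b <- dvf(array(rep(c(1, 0.25, -0.5), each = prod(dims)), c(dims, 3)))
  expect_equal(compose_dvf(a, b)$u, a$u + b$u, tolerance = 1e-12)
  # warp(warp(v, g), l) ~ warp(v, compose(g, l)) within 1% of range for
  # phantom-scale smooth fields
  v <- make_phantom(phantom_spec(shape = dimsc, n_fiducials = 0,
                                 seed = 5))$volume
  gc2 <- make_smooth_dvf(dimsc, 3, 8, seed = 6)
  lc2 <- make_smooth_dvf(dimsc, 3, 8, seed = 7)
  two <- warp(warp(v, gc2), lc2)
  one <- warp(v, compose_dvf(gc2, lc2))
  rng <- diff(range(v$data))
  expect_lt(mean(abs(two$data - one$data)), 0.01 * rng)
})

test_that("DVF upsampling rescales displacements to the new voxel units", {
  dims <- c(8, 8, 8)
  cst <- dvf(array(rep(c(2, 0, 0), each = prod(dims)), c(dims, 3)))
  up <- upsample_dvf(cst, c(16, 16, 16))
  expect_equal(up$u[, , , 1], array(4, c(16, 16, 16)), tolerance = 1e-12)
  expect_equal(max(abs(up$u[, , , 2:3])), 0)
  # identity-shape upsample is a no-op
  expect_identical(upsample_dvf(cst, dims)$u, cst$u)
  # linear fields are fixed points (away from the clamped trailing edge)
  lin <- array(0, c(dims, 3))
  lin[, , , 1] <- 0.1 * array(rep(0:7, 64), dims)
  up2 <- upsample_dvf(dvf(lin), c(16, 16, 16))
  xs <- array(rep(0:15, 16 * 16), c(16, 16, 16))
  expect_equal(up2$u[1:14, , , 1], (0.1 * xs)[1:14, , ], tolerance = 1e-12)
})

test_that("patch planning reproduces the production tiling arithmetic", {
  g <- plan_patches(c(128, 128, 96))
  expect_equal(g$stride, c(32, 32, 16))
  expect_equal(nrow(g$starts), 27)
  expect_equal(sort(unique(g$starts[, 3])), c(0, 16, 32))
  # volume == patch -> single patch at the origin
  g1 <- plan_patches(c(64, 64, 64))
  expect_equal(nrow(g1$starts), 1)
  expect_equal(g1$starts[1, ], c(0, 0, 0))
  # clinical volume size: clamped final z start
  g2 <- plan_patches(c(512, 512, 88))
  expect_equal(length(unique(g2$starts[, 1])), 15)
  expect_equal(length(unique(g2$starts[, 2])), 15)
  expect_equal(sort(unique(g2$starts[, 3])), c(0, 16, 24))
  expect_error(plan_patches(c(32, 32, 32)), "exceed")
})

test_that("extract then fuse is the identity and overlaps average", {
  dims <- c(16, 16, 12)
  u <- rand_dvf(dims, seed = 20)$u
  grid <- plan_patches(dims, c(8, 8, 8), c(4, 4, 4))
  fused <- fuse_patches(extract_patches(u, grid), grid, dims)
  expect_equal(fused$u, u, tolerance = 1e-12)
  # all-constant patches fuse to the constant
  cpatches <- replicate(nrow(grid$starts),
                        array(0.7, c(8, 8, 8, 3)), simplify = FALSE)
  expect_equal(as.numeric(fuse_patches(cpatches, grid, dims)$u),
               rep(0.7, prod(dims) * 3), tolerance = 1e-12)
  # two overlapping patches valued 1 and 3 average to 2 in the overlap
  g2 <- plan_patches(c(12, 8, 8), c(8, 8, 8), c(4, 4, 4))
  expect_equal(nrow(g2$starts), 2)
  p <- list(array(1, c(8, 8, 8, 3)), array(3, c(8, 8, 8, 3)))
  f2 <- fuse_patches(p, g2, c(12, 8, 8))
  expect_equal(unique(as.numeric(f2$u[5:8, , , ])), 2)
  expect_error(fuse_patches(p[1], g2, c(12, 8, 8)), "one patch DVF per")
})

test_that("Jacobian determinant matches closed forms", {
  dims <- c(8, 8, 8)
  expect_equal(jacobian_determinant(zero_dvf(dims)),
               array(1, dims), tolerance = 1e-12)
  X <- array(rep(0:7, 64), dims)
  Y <- array(rep(rep(0:7, each = 8), 8), dims)
  Z <- array(rep(0:7, each = 64), dims)
  ue <- array(0, c(dims, 3))
  ue[, , , 1] <- 0.1 * X; ue[, , , 2] <- 0.1 * Y; ue[, , , 3] <- 0.1 * Z
  jd <- jacobian_determinant(dvf(ue))
  expect_equal(jd[2:7, 2:7, 2:7], array(1.331, c(6, 6, 6)), tolerance = 1e-9)
  # folding field: det = -1 interior, flagged by the %N ratio
  uf <- array(0, c(dims, 3)); uf[, , , 1] <- -2 * X
  jf <- jacobian_determinant(dvf(uf))
  expect_equal(jf[2:7, , ], array(-1, c(6, 8, 8)), tolerance = 1e-12)
  full <- mask(array(1, dims))
  expect_equal(nonpositive_jacobian_ratio(zero_dvf(dims), full), 0)
  interior <- array(0, dims); interior[2:7, , ] <- 1
  expect_equal(nonpositive_jacobian_ratio(dvf(uf), mask(interior)), 1)
  expect_error(nonpositive_jacobian_ratio(zero_dvf(dims),
                                          mask(array(0, dims))), "empty")
})

test_that("smooth generated fields are fold-free", {
  d <- make_smooth_dvf(c(24, 24, 16), 3, 8, seed = 3)
  expect_equal(nonpositive_jacobian_ratio(d, mask(array(1, c(24, 24, 16)))), 0)
})
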