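test_that("phantom generation is deterministic and well-formed", {
  spec <- phantom_spec(shape = c(32, 32, 24), n_fiducials = 4, seed = 1)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$landmarks$coords, p2$landmarks$coords)
  expect_gte(length(p1$landmarks), 4)
  # all landmarks inside the body mask
  vox <- round(dirgan:::mm_to_voxel(p1$landmarks$coords, p1$volume)) + 1
  for (r in seq_len(nrow(vox)))
    expect_true(p1$body$data[vox[r, 1], vox[r, 2], vox[r, 3]])
  # markers are bright
  fidvox <- vox[grepl("^fid", p1$landmarks$labels), , drop = FALSE]
  for (r in seq_len(nrow(fidvox)))
    expect_gte(p1$volume$data[fidvox[r, 1], fidvox[r, 2], fidvox[r, 3]], 2000)
})

test_that("bone voxel bookkeeping matches the thresholded mask", {
  p <- make_phantom(phantom_spec(shape = c(32, 32, 24), n_fiducials = 3,
                                 seed = 2))
  n_mask <- sum(bone_mask(p$volume)$data)
  # mask = structural bone + marker voxels (<= 5 voxels per marker)
  expect_gte(n_mask, p$n_bone_voxels)
  expect_lte(n_mask, p$n_bone_voxels + 5 * 3)
})

test_that("smooth DVF generator honours its contract", {
  expect_identical(make_smooth_dvf(c(16, 16, 16), 0, 8, seed = 1)$u,
                   zero_dvf(c(16, 16, 16))$u)
  d1 <- make_smooth_dvf(c(24, 24, 16), 3, 8, seed = 9)
  d2 <- make_smooth_dvf(c(24, 24, 16), 3, 8, seed = 9)
  expect_identical(d1$u, d2$u)
  mag <- sqrt(d1$u[, , , 1]^2 + d1$u[, , , 2]^2 + d1$u[, , , 3]^2)
  expect_equal(max(mag), 3, tolerance = 1e-12)
  expect_equal(nonpositive_jacobian_ratio(d1, mask(array(1, c(24, 24, 16)))),
               0)
})

test_that("degradation has exact closed-form and determinism properties", {
  p <- make_phantom(phantom_spec(shape = c(24, 24, 16), seed = 3))
  v <- p$volume
  expect_identical(degrade(v, 0, 0)$data, v$data)
  # pure shift: body MAE is exactly the shift
  shifted <- degrade(v, 0, 20)
  expect_equal(mae(shifted, v, p$body), 20, tolerance = 1e-12)
  g1 <- degrade(v, 15, 10, seed = 4)
  g2 <- degrade(v, 15, 10, seed = 4)
  expect_identical(g1$data, g2$data)
  expect_gt(mae(g1, v, p$body), 0)
})

test_that("ground-truth pairs have self-consistent landmarks", {
  pair <- make_registration_pair(phantom_spec(shape = c(32, 32, 24),
                                              n_fiducials = 3, seed = 6),
                                 max_displacement_vox = 2,
                                 smoothness_sigma_vox = 6)
  # moving landmark x satisfies x + u(x) = p for the target landmark p
  vox_t <- dirgan:::mm_to_voxel(pair$landmarks_target$coords, pair$target)
  vox_m <- dirgan:::mm_to_voxel(pair$landmarks_moving$coords, pair$target)
  u_at <- dirgan:::cpp_sample_trilinear(as.numeric(pair$gt_dvf$u),
                                        dim(pair$target$data), 3L,
                                        vox_m)
  expect_lt(max(abs(vox_m + u_at - vox_t)), 2e-3)
  # pre-registration TRE equals the landmark displacement magnitude
  pre <- tre(pair$landmarks_moving, pair$landmarks_target,
             zero_dvf(dim(pair$target$data), pair$target$spacing))
  disp_mm <- sqrt(rowSums((vox_m - vox_t)^2)) * pair$target$spacing[1]
  expect_equal(unname(pre), unname(disp_mm), tolerance = 1e-6)
})

test_that("fiducial overcrowding is rejected", {
  expect_error(make_phantom(phantom_spec(shape = c(16, 16, 16),
                                         n_fiducials = 400, seed = 1)),
               "fiducials")
})
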