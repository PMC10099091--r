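test_that("training on an identical pair keeps the field near zero", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), n_fiducials = 1,
                                  seed = 51))
  pair <- list(moving = ph$volume, target = ph$volume)
  cfg <- tiny_train_config(iters = 3, seed = 51)
  g <- train_global(pair, cfg)
  # similarity of a perfectly aligned pair is zero from the first iteration
  expect_equal(g$history$similarity[1], 0, tolerance = 1e-10)
  out <- dirgan:::global_dvf_for(ph$volume, ph$volume, g$checkpoint)
  expect_lt(max(abs(out$u)), 0.05)
})

test_that("training runs are reproducible from the seed", {
  pair <- make_registration_pair(phantom_spec(shape = c(16, 16, 16),
                                              n_fiducials = 1, seed = 52),
                                 max_displacement_vox = 1,
                                 smoothness_sigma_vox = 4)
  p <- list(moving = pair$moving, target = pair$target)
  cfg <- tiny_train_config(iters = 3, seed = 99)
  g1 <- train_global(p, cfg)
  g2 <- train_global(p, cfg)
  expect_identical(g1$history, g2$history)
  expect_identical(g1$checkpoint$gen, g2$checkpoint$gen)
  l1 <- train_local(p, g1$checkpoint, cfg)
  l2 <- train_local(p, g2$checkpoint, cfg)
  expect_identical(l1$history, l2$history)
})

test_that("loss traces are finite and complete", {
  pair <- make_registration_pair(phantom_spec(shape = c(16, 16, 16),
                                              n_fiducials = 1, seed = 53),
                                 max_displacement_vox = 1,
                                 smoothness_sigma_vox = 4)
  p <- list(moving = pair$moving, target = pair$target)
  cfg <- tiny_train_config(iters = 4, seed = 1)
  g <- train_global(p, cfg)
  expect_equal(nrow(g$history), 4)
  expect_true(all(is.finite(g$history$total)))
  expect_true(all(is.finite(g$history$disc_loss)))
  l <- train_local(p, g$checkpoint, cfg)
  expect_equal(nrow(l$history), 4)
  expect_true(all(is.finite(l$history$total)))
})

test_that("the local stage visits exactly the planned patch grid per epoch", {
  pair <- make_registration_pair(phantom_spec(shape = c(16, 16, 16),
                                              n_fiducials = 1, seed = 54),
                                 max_displacement_vox = 1,
                                 smoothness_sigma_vox = 4)
  p <- list(moving = pair$moving, target = pair$target)
  grid <- plan_patches(c(16, 16, 16), c(8, 8, 8), c(4, 4, 4))
  n_patches <- nrow(grid$starts)
  cfg <- tiny_train_config(iters = n_patches, seed = 2)
  g <- train_global(p, tiny_train_config(iters = 2, seed = 2))
  l <- train_local(p, g$checkpoint, cfg)
  # one epoch = one generator update per planned patch
  expect_equal(nrow(l$history), n_patches)
})

test_that("checkpoints round-trip through files", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), n_fiducials = 1,
                                  seed = 55))
  cfg <- tiny_train_config(iters = 2, seed = 3)
  g <- train_global(list(moving = ph$volume, target = ph$volume), cfg)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(g$checkpoint, path)
  r <- load_checkpoint(path)
  expect_identical(r$gen, g$checkpoint$gen)
  expect_identical(r$kind, "global")
  expect_error(load_checkpoint(tempfile()), "no such")
})
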