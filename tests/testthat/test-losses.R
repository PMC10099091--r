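test_that("NCC identities and oracle agreement hold", {
  set.seed(31)
  v <- array(stats::runif(6^3), c(6, 6, 6))
  b <- array(stats::runif(6^3), c(6, 6, 6))
  expect_equal(ncc_score(v, v), 1, tolerance = 1e-12)
  expect_equal(ncc_score(v, -v + 3), -1, tolerance = 1e-12)
  ac <- v - mean(v); bc <- b - mean(b)
  oracle <- sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  expect_equal(ncc_score(v, b), oracle, tolerance = 1e-12)
  expect_error(ncc_score(array(1, c(6, 6, 6)), v), "constant")
})

test_that("gradient difference has its closed forms and symmetry", {
  set.seed(32)
  a <- array(stats::runif(6^3), c(6, 6, 6))
  b <- array(stats::runif(6^3), c(6, 6, 6))
  expect_equal(gradient_difference(a, a), 0)
  expect_equal(gradient_difference(a, b), gradient_difference(b, a))
  # ramp 0.1 x vs 0: the x-axis derivative mismatch is 0.1 everywhere
  # (one-sided at borders reproduces the slope exactly), so the x term
  # contributes 0.01 and the y/z terms 0
  n <- 10
  ramp <- 0.1 * array(rep(0:(n - 1), n * n), c(n, n, n))
  expect_equal(gradient_difference(ramp, array(0, c(n, n, n))),
               0.01 / 3, tolerance = 1e-12)
})

test_that("similarity loss vanishes iff descriptors agree and is
           HU-affine invariant", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), n_fiducials = 1,
                                  seed = 33))
  v <- ph$volume
  expect_equal(similarity_loss(v, v), 0, tolerance = 1e-12)
  v2 <- volume(2 * v$data + 100, v$spacing)
  expect_lt(similarity_loss(v2, v), 1e-8)
  # a genuinely deformed pair has strictly positive loss
  d <- make_smooth_dvf(c(16, 16, 16), 2, 4, seed = 34)
  expect_gt(similarity_loss(warp(v, d), v), 1e-4)
})

test_that("DVF regularization has closed forms and quadratic homogeneity", {
  dims <- c(10, 10, 10)
  expect_equal(dvf_regularization(zero_dvf(dims)), 0)
  cst <- dvf(array(5, c(dims, 3)))
  expect_equal(dvf_regularization(cst), 0, tolerance = 1e-12)
  # linear field u_x = c x: mean |grad u|^2 = c^2, Laplacian = 0
  cc <- 0.2
  lin <- array(0, c(dims, 3))
  lin[, , , 1] <- cc * array(rep(0:9, 100), dims)
  expect_equal(dvf_regularization(dvf(lin), mu1 = 1, mu2 = 0.5), cc^2,
               tolerance = 1e-12)
  u <- rand_dvf(dims, seed = 35)
  expect_equal(dvf_regularization(dvf(2 * u$u)),
               4 * dvf_regularization(u), tolerance = 1e-9)
})

test_that("adversarial losses match the BCE closed forms", {
  half <- array(0.5, c(3, 3, 3))
  r <- adversarial_losses(half, half)
  expect_equal(r$gen_loss, -log(0.5), tolerance = 1e-12)
  expect_equal(r$disc_loss, -log(0.5), tolerance = 1e-12)
  # near-perfect discriminator: small disc loss, large gen loss
  eps <- 1e-4
  r2 <- adversarial_losses(array(1 - eps, c(2, 2, 2)), array(eps, c(2, 2, 2)))
  expect_lt(r2$disc_loss, 1e-3)
  expect_gt(r2$gen_loss, 9)
  # elementwise brute-force oracle on random scores
  set.seed(36)
  sr <- array(stats::runif(8, 0.1, 0.9), c(2, 2, 2))
  sf <- array(stats::runif(8, 0.1, 0.9), c(2, 2, 2))
  r3 <- adversarial_losses(sr, sf)
  expect_equal(r3$gen_loss, mean(-log(sf)), tolerance = 1e-12)
  expect_equal(r3$disc_loss, 0.5 * (mean(-log(sr)) + mean(-log(1 - sf))),
               tolerance = 1e-12)
  expect_error(adversarial_losses(array(0, c(2, 2, 2)), sf), "strictly")
})

test_that("default loss weights are the production values", {
  w <- loss_weights()
  expect_equal(w$alpha, 200)
  expect_equal(w$beta, 1)
  expect_equal(w$gamma, 10)
  expect_equal(w$delta, 5)
  expect_equal(w$mu1, 1)
  expect_equal(w$mu2, 0.5)
  expect_error(loss_weights(alpha = -1), "non-negative")
})

test_that("total generator loss reduces to the adversarial term for a
           perfectly aligned pair with zero field", {
  v <- rand_volume(c(10, 10, 10), seed = 37)
  z <- zero_dvf(c(10, 10, 10))
  tot <- total_generator_loss(v, v, z, loss_weights(),
                              disc_score_fake = array(0.5, c(2, 2, 2)))
  expect_equal(as.numeric(tot), -log(0.5), tolerance = 1e-9)
  comp <- attr(tot, "components")
  expect_equal(comp$similarity, 0, tolerance = 1e-12)
  expect_equal(comp$regularization, 0)
  # beta = 0 switches the adversarial term off exactly
  tot0 <- total_generator_loss(v, v, z, loss_weights(beta = 0),
                               disc_score_fake = array(0.5, c(2, 2, 2)))
  expect_identical(attr(tot0, "components")$adversarial, 0)
  expect_equal(as.numeric(tot0), 0, tolerance = 1e-12)
})

test_that("loss gradients match finite differences", {
  set.seed(38)
  u <- array(stats::rnorm(5 * 6 * 7 * 3) * 0.3, c(5, 6, 7, 3))
  r <- dirgan:::reg_with_grad(u, 1, 0.5)
  eps <- 1e-6
  for (ii in sample(length(u), 6)) {
    up <- u; up[ii] <- up[ii] + eps
    um <- u; um[ii] <- um[ii] - eps
    fd <- (dirgan:::reg_with_grad(up, 1, 0.5, want_grad = FALSE)$value -
             dirgan:::reg_with_grad(um, 1, 0.5, want_grad = FALSE)$value) /
      (2 * eps)
    expect_equal(r$gu[ii], fd, tolerance = 1e-6)
  }
  a <- array(stats::runif(6^3), c(6, 6, 6))
  b <- array(stats::runif(6^3), c(6, 6, 6))
  gg <- dirgan:::gd_with_grad(a, b)
  for (ii in sample(length(a), 6)) {
    ap <- a; ap[ii] <- ap[ii] + eps
    am <- a; am[ii] <- am[ii] - eps
    fd <- (dirgan:::gd_with_grad(ap, b, want_grad = FALSE)$value -
             dirgan:::gd_with_grad(am, b, want_grad = FALSE)$value) / (2 * eps)
    expect_equal(gg$ga[ii], fd, tolerance = 1e-6)
  }
})
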