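test_that("generator meets its shape, determinism and identity contracts", {
  gcfg <- generator_config(base_filters = 2)
  gen <- generator_init(gcfg, seed = 1)
  mov <- array(stats::runif(16^3), c(16, 16, 16))
  tgt <- array(stats::runif(16^3), c(16, 16, 16))
  o1 <- generator_forward(mov, tgt, gen, gcfg)
  expect_equal(dim(o1$u), c(16, 16, 16, 3))
  o2 <- generator_forward(mov, tgt, gen, gcfg)
  expect_identical(o1$u, o2$u)
  # zero-initialized head -> exactly the zero field -> identity warp
  expect_identical(as.numeric(o1$u), rep(0, length(o1$u)))
  v <- rand_volume(c(16, 16, 16), seed = 2)
  expect_identical(warp(v, dvf(o1$u))$data, v$data)
  expect_error(generator_forward(mov, array(0, c(16, 16, 8)), gen, gcfg),
               "identical shape")
  expect_error(generator_forward(array(0, c(6, 6, 6)),
                                 array(0, c(6, 6, 6)), gen, gcfg),
               "divisible by 4")
})

test_that("attention gating bounds outputs by the skip features", {
  gcfg <- generator_config(base_filters = 2)
  gen <- generator_init(gcfg, seed = 3)
  set.seed(4)
  skip <- array(stats::rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  gate <- array(stats::rnorm(8 * 8 * 8 * 8), c(8, 8, 8, 8))
  a <- dirgan:::attention_fwd(skip, gate, gen$ag2)
  expect_true(all(abs(a$gated) <= abs(skip) + 1e-12))
  expect_true(all(a$s > 0 & a$s < 1))
  # forced all-ones / all-zeros map
  ones <- a; ones$s[] <- 1
  expect_equal(skip * as.numeric(ones$s[, , , 1]),
               skip, tolerance = 1e-12)
})

test_that("discriminator scores live strictly inside (0, 1)", {
  dcfg <- discriminator_config(base_filters = 2)
  disc <- discriminator_init(dcfg, seed = 5)
  img <- array(stats::runif(16^3, -1, 1), c(16, 16, 16))
  s1 <- discriminator_forward(img, disc, dcfg)$scores
  expect_true(all(s1 > 0 & s1 < 1))
  expect_gt(length(s1), 0)
  s2 <- discriminator_forward(img, disc, dcfg)$scores
  expect_identical(s1, s2)
  expect_error(discriminator_forward(array(0, c(16, 16, 2)), disc, dcfg),
               "divisible")
})

test_that("parameter counts are a pure function of the configuration", {
  count_for <- function(f) n_params(generator_init(generator_config(f), 1))
  # regression values computed from the layer table of the architecture
  expect_equal(count_for(2), 5509)
  expect_equal(count_for(4), 21685)
  expect_equal(count_for(8) > count_for(4), TRUE)
  expect_equal(n_params(discriminator_init(discriminator_config(2), 1)), 717)
})

test_that("generator backward matches finite differences on a tiny net", {
  gcfg <- generator_config(base_filters = 2)
  gen <- generator_init(gcfg, seed = 7)
  set.seed(5)
  gen$head$w <- stats::rnorm(length(gen$head$w), sd = 0.1)
  mov <- array(stats::runif(8^3), c(8, 8, 8))
  tgt <- array(stats::runif(8^3), c(8, 8, 8))
  fw <- generator_forward(mov, tgt, gen, gcfg, keep_cache = TRUE)
  set.seed(6)
  gu <- array(stats::rnorm(length(fw$u)), dim(fw$u))
  gr <- generator_backward(fw$cache, gu, gen, gcfg)
  L <- function(p) sum(generator_forward(mov, tgt, p, gcfg)$u * gu)
  eps <- 1e-6
  for (leaf in list(c("enc1a", "w"), c("bota", "w"), c("decb", "b"),
                    c("head", "w"))) {
    p0 <- gen[[leaf[1]]][[leaf[2]]]
    gl <- gr[[leaf[1]]][[if (leaf[2] == "w") "gw" else "gb"]]
    for (ii in sample(length(p0), 2)) {
      pp <- gen; pp[[leaf[1]]][[leaf[2]]][ii] <- p0[ii] + eps
      pm <- gen; pm[[leaf[1]]][[leaf[2]]][ii] <- p0[ii] - eps
      fd <- (L(pp) - L(pm)) / (2 * eps)
      expect_equal(gl[ii], fd, tolerance = 1e-4)
    }
  }
  # attention-gate parameters too
  p0 <- gen$ag1$psi$w
  for (ii in sample(length(p0), 2)) {
    pp <- gen; pp$ag1$psi$w[ii] <- p0[ii] + eps
    pm <- gen; pm$ag1$psi$w[ii] <- p0[ii] - eps
    fd <- (L(pp) - L(pm)) / (2 * eps)
    expect_equal(gr$ag1$psi$gw[ii], fd, tolerance = 1e-4)
  }
})

test_that("discriminator input gradient matches finite differences", {
  dcfg <- discriminator_config(base_filters = 2)
  disc <- discriminator_init(dcfg, seed = 8)
  set.seed(9)
  img <- array(stats::runif(8^3), c(8, 8, 8))
  fd1 <- discriminator_forward(img, disc, dcfg, keep_cache = TRUE)
  gs <- array(stats::rnorm(length(fd1$scores)), dim(fd1$scores))
  bb <- dirgan:::discriminator_backward(fd1$cache, gs, disc, dcfg)
  Ld <- function(im) sum(discriminator_forward(im, disc, dcfg)$scores * gs)
  eps <- 1e-6
  for (ii in sample(length(img), 5)) {
    ip <- img; ip[ii] <- ip[ii] + eps
    im2 <- img; im2[ii] <- im2[ii] - eps
    fdv <- (Ld(ip) - Ld(im2)) / (2 * eps)
    expect_equal(bb$g_input[ii], fdv, tolerance = 1e-5)
  }
})
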