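test_that("TRE reproduces the 3-4-5 case and zero-field identities", {
  z <- zero_dvf(c(16, 16, 16))
  a <- landmark_set("p", matrix(c(0, 0, 0), 1, 3))
  b <- landmark_set("p", matrix(c(3, 4, 0), 1, 3))
  expect_equal(unname(tre(a, b, z, spacing = c(1, 1, 1))), 5)
  set.seed(41)
  ls <- landmark_set(letters[1:4], matrix(stats::runif(12, 2, 10), 4, 3))
  expect_equal(unname(tre(ls, ls, z, spacing = c(1, 1, 1))), rep(0, 4))
  expect_error(tre(a, landmark_set("q", matrix(0, 1, 3)), z), "labels")
})

test_that("TRE propagates through a constant field by its analytic inverse", {
  dims <- c(16, 16, 16)
  u <- array(0, c(dims, 3)); u[, , , 1] <- 2
  d <- dvf(u, spacing = c(1, 1, 1))
  # backward-mapping +2 translation: a moving landmark at x appears at x - 2
  mv <- landmark_set("p", matrix(c(8, 8, 8), 1, 3))
  tg <- landmark_set("p", matrix(c(6, 8, 8), 1, 3))
  expect_equal(unname(tre(mv, tg, d, spacing = c(1, 1, 1))), 0,
               tolerance = 1e-3)
  # and against a deliberately offset target
  tg2 <- landmark_set("p", matrix(c(8, 8, 8), 1, 3))
  expect_equal(unname(tre(mv, tg2, d, spacing = c(1, 1, 1))), 2,
               tolerance = 1e-3)
})

test_that("masked MAE and NCC match brute-force loops", {
  set.seed(42)
  dims <- c(8, 8, 8)
  a <- rand_volume(dims, seed = 43)
  b <- rand_volume(dims, seed = 44)
  m <- mask(array(stats::runif(prod(dims)) > 0.4, dims))
  expect_equal(mae(a, a, m), 0)
  expect_equal(mae(volume(a$data + 10), a, m), 10, tolerance = 1e-12)
  sel <- which(m$data)
  expect_equal(mae(a, b, m), mean(abs(a$data[sel] - b$data[sel])),
               tolerance = 1e-12)
  av <- a$data[sel] - mean(a$data[sel])
  bv <- b$data[sel] - mean(b$data[sel])
  expect_equal(ncc_metric(a, b, m),
               sum(av * bv) / sqrt(sum(av^2) * sum(bv^2)), tolerance = 1e-12)
  expect_equal(ncc_metric(a, a, m), 1, tolerance = 1e-12)
  neg <- volume(-(a$data - mean(a$data[sel])) + 7)
  expect_equal(ncc_metric(neg, a, m), -1, tolerance = 1e-12)
  expect_error(mae(a, b, mask(array(0, dims))), "empty")
})

test_that("Dice behaves on identical, disjoint and half-overlapping masks", {
  dims <- c(10, 10, 10)
  A <- array(0, dims); A[1:5, , 1:2] <- 1
  B <- array(0, dims); B[6:10, , 1:2] <- 1
  expect_equal(dsc(mask(A), mask(A)), 1)
  expect_equal(dsc(mask(A), mask(B)), 0)
  expect_equal(dsc(mask(A), mask(B)), dsc(mask(B), mask(A)))
  # |A| = |B| = 100, overlap 50
  A2 <- array(0, dims); A2[1:10, 1:10, 1] <- 1
  B2 <- array(0, dims); B2[1:10, 1:10, 2] <- 1
  B2[1:5, 1:10, 1] <- 1; B2[1:10, 1:5, 2] <- 0
  expect_equal(sum(A2), 100)
  expect_equal(sum(B2), 100)
  expect_equal(dsc(mask(A2), mask(B2)), 2 * 50 / 200)
  expect_error(dsc(mask(array(0, dims)), mask(array(0, dims))), "empty")
})

test_that("regularity report hits its closed forms", {
  dims <- c(10, 10, 10)
  full <- mask(array(1, dims))
  r0 <- regularity_report(zero_dvf(dims), full)
  expect_equal(r0$jacobian_index, 0)
  expect_equal(r0$pct_nonpositive, 0)
  # uniform expansion: constant det -> zero spread, no folding
  X <- array(rep(0:9, 100), dims)
  Y <- array(rep(rep(0:9, each = 10), 10), dims)
  Z <- array(rep(0:9, each = 100), dims)
  ue <- array(0, c(dims, 3))
  ue[, , , 1] <- 0.1 * X; ue[, , , 2] <- 0.1 * Y; ue[, , , 3] <- 0.1 * Z
  interior <- array(0, dims); interior[2:9, 2:9, 2:9] <- 1
  re <- regularity_report(dvf(ue), mask(interior))
  expect_equal(re$jacobian_index, 0, tolerance = 1e-9)
  expect_equal(re$pct_nonpositive, 0)
  uf <- array(0, c(dims, 3)); uf[, , , 1] <- -2 * X
  rf <- regularity_report(dvf(uf), mask(interior))
  expect_equal(rf$pct_nonpositive, 1)
})

test_that("difference profiles index the right line", {
  a <- rand_volume(c(8, 10, 6), seed = 45)
  b <- rand_volume(c(8, 10, 6), seed = 46)
  expect_equal(difference_profile(a, a, 2, c(3, 4)), rep(0, 10))
  off <- volume(a$data + 12)
  expect_equal(difference_profile(off, a, 1, c(2, 5)), rep(12, 8))
  pr <- difference_profile(a, b, 3, c(4, 7))
  expect_equal(pr, abs(a$data[4, 7, ] - b$data[4, 7, ]))
  expect_error(difference_profile(a, b, 2, c(9, 1)), "bounds")
})
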