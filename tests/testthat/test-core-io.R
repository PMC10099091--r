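test_that("volume and DVF constructors enforce their invariants", {
  expect_error(volume(array(1, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(volume(array(1, c(4, 4, 4)), c(1, -1, 1)), "positive")
  expect_error(volume(array(c(NA, rep(1, 63)), c(4, 4, 4))), "finite")
  expect_error(dvf(array(0, c(4, 4, 4, 2))), "3 components")
  v <- volume(array(0, c(4, 4, 4)), spacing = c(0.9, 0.9, 2))
  expect_equal(v$spacing, c(0.9, 0.9, 2))
  expect_error(landmark_set(c("a", "a"), matrix(0, 2, 3)), "unique")
})

test_that("NIfTI volumes round-trip data, spacing and origin", {
  v <- rand_volume(c(16, 16, 8), seed = 7)
  v <- volume(v$data, spacing = c(0.9, 0.9, 2.0), origin = c(5, 10, 15))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path, "nifti")
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$spacing, c(0.9, 0.9, 2.0), tolerance = 1e-6)
  expect_equal(r$origin, c(5, 10, 15), tolerance = 1e-5)
  expect_error(read_volume(tempfile(fileext = ".nii"), "nifti"), "no such file")
})

test_that("MetaImage volumes round-trip in both .mha and .mhd forms", {
  v <- rand_volume(c(12, 10, 6), seed = 8)
  v <- volume(round(v$data), spacing = c(1.5, 1.5, 3), origin = c(-4, 0, 2))
  for (ext in c(".mha", ".mhd")) {
    path <- file.path(tempdir(), paste0("vol", ext))
    write_volume(v, path)
    r <- read_volume(path, "metaimage")
    expect_identical(r$data, v$data)
    expect_equal(r$spacing, v$spacing)
    expect_equal(r$origin, v$origin)
  }
})

test_that("DICOM series round-trip and missing-slice detection work", {
  v <- rand_volume(c(12, 10, 6), lo = -1000, hi = 1500, seed = 9)
  v <- volume(round(v$data), spacing = c(0.9, 0.9, 2.0), origin = c(0, 0, 10))
  dir1 <- file.path(tempdir(), "dcm_ok")
  unlink(dir1, recursive = TRUE)
  dirgan:::write_dicom_series(v, dir1)
  r <- read_volume(dir1, "dicom_series")
  expect_identical(r$data, v$data)
  expect_equal(r$spacing, c(0.9, 0.9, 2.0))
  # remove a middle slice -> inconsistent spacing must be flagged
  file.remove(file.path(dir1, "slice_003.dcm"))
  expect_error(read_volume(dir1, "dicom_series"), "spacing")
})

test_that("DVFs round-trip as 4D NIfTI with spacing", {
  d <- rand_dvf(c(8, 6, 4), seed = 10)
  d <- dvf(d$u, spacing = c(2, 2, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_dvf(d, path)
  r <- read_dvf(path)
  expect_equal(r$u, d$u, tolerance = 1e-6)
  expect_equal(r$spacing, c(2, 2, 2), tolerance = 1e-6)
})

test_that("HU-threshold masks follow the strict > rule", {
  dims <- c(8, 8, 8)
  expect_equal(sum(body_mask(volume(array(-1000, dims)))$data), 0)
  expect_equal(sum(body_mask(volume(array(0, dims)))$data), prod(dims))
  expect_equal(sum(bone_mask(volume(array(0, dims)))$data), 0)
  expect_equal(sum(bone_mask(volume(array(500, dims)))$data), prod(dims))
  # half at -500, half at +50: brute-force voxel count
  arr <- array(-500, dims)
  arr[1:4, , ] <- 50
  v <- volume(arr)
  cnt <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if (arr[i, j, k] > -300) cnt <- cnt + 1
  expect_equal(sum(body_mask(v)$data), cnt)
  expect_equal(cnt, 4 * 8 * 8)
})

test_that("body mask is monotone in the threshold and contains the bone mask", {
  v <- rand_volume(c(10, 10, 10), lo = -1200, hi = 1200, seed = 11)
  thresholds <- c(-600, -300, 0, 300, 600)
  counts <- vapply(thresholds, function(t) sum(body_mask(v, t)$data), 0)
  expect_true(all(diff(counts) <= 0))
  bm <- body_mask(v)$data
  km <- bone_mask(v)$data
  expect_true(all(bm[km]))
})

test_that("landmark CSVs round-trip and reject duplicates", {
  ls <- landmark_set(c("a", "b", "c", "d"),
                     matrix(stats::rnorm(12), 4, 3))
  path <- tempfile(fileext = ".csv")
  write_landmarks(ls, path)
  r <- read_landmarks(path)
  expect_equal(r$labels, ls$labels)
  expect_equal(unname(r$coords), unname(ls$coords), tolerance = 1e-12)
  # header-only file -> empty set
  writeLines("label,x_mm,y_mm,z_mm", path)
  expect_equal(length(read_landmarks(path)), 0)
  writeLines(c("label,x_mm,y_mm,z_mm", "a,1,2,3", "a,4,5,6"), path)
  expect_error(read_landmarks(path), "unique")
})
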