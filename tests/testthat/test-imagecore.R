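test_that("NIfTI round-trip preserves data and grid metadata", {
  set.seed(3)
  aff <- diag(c(0.1, 0.1, 0.5, 1))
  aff[1:3, 4] <- c(-0.75, -0.75, -3.75)
  v <- scalar_volume(array(rnorm(16^3), c(16, 16, 16)), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, "scalar")
  expect_equal(r$data, v$data, ignore_attr = TRUE)
  expect_equal(r$affine, v$affine, tolerance = 1e-6)
  expect_equal(r$spacing, c(0.1, 0.1, 0.5), tolerance = 1e-6)

  l <- random_labels(ids = c(0L, 1L, 88L))
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(l, fl)
  rl <- read_volume(fl, "label")
  expect_identical(rl$data, l$data)
  expect_identical(labels_present(rl), c(1L, 88L))
})

test_that("label files with non-integral values are rejected", {
  v <- scalar_volume(array(c(2.5, rep(1, 26)), c(3, 3, 3)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  expect_error(read_volume(f, "label"), "non-integral")
  expect_error(read_volume(file.path(tempdir(), "nope.nii"), "scalar"),
               "not found")
})

test_that("phantom label volumes round-trip with the generator's region set", {
  bp <- small_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(bp$labels, f)
  r <- read_volume(f, "label")
  expect_identical(labels_present(r), sort(small_spec()$labels))
})

test_that("shipped lookup table has the 27-region nomenclature", {
  lut <- default_label_lut()
  expect_equal(nrow(lut), 27L)
  expect_false(anyDuplicated(lut$label_id) > 0)
  expect_identical(lut$label_id[1:2], c(1L, 2L))
  expect_identical(lut$label_id[27], 88L)
  expect_match(lut$region_name[lut$label_id == 84], "Brain stem")
  # round-trip through the TSV writer
  f <- withr::local_tempfile(fileext = ".tsv")
  write_label_lut(lut, f)
  expect_identical(read_label_lut(f), lut)
})

test_that("identity resampling reproduces the input", {
  v <- random_scalar()
  r <- resample(v, as_grid(v))
  expect_equal(r$data, v$data, ignore_attr = TRUE)
  l <- random_labels()
  rl <- resample(l, as_grid(l))
  expect_identical(rl$data, l$data)
})

test_that("label resampling never creates new labels and rejects trilinear", {
  l <- random_labels(ids = c(0L, 2L, 5L, 9L), seed = 4)
  t <- linear_transform("affine", c(0.3, -0.7, 1.1, 0.1, -0.05, 0.2,
                                    1.04, 0.96, 1.02))
  r <- resample(l, as_grid(l), t)
  expect_true(all(labels_present(r, include_background = TRUE) %in%
                  labels_present(l, include_background = TRUE)))
  expect_error(resample(l, as_grid(l), interp = "trilinear"),
               "nearest-neighbour")
})

test_that("half-voxel translation of a ramp shifts values by half an increment", {
  g <- grid_spec(c(16, 16, 16), 1)
  ramp <- array(rep(0:15, times = 16 * 16), c(16, 16, 16))
  v <- scalar_volume(ramp, affine = g$affine)
  r <- resample(v, g, linear_transform("rigid", c(0.5, 0, 0, 0, 0, 0)))
  expect_equal(r$data[2:15, , ], ramp[2:15, , ] + 0.5, ignore_attr = TRUE)
})

test_that("gaussian blur matches the analytic kernel and conserves mean", {
  # fwhm 0 and constant input are identities
  v <- random_scalar(c(12, 12, 12))
  expect_equal(gaussian_blur(v, 0)$data, v$data, ignore_attr = TRUE)
  cv <- scalar_volume(array(3.5, c(12, 12, 12)), spacing = 0.2)
  expect_equal(gaussian_blur(cv, 1)$data, cv$data, tolerance = 1e-10,
               ignore_attr = TRUE)
  # delta impulse at 0.1 mm spacing, 1 mm FWHM -> sigma 4.2466 voxels
  d <- array(0, c(41, 41, 41)); d[21, 21, 21] <- 1
  b <- gaussian_blur(scalar_volume(d, spacing = 0.1), 1)
  sigma_expect <- 1 / (0.1 * 2 * sqrt(2 * log(2)))
  expect_equal(sigma_expect, 4.2466, tolerance = 1e-4)
  prof <- b$data[, 21, 21]
  ref <- exp(-0.5 * ((1:41 - 21) / sigma_expect)^2)
  ref <- ref / sum(exp(-0.5 * ((-170:170) / sigma_expect)^2))  # kernel norm
  expect_equal(prof / max(prof), ref / max(ref), tolerance = 1e-3)
  # mean conservation under reflective boundary
  expect_equal(mean(gaussian_blur(random_scalar(c(16, 16, 16), seed = 9), 2)$data),
               mean(random_scalar(c(16, 16, 16), seed = 9)$data),
               tolerance = 1e-6)
  expect_error(gaussian_blur(v, -1), "non-negative")
})

test_that("blur then downsample agrees with downsample of the blurred volume", {
  v <- gaussian_blur(random_scalar(c(24, 24, 24), seed = 11, spacing = 0.5), 2)
  coarse <- grid_spec(c(12, 12, 12), 1)
  a <- resample(gaussian_blur(v, 1), coarse)
  b <- gaussian_blur(resample(v, coarse), 1)
  # the orderings agree on smooth inputs away from the boundary
  expect_lt(max(abs(a$data[3:10, 3:10, 3:10] - b$data[3:10, 3:10, 3:10])) /
            diff(range(v$data)), 0.06)
})

test_that("volume constructors enforce their invariants", {
  expect_error(scalar_volume(array(1, c(4, 4))), "3-D")
  expect_error(label_volume(array(1.5, c(4, 4, 4))), "integral")
  expect_error(label_volume(array(-1L, c(4, 4, 4))), "non-negative")
  expect_error(scalar_volume(array(NA_real_, c(4, 4, 4))), "NA")
  expect_error(grid_spec(c(4, 4, 4), spacing = c(1, 0, 1)), "positive")
})
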