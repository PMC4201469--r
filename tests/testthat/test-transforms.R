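test_that("rigid matrices are rotations and affine has 9 DOF", {
  t <- linear_transform("rigid", c(1, -2, 3, 0.2, -0.1, 0.3))
  R <- t$matrix[1:3, 1:3]
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_error(linear_transform("rigid", rep(0, 9)), "6 parameters")
  expect_error(linear_transform("affine", rep(0, 6)), "9 parameters")
})

test_that("chain application equals sequential application", {
  set.seed(5)
  a <- linear_transform("rigid", c(0.4, -0.2, 0.1, 0.05, -0.02, 0.1))
  b <- linear_transform("affine", c(-0.3, 0.5, 0.2, 0, 0.1, -0.05,
                                    1.05, 0.95, 1.02))
  f <- deformation_field(array(rnorm(5^3 * 3, sd = 0.1), c(5, 5, 5, 3)),
                         spacing = 4)
  pts <- matrix(runif(300, -5, 5), 100, 3)
  chain <- transform_chain(a, f, b)
  seq_pts <- apply_transform(b, apply_transform(f, apply_transform(a, pts)))
  expect_equal(apply_transform(chain, pts), seq_pts, tolerance = 1e-9)
  # compose flattens and merges adjacent linears into the matrix product
  comp <- compose(a, b)
  expect_length(comp$transforms, 1L)
  expect_equal(comp$transforms[[1]]$matrix, b$matrix %*% a$matrix,
               tolerance = 1e-12)
  expect_equal(apply_transform(comp, pts), apply_transform(b, apply_transform(a, pts)),
               tolerance = 1e-9)
  # composed mixed chain still matches sequential application
  comp2 <- compose(a, b, f)
  expect_equal(apply_transform(comp2, pts),
               apply_transform(f, apply_transform(b, apply_transform(a, pts))),
               tolerance = 1e-6)
  # empty chain is the identity
  expect_equal(apply_transform(transform_chain(), pts), pts)
})

test_that("linear inversion is exact and chains invert element-wise", {
  a <- linear_transform("affine", c(0.4, -0.2, 0.1, 0.05, -0.02, 0.1,
                                    1.1, 0.9, 1.05))
  pts <- matrix(runif(60, -5, 5), 20, 3)
  round_trip <- apply_transform(invert(a), apply_transform(a, pts))
  expect_equal(round_trip, pts, tolerance = 1e-10)
})

test_that("pure translation fields invert to the negated translation", {
  d <- array(0, c(6, 6, 6, 3)); d[, , , 1] <- 0.4
  f <- deformation_field(d, spacing = 2)
  fi <- invert(f)
  expect_equal(max(abs(fi$displacement[, , , 1] + 0.4)), 0, tolerance = 1e-6)
  expect_equal(max(abs(fi$displacement[, , , 2:3])), 0, tolerance = 1e-9)
  # identity field inverts to identity
  z <- deformation_field(array(0, c(4, 4, 4, 3)), spacing = 2)
  expect_equal(max(abs(invert(z)$displacement)), 0)
})

test_that("random smooth fields invert below the fixed-point tolerance", {
  g <- grid_spec(c(24, 24, 24), 0.5)
  for (s in 1:3) {
    set.seed(s)
    f <- atlasseg:::random_smooth_field(g, 1, 3)
    fi <- invert(f)
    idx <- atlasseg:::grid_index_matrix(c(24L, 24L, 24L))
    pts <- voxel_to_world(g, idx)
    # contract order: t o invert(t), measured on the field grid
    resid <- apply_transform(f, apply_transform(fi, pts)) - pts
    expect_lt(max(sqrt(rowSums(resid^2))), 0.05)
    # involution: inverting twice returns close to the original field
    fii <- invert(fi)
    expect_lt(max(abs(fii$displacement - f$displacement)), 0.1)
  }
})

test_that("folded fields are rejected by inversion", {
  # displacement gradient < -1 along x folds space
  d <- array(0, c(9, 9, 9, 3))
  d[, , , 1] <- -1.6 * (rep(0:8, 81) - 4)
  f <- deformation_field(d, spacing = 1)
  expect_error(invert(f), "folds")
})

test_that("transforms round-trip through their file formats", {
  dir <- withr::local_tempdir()
  a <- linear_transform("affine", c(0.4, -0.2, 0.1, 0.05, -0.02, 0.1,
                                    1.1, 0.9, 1.05))
  fa <- file.path(dir, "aff.txt")
  write_transform(a, fa)
  ra <- read_transform(fa)
  expect_equal(ra$matrix, a$matrix, tolerance = 1e-12)
  expect_identical(ra$kind, "affine")

  set.seed(2)
  f <- deformation_field(array(rnorm(4^3 * 3, sd = 0.2), c(4, 4, 4, 3)),
                         spacing = 4)
  ff <- file.path(dir, "field.nii.gz")
  write_transform(f, ff)
  rf <- read_transform(ff)
  expect_equal(rf$displacement, f$displacement, ignore_attr = TRUE)
  expect_equal(rf$affine, f$affine, tolerance = 1e-6)

  ch <- transform_chain(f, a)
  fc <- file.path(dir, "chain.json")
  write_transform(ch, fc)
  rc <- read_transform(fc)
  pts <- matrix(runif(30, -3, 3), 10, 3)
  expect_equal(apply_transform(rc, pts), apply_transform(ch, pts),
               tolerance = 1e-6)
})
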