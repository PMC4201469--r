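# Fast similarity-metric properties plus single-case registration checks;
# the seeded multi-trial recovery battery lives in the acceptance tests.

test_that("mutual information has its self-identity and independence bounds", {
  a <- random_scalar(c(22, 22, 22), seed = 1)
  # MI(a, a) with hard binning equals the marginal histogram entropy
  mi_aa <- similarity_mi(a, a, bins = 16)
  counts <- tabulate(pmin(16L, 1L + floor(
    (as.numeric(a$data) - min(a$data)) / diff(range(a$data)) * 16)), 16)
  p <- counts / sum(counts)
  expect_equal(mi_aa, -sum(p[p > 0] * log2(p[p > 0])), tolerance = 1e-8)
  # independent uniform noise, >= 1e4 voxels: MI below the sampling bound
  u1 <- scalar_volume(array(runif(22^3), c(22, 22, 22)))
  u2 <- scalar_volume(array(runif(22^3), c(22, 22, 22)))
  expect_lt(similarity_mi(u1, u2, bins = 16), 0.05)
  # symmetry
  expect_equal(similarity_mi(u1, u2), similarity_mi(u2, u1), tolerance = 1e-10)
  # invariance under bijective intensity relabeling at fixed binning:
  # reverse all intensities of one argument
  b <- scalar_volume(max(a$data) + min(a$data) - a$data, affine = a$affine)
  expect_equal(similarity_mi(a, u1, bins = 16), similarity_mi(b, u1, bins = 16),
               tolerance = 1e-10)
  expect_error(similarity_mi(a, random_scalar(c(8, 8, 8))), "share one grid")
})

test_that("cross-correlation behaves like a Pearson correlation", {
  a <- random_scalar(c(10, 10, 10), seed = 2)
  neg <- scalar_volume(-a$data, affine = a$affine)
  shifted <- scalar_volume(a$data + 11.3, affine = a$affine)
  expect_equal(similarity_cc(a, a), 1)
  expect_equal(similarity_cc(a, neg), -1)
  expect_equal(similarity_cc(a, shifted), 1)
  const <- scalar_volume(array(2, c(10, 10, 10)))
  expect_error(similarity_cc(a, const), "degenerate")
  # masked evaluation
  m <- array(FALSE, c(10, 10, 10)); m[3:8, 3:8, 3:8] <- TRUE
  expect_equal(similarity_cc(a, a, mask = m), 1)
})

test_that("self-registration returns near-identity", {
  bp <- small_phantom()
  for (kind in c("rigid", "affine")) {
    t <- register_linear(bp$mri, bp$mri, kind = kind,
                         fwhm = c(1, 0.5), stride = 2L,
                         maxit = c(200L, 200L), restarts = 2L)
    expect_lt(max(abs(t$params[1:3])), 0.02)
    expect_lt(max(abs(t$params[4:6])), 0.002)
    if (kind == "affine") expect_lt(max(abs(t$params[7:9] - 1)), 0.002)
  }
  const <- scalar_volume(array(1, c(8, 8, 8)))
  expect_error(register_linear(const, const), "degenerate")
})

test_that("a known translation is recovered within a twentieth of a voxel", {
  spec <- small_spec()
  clean <- make_base_phantom(spec, noise = FALSE)
  t_true <- linear_transform("rigid", c(0.5, -0.3, 0.2, 0, 0, 0))
  moved <- resample(clean$mri, as_grid(clean$mri), t_true)
  set.seed(5)
  moved <- scalar_volume(moved$data + rnorm(length(moved$data), 0, spec$noise_sigma),
                         affine = moved$affine)
  base <- scalar_volume(clean$mri$data + rnorm(length(clean$mri$data), 0, spec$noise_sigma),
                        affine = clean$mri$affine)
  rec <- register_linear(moved, base, kind = "rigid")
  # pull-back of registering moved onto base is the inverse of t_true
  expect_lt(max(abs(rec$params[1:3] - c(-0.5, 0.3, -0.2))), 0.05)
  expect_lt(max(abs(rec$params[4:6])), 0.005)
})

test_that("non-linear registration of identical images stays near zero", {
  bp <- small_phantom()
  sched <- nl_schedule(fwhm = c(1, 0.5), spacing = c(2, 1),
                       iters = c(30L, 20L), stride = c(2L, 2L))
  init <- identity_transform()
  ch <- register_nonlinear(bp$mri, bp$mri, schedule = sched, init = init)
  field <- ch$transforms[[1]]
  mag <- sqrt(apply(field$displacement^2, 1:3, sum))
  expect_lt(max(mag), 0.05)
  expect_error(register_nonlinear(bp$mri, bp$mri, schedule = sched),
               "init")
  expect_error(nl_schedule(fwhm = c(1, 0.5), spacing = 1.6), "equal lengths")
})

test_that("non-linear registration increases cross-correlation", {
  spec <- small_spec()
  cohort <- fixture("small_cohort", make_cohort(spec, 4L))
  a <- cohort$atlases$entries[[1]]
  b <- cohort$atlases$entries[[2]]
  aff <- register_linear(a$mri, b$mri, kind = "affine", fwhm = c(1, 0.5),
                         stride = 2L, maxit = c(200L, 150L), restarts = 1L)
  sched <- nl_schedule(fwhm = c(1, 0.5), spacing = c(2, 1),
                       iters = c(40L, 30L), stride = c(2L, 2L))
  ch <- register_nonlinear(a$mri, b$mri, schedule = sched, init = aff)
  before <- similarity_cc(b$mri, resample(a$mri, as_grid(b$mri), aff))
  after <- similarity_cc(b$mri, resample(a$mri, as_grid(b$mri), ch))
  expect_gte(after, before)
  # the per-level optimizer never decreased its own objective
  for (tr in attr(ch, "objective")) expect_gte(tr["end"], tr["start"] - 1e-12)
})
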