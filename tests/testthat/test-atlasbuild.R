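test_that("label fusion equals the per-voxel histogram-argmax oracle", {
  for (s in 1:10) {
    vols <- lapply(1:5, function(k)
      random_labels(dim = c(6L, 6L, 6L), ids = 0:3, seed = s * 10 + k))
    fused <- fuse_labels(vols)
    expect_identical(fused$data, brute_fuse(vols)$data)
  }
  # forced even-voter ties exercise the tie policy
  for (s in 1:10) {
    vols <- lapply(1:4, function(k)
      random_labels(dim = c(5L, 5L, 5L), ids = 0:2, seed = 400 + s * 10 + k))
    expect_identical(fuse_labels(vols)$data, brute_fuse(vols)$data)
  }
})

test_that("fusion respects majority, ties and permutation invariance", {
  mk <- function(v) label_volume(array(v, c(1, 1, 1)))
  # votes 1,1,1,2,2,0,0 -> strict majority 1
  expect_equal(as.integer(fuse_labels(lapply(c(1, 1, 1, 2, 2, 0, 0), mk))$data), 1L)
  # tie 1,1,2,2 -> smallest competing nonzero id
  expect_equal(as.integer(fuse_labels(lapply(c(1, 1, 2, 2), mk))$data), 1L)
  # nonzero preferred over background on ties
  expect_equal(as.integer(fuse_labels(lapply(c(0, 0, 5, 5), mk))$data), 5L)
  # all inputs identical -> identity
  v <- random_labels(ids = 0:4, seed = 3)
  expect_identical(fuse_labels(list(v, v, v))$data, v$data)
  # permutation invariance
  vols <- lapply(1:5, function(k) random_labels(ids = 0:3, seed = 50 + k))
  expect_identical(fuse_labels(vols)$data, fuse_labels(rev(vols))$data)
  # the winning label's vote count is maximal at every voxel
  fused <- fuse_labels(vols)
  stack <- vapply(vols, function(v) as.integer(v$data), integer(512))
  for (i in seq(1, 512, by = 37)) {
    counts <- table(stack[i, ])
    expect_equal(unname(counts[as.character(fused$data[i])]),
                 max(counts), ignore_attr = TRUE)
  }
  expect_error(fuse_labels(list(v, random_labels(spacing = 2))),
               "share one grid")
})

test_that("template building is a fixed point for identical inputs", {
  bp <- small_phantom()
  mris <- list(a = bp$mri, b = bp$mri, c = bp$mri)
  space <- build_template(mris, initial_target = 1L,
                          grid = as_grid(bp$mri), iterations = 1L,
                          fwhm = c(1, 0), stride = 2L,
                          maxit = c(60L, 60L), restarts = 1L)
  norm_ref <- atlasseg:::normalize_foreground_mean(bp$mri)
  # intensity-normalized average of self-registered copies reproduces the input
  expect_equal(mean(abs(space$template$data - norm_ref$data)) /
               diff(range(norm_ref$data)), 0, tolerance = 0.02)
  expect_error(build_template(mris[1]), "at least two")
})

test_that("template output grid follows the requested specification", {
  bp <- small_phantom()
  g <- default_template_grid()
  expect_identical(g$dim, c(256L, 256L, 225L))
  expect_equal(g$spacing, rep(0.1, 3))
  space <- build_template(list(a = bp$mri, b = bp$mri), initial_target = 1L,
                          grid = g, iterations = 1L, fwhm = 0, stride = 12L,
                          maxit = 20L, restarts = 1L)
  expect_identical(dim(space$template$data), c(256L, 256L, 225L))
  expect_equal(space$template$spacing, rep(0.1, 3), tolerance = 1e-9)
})

test_that("maximum-probability atlas equals resample-then-fuse decomposition", {
  spec <- small_spec()
  cohort <- fixture("small_cohort", make_cohort(spec, 4L))
  entries <- cohort$atlases$entries
  grid <- as_grid(entries[[1]]$mri)
  # use the ground-truth generating chains as the registration transforms:
  # they map subject space to canonical space, so their inverses map
  # canonical->subject; here we only need consistency, not accuracy
  transforms <- lapply(cohort$truth, `[[`, "chain")
  space <- structure(list(template = cohort$base$mri,
                          transforms = transforms),
                     class = "template_space")
  ids <- names(entries)
  names(transforms) <- ids
  space$transforms <- transforms
  mp <- build_max_probability_atlas(cohort$atlases, space)
  moved <- lapply(ids, function(id)
    resample(entries[[id]]$labels, grid, transforms[[id]], "nearest"))
  manual <- fuse_labels(moved)
  expect_identical(mp$data, manual$data)
  # the fused label set never exceeds the union of input label sets
  expect_true(all(labels_present(mp) %in%
                  sort(unique(unlist(lapply(entries, function(e)
                    labels_present(e$labels)))))))
  # single-entry set: atlas equals that entry's resampled labels
  one <- atlas_set(entries[1], lut = spec$lut)
  mp1 <- build_max_probability_atlas(one, space)
  expect_identical(mp1$data, moved[[1]]$data)
  # missing transform is a contract error
  space$transforms <- transforms[-1]
  expect_error(build_max_probability_atlas(cohort$atlases, space),
               "no template transform")
})
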