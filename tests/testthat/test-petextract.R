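test_that("SUV conversion follows the body-weight definition", {
  # uniform concentration equal to dose/weight -> SUV 1 everywhere
  conc <- 12100 / 300  # kBq/mL
  pet <- scalar_volume(array(conc, c(8, 8, 8)), spacing = 0.5)
  st <- pet_study(pet, injected_dose_mbq = 12.1, body_weight_g = 300)
  expect_equal(unique(as.numeric(suv_convert(st)$data)), 1, tolerance = 1e-12)
  # hand arithmetic: 4.0333 kBq/mL, 300 g, 12.1 MBq -> SUV 0.1
  pet2 <- scalar_volume(array(4.0333, c(4, 4, 4)), spacing = 0.5)
  st2 <- pet_study(pet2, 12.1, 300)
  expect_equal(unique(as.numeric(suv_convert(st2)$data)), 0.1,
               tolerance = 1e-4)
  # zero activity maps to SUV 0; linearity in concentration and dose
  expect_equal(max(abs(suv_convert(pet_study(
    scalar_volume(array(0, c(4, 4, 4))), 12.1, 300))$data)), 0)
  st3 <- pet_study(pet2, 2 * 12.1, 300)
  expect_equal(suv_convert(st3)$data, suv_convert(st2)$data / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(pet_study(pet, -1, 300), "dose")
  expect_error(pet_study(pet, 12.1, 0), "weight")
})

test_that("regional extraction equals the voxel-loop oracle", {
  set.seed(8)
  suv <- random_scalar(c(8, 8, 8), seed = 8)
  labs <- random_labels(ids = 0:3, seed = 9)
  tab <- extract_regional(suv, labs)
  for (id in 1:3) {
    acc <- 0; n <- 0
    for (i in seq_along(labs$data)) {
      if (labs$data[i] == id) { acc <- acc + suv$data[i]; n <- n + 1 }
    }
    expect_equal(tab$mean_suv[tab$label_id == id], acc / n,
                 tolerance = 1e-12)
    expect_equal(tab$n_voxels[tab$label_id == id], n)
  }
  # piecewise-constant SUV matching labels -> means equal the constants
  vals <- c(0.3, 1.2, 2.4, 0.9)
  pc <- scalar_volume(array(vals[labs$data + 1L], dim(labs$data)),
                      affine = labs$affine)
  tab2 <- extract_regional(pc, labs)
  expect_equal(tab2$mean_suv, vals[tab2$label_id + 1L], tolerance = 1e-12)
  # single-voxel region
  one <- labs$data; one[one == 3L] <- 0L; one[1, 1, 1] <- 3L
  labs1 <- label_volume(one, affine = labs$affine)
  t3 <- extract_regional(suv, labs1)
  expect_equal(t3$mean_suv[t3$label_id == 3], suv$data[1, 1, 1])
  # lut-listed empty regions are flagged with zero counts
  lut <- data.frame(label_id = c(1L, 2L, 3L, 7L),
                    region_name = c("a", "b", "c", "ghost"))
  t4 <- extract_regional(suv, labs, lut = lut)
  expect_equal(t4$n_voxels[t4$label_id == 7], 0L)
  expect_true(is.na(t4$mean_suv[t4$label_id == 7]))
})

test_that("agreement regression matches the normal-equations oracle", {
  set.seed(0)
  manual <- data.frame(label_id = 1:10,
                       mean_suv = runif(10, 0.5, 2.5))
  auto <- data.frame(label_id = 1:10,
                     mean_suv = 0.98 * manual$mean_suv + 0.03 +
                       rnorm(10, 0, 0.02))
  fit <- agreement_regression(auto, manual)
  X <- cbind(1, manual$mean_suv)
  beta <- solve(t(X) %*% X, t(X) %*% auto$mean_suv)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  pred <- X %*% beta
  r2 <- 1 - sum((auto$mean_suv - pred)^2) /
    sum((auto$mean_suv - mean(auto$mean_suv))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  # exact agreement and exact doubling (lm warns about the perfect fit)
  same <- suppressWarnings(agreement_regression(manual, manual))
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(same$r_squared, 1, tolerance = 1e-12)
  dbl <- suppressWarnings(
    agreement_regression(transform(manual, mean_suv = 2 * mean_suv), manual))
  expect_equal(dbl$slope, 2, tolerance = 1e-12)
  expect_error(agreement_regression(manual[1:2, ], manual[1:2, ]),
               "at least three")
})

test_that("aligned PF extraction reproduces ground-truth activities exactly", {
  # PET simulated in perfect alignment with its phantom, no PSF blur:
  # extracting through the true labels returns the regional constants
  spec <- small_spec(noise_sigma = 0, pet_psf_fwhm_mm = 0)
  spec$pet_dim <- spec$dim; spec$pet_spacing <- spec$spacing
  bp <- make_base_phantom(spec)
  act <- stats::setNames(seq(30, 90, length.out = spec$n_regions),
                         spec$labels)
  st <- make_pet(bp, spec, act, injected_dose_mbq = 12.1,
                 body_weight_g = 300, background_activity = 0)
  suv <- suv_convert(st)
  tab <- extract_regional(suv, bp$labels)
  expect_equal(tab$mean_suv[match(spec$labels, tab$label_id)],
               unname(act) * 300 / 12100, tolerance = 1e-10)
})
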