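test_that("noiseless blur-free brain image is exactly piecewise constant", {
  sim <- gen_brain_pet(bg_suv = 1.0,
                       lesions = list(lesion_spec(c(17, 17, 17), 10, 4)),
                       scanner = scanner_profile(0, 0),
                       grid_shape = c(33, 33, 33), seed = 1)
  expect_true(all(sim$image$values[sim$lesion_mask] == 4.0))
  expect_true(all(sim$image$values[!sim$lesion_mask] == 1.0))
  expect_gt(sum(sim$lesion_mask), 0)
})

test_that("background noise has the requested mean and generators are deterministic", {
  sim <- gen_brain_pet(bg_suv = 1.0, lesions = list(),
                       scanner = scanner_profile(0, 0.05),
                       grid_shape = c(64, 64, 64), seed = 42)
  expect_lt(abs(mean(sim$image$values) - 1.0), 0.01)
  sim2 <- gen_brain_pet(bg_suv = 1.0, lesions = list(),
                        scanner = scanner_profile(0, 0.05),
                        grid_shape = c(64, 64, 64), seed = 42)
  expect_identical(sim$image$values, sim2$image$values)
  ph1 <- gen_nema_phantom(seed = 3, grid_shape = c(64, 64, 64),
                          sphere_volumes_cc = c(0.5, 0.8, 1.2, 2, 3, 4))
  ph2 <- gen_nema_phantom(seed = 3, grid_shape = c(64, 64, 64),
                          sphere_volumes_cc = c(0.5, 0.8, 1.2, 2, 3, 4))
  expect_identical(ph1$image$values, ph2$image$values)
})

test_that("lesions outside the grid and invalid specs are rejected", {
  expect_error(gen_brain_pet(lesions = list(lesion_spec(c(2, 2, 2), 20, 4)),
                             grid_shape = c(16, 16, 16)),
               "outside the grid")
  expect_error(lesion_spec(c(1, 1, 1), -1, 4), "radius_mm")
  expect_error(lesion_spec(c(1, 1, 1), 5, 0.9), "contrast")
  expect_error(gen_nema_phantom(sphere_volumes_cc = c(0.2, 1, 2, 3, 4, 5)),
               "0.5, 25")
})

test_that("phantom sphere voxel counts match the analytic volumes", {
  ph <- gen_nema_phantom(scanner = scanner_profile(0, 0), seed = 1)
  vols <- c(0.5, 1.2, 2.6, 5.6, 11.5, 25)
  for (i in seq_len(6)) {
    nvox <- sum(ph$sphere_masks[[i]])
    r <- (3 * vols[i] * 1000 / (4 * pi))^(1 / 3)
    shell <- 4 * pi * r^2 * 2 / 8   # one-voxel shell, in voxels
    expect_lt(abs(nvox - vols[i] * 1000 / 8), shell + 1)
  }
  # 0.5 cc at 8 microlitre voxels is about 62 voxels
  expect_lt(abs(sum(ph$sphere_masks[[1]]) - 62.5), 15)
})

test_that("40% threshold segmentation recovers noiseless spheres exactly", {
  ph <- gen_nema_phantom(scanner = scanner_profile(0, 0), seed = 1)
  for (i in c(1, 4, 6)) {
    region <- dilate_margin(ph$sphere_masks[[i]], 6, ph$image$spacing)
    seg <- segment_sphere_40pct(ph$image, region)
    expect_identical(seg, ph$sphere_masks[[i]])
  }
})

test_that("background contours respect count, volume range and determinism", {
  ph <- gen_nema_phantom(scanner = scanner_profile(0, 0.05), seed = 2)
  avoid <- Reduce(`|`, ph$sphere_masks)
  masks <- gen_background_contours(ph$image, n = 102,
                                   volume_range_cc = c(0.8, 234),
                                   avoid = avoid, seed = 5)
  expect_length(masks, 102)
  counts <- vapply(masks, sum, numeric(1))
  expect_gte(min(counts), 80)   # 0.8 cc at 8 microlitre/voxel, voxelized
  expect_false(any(vapply(masks, function(m) any(m & avoid), logical(1))))
  one <- gen_background_contours(ph$image, n = 1, volume_range_cc = c(8, 8),
                                 seed = 9)
  expect_lt(abs(sum(one[[1]]) - 1000), 120)
  again <- gen_background_contours(ph$image, n = 1, volume_range_cc = c(8, 8),
                                   seed = 9)
  expect_identical(one[[1]], again[[1]])
})

test_that("cohort generator honours its marginals and hazard direction", {
  spec0 <- cohort_spec(n_subjects = 400,
                       feature_means = c(A = 0, B = 10),
                       feature_sds = c(A = 1, B = 2),
                       cox_coefficients_ttp = c(A = 0),
                       censor_rate = 0.3, seed = 11)
  tab <- gen_cohort(spec0)
  expect_equal(nrow(tab), 400)
  expect_true(all(tab$ttp_days > 0) && all(tab$os_days > 0))
  # censoring fraction within 3 binomial SD of the target
  frac <- mean(!tab$ttp_event)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  # RL label only defined where the TTP event happened
  expect_true(all(is.na(tab$rl_label[!tab$ttp_event])))
  expect_false(anyNA(tab$rl_label[tab$ttp_event]))
  # positive hazard coefficient shortens TTP for high-feature subjects
  spec1 <- cohort_spec(n_subjects = 1000,
                       feature_means = c(SZLGE = 0.03),
                       feature_sds = c(SZLGE = 0.01),
                       cox_coefficients_ttp = c(SZLGE = 100),  # 1 per SD
                       censor_rate = 0, seed = 12)
  tb <- gen_cohort(spec1)
  hi <- tb$SZLGE > median(tb$SZLGE)
  expect_lt(median(tb$ttp_days[hi]), median(tb$ttp_days[!hi]))
  expect_identical(gen_cohort(spec1), tb)
})

test_that("Cox fits on one generated cohort recover the coefficients", {
  spec <- cohort_spec(n_subjects = 600,
                      feature_means = c(A = 0, B = 0),
                      feature_sds = c(A = 1, B = 1),
                      cox_coefficients_ttp = c(A = 0.8, B = -0.5),
                      censor_rate = 0.2, seed = 21)
  tab <- gen_cohort(spec)
  fit <- survival::coxph(survival::Surv(ttp_days, ttp_event) ~ A + B,
                         data = tab)
  se <- sqrt(diag(fit$var))
  expect_lt(abs(coef(fit)[["A"]] - 0.8), 3 * se[1])
  expect_lt(abs(coef(fit)[["B"]] + 0.5), 3 * se[2])
})
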