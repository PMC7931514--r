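test_that("background estimate is the mean of per-sphere means", {
  img <- suv_image(array(1.2, c(40, 40, 40)), c(2, 2, 2))
  bg <- estimate_background(img, list(c(10, 10, 10), c(30, 30, 30)),
                            diameter_mm = 10)
  expect_equal(bg$suv_bg, 1.2)
  # unequal sphere sizes and values: mean of the two per-sphere means, not
  # the pooled voxel mean (which would be pulled towards the larger sphere)
  vals <- array(0.5, c(40, 40, 40))
  mA <- sphere_mask(c(40, 40, 40), c(2, 2, 2), c(10, 10, 10), 5)
  mB <- sphere_mask(c(40, 40, 40), c(2, 2, 2), c(30, 30, 30), 9)
  vals[mA] <- 1; vals[mB] <- 2
  img2 <- suv_image(vals, c(2, 2, 2))
  bg2 <- estimate_background(img2, list(c(10, 10, 10), c(30, 30, 30)),
                             diameter_mm = c(10, 18))
  expect_equal(bg2$suv_bg, 1.5)
  pooled <- mean(vals[mA | mB])
  expect_gt(pooled, 1.6)   # the definitions genuinely differ here
  expect_error(estimate_background(img, list(c(1, 1, 1), c(30, 30, 30)),
                                   diameter_mm = 30), "exceeds")
})

test_that("threshold comparison is inclusive and monotone in the factor", {
  vals <- array(1, c(5, 5, 5))
  vals[3, 3, 3] <- 1.8
  vals[2, 2, 2] <- 1.7999
  img <- suv_image(vals)
  m <- threshold_segment(img, 1.0, factor = 1.8)
  expect_true(m[3, 3, 3])
  expect_false(m[2, 2, 2])
  expect_equal(sum(m), 1)
  # sub-threshold image gives an empty mask and the pipeline reports it
  img2 <- suv_image(array(1.7, c(5, 5, 5)))
  expect_equal(sum(threshold_segment(img2, 1.0)), 0)
  expect_error(segment_tumor(img2, list(c(3, 3, 3), c(3, 3, 3)),
                             bg_diameter_mm = 2),
               "no PET-positive volume")
  # monotonicity: raising the factor never adds voxels
  set.seed(4)
  img3 <- suv_image(array(runif(1000, 0, 4), c(10, 10, 10)))
  m_lo <- threshold_segment(img3, 1.0, 1.5)
  m_hi <- threshold_segment(img3, 1.0, 2.0)
  expect_true(all(m_lo[m_hi]))
})

test_that("exclusion mask removes regions and validates grids", {
  v <- array(FALSE, c(6, 6, 1))
  v[1:2, 1:2, 1] <- TRUE; v[5:6, 5:6, 1] <- TRUE
  expect_identical(apply_exclusion(v, NULL), v)
  excl <- array(FALSE, c(6, 6, 1)); excl[5:6, 5:6, 1] <- TRUE
  out <- apply_exclusion(v, excl)
  expect_equal(sum(out), 4)
  expect_false(any(out[5:6, 5:6, 1]))
  expect_equal(sum(apply_exclusion(v, array(TRUE, c(6, 6, 1)))), 0)
  expect_error(apply_exclusion(v, array(FALSE, c(5, 5, 1))), "different grids")
})

test_that("margin dilation matches the exact Euclidean-distance oracle", {
  # single voxel at 2 mm isotropic spacing, 3 mm margin: the face (2.0 mm)
  # and edge (2.83 mm) neighbors are in, the corner (3.46 mm) neighbors out
  v <- array(FALSE, c(7, 7, 7)); v[4, 4, 4] <- TRUE
  d19 <- dilate_margin(v, 3, c(2, 2, 2))
  expect_equal(sum(d19), 19)
  offs <- expand.grid(-3:3, -3:3, -3:3)
  want <- sum(sqrt(rowSums((offs * 2)^2)) <= 3)
  expect_equal(sum(d19), want)
  # anisotropic spacing respected: with dz = 4 mm no out-of-plane neighbor
  da <- dilate_margin(v, 3, c(2, 2, 4))
  expect_equal(sum(da), sum(sqrt((offs[, 1] * 2)^2 + (offs[, 2] * 2)^2 +
                                 (offs[, 3] * 4)^2) <= 3))
  # margin zero is the identity; empty input is an error
  expect_identical(dilate_margin(v, 0), v)
  expect_error(dilate_margin(array(FALSE, c(3, 3, 3)), 3), "empty")
})

test_that("dilating a sphere approximates the analytic r + margin sphere", {
  dims <- c(31, 31, 31); sp <- c(2, 2, 2)
  m <- sphere_mask(dims, sp, c(16, 16, 16), 10)
  dil <- dilate_margin(m, 3, sp)
  v_analytic <- 4 / 3 * pi * 13^3 / 1000   # cc
  v_got <- sum(dil) * prod(sp) / 1000
  shell_cc <- 4 * pi * 13^2 * 2 / 1000
  expect_lt(abs(v_got - v_analytic), shell_cc)
  expect_gte(sum(dil), sum(m))
  # dilation commutes with grid translation
  m2 <- fetrad:::shift_array(m, c(2, 1, 0), fill = FALSE)
  expect_identical(dilate_margin(m2, 3, sp),
                   fetrad:::shift_array(dil, c(2, 1, 0), fill = FALSE))
})

test_that("max-SUV component extraction follows the definition and tie rule", {
  vals <- array(1, c(9, 9, 1))
  v <- array(FALSE, c(9, 9, 1))
  v[1:3, 1:3, 1] <- TRUE    # big component
  v[8:9, 8:9, 1] <- TRUE    # small component holds the max
  vals[9, 9, 1] <- 5
  img <- suv_image(vals)
  out <- extract_max_component(img, v)
  expect_equal(sum(out), 4)
  expect_true(out[9, 9, 1])
  # single component: identity
  v1 <- array(FALSE, c(9, 9, 1)); v1[2:4, 2:4, 1] <- TRUE
  expect_identical(extract_max_component(img, v1), v1)
  # tie on the max: component of the lexicographically first max voxel wins
  vals2 <- array(1, c(9, 9, 1)); vals2[2, 2, 1] <- 5; vals2[8, 8, 1] <- 5
  img2 <- suv_image(vals2)
  v2 <- array(FALSE, c(9, 9, 1)); v2[1:3, 1:3, 1] <- TRUE; v2[7:9, 7:9, 1] <- TRUE
  out2 <- extract_max_component(img2, v2)
  expect_true(out2[2, 2, 1])
  expect_false(out2[8, 8, 1])
  expect_error(extract_max_component(img, array(FALSE, c(9, 9, 1))), "empty")
})

test_that("background reference sphere has 4 cc and avoids the tumor", {
  img <- suv_image(array(1, c(40, 40, 40)), c(2, 2, 2))
  m <- place_background_sphere(img, 4.0)
  expect_lt(abs(sum(m) - 500), 60)
  avoid <- array(FALSE, c(40, 40, 40)); avoid[1:20, , ] <- TRUE
  m2 <- place_background_sphere(img, 4.0, avoid = avoid)
  expect_false(any(m2 & avoid))
  expect_error(place_background_sphere(img, 4.0,
                                       avoid = array(TRUE, c(40, 40, 40))),
               "no placement")
})

test_that("full contouring keeps the nesting invariant and recovers spheres", {
  sim <- gen_brain_pet(bg_suv = 1.0,
                       lesions = list(lesion_spec(c(20, 20, 20), 10, 4)),
                       scanner = scanner_profile(0, 0),
                       grid_shape = c(40, 40, 40), seed = 2)
  cs <- segment_tumor(sim$image, list(c(7, 7, 7), c(33, 33, 33)),
                      bg_diameter_mm = 10)
  expect_true(all(cs$v_pet[cs$v_petmax]))
  expect_true(all(cs$v_pet3mm[cs$v_pet]))
  expect_true(all(cs$v_threshold[cs$v_pet]))
  expect_false(any(cs$v_bg & cs$v_pet3mm))
  # noiseless contrast-4 lesion: threshold volume equals ground truth
  expect_identical(cs$v_threshold, sim$lesion_mask)
  # volume error below one voxel shell against the analytic sphere
  v_analytic <- 4 / 3 * pi * 10^3 / 1000
  v_got <- sum(cs$v_pet) * 8 / 1000
  expect_lt(abs(v_got - v_analytic), 4 * pi * 100 * 2 / 1000)
})
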