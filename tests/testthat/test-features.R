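test_that("SZLGE matches its closed forms and is monotone in gray level", {
  # one zone, level 1, size 8
  z <- build_glszm(make_disc(array(1L, c(2, 2, 2))))
  expect_equal(szlge(z), 1 / 64)
  # the three-zone plane fixture
  lv <- array(NA_integer_, c(3, 3, 1))
  lv[1, , 1] <- c(1L, 1L, 2L); lv[2, , 1] <- c(1L, 2L, 2L); lv[3, , 1] <- c(3L, 3L, 3L)
  z2 <- build_glszm(make_disc(lv))
  expect_equal(szlge(z2), (1 / 3) * (1 / 9 + 1 / 36 + 1 / 81))
  # relabeling every level i -> 2i strictly decreases SZLGE
  z_hi <- build_glszm(make_disc(lv * 2L))
  expect_lt(szlge(z_hi), szlge(z2))
  # and HGZE strictly increases under the same shift
  expect_gt(glszm_features(z_hi)[["HGZE"]], glszm_features(z2)[["HGZE"]])
})

test_that("NGTDM busyness and strength follow their formulas", {
  # constant ROI: fewer than two occupied levels, flagged undefined
  t0 <- build_ngtdm(make_disc(array(2L - 1L, c(2, 2, 2))))
  expect_true(is.na(ngtdm_busyness(t0)))
  expect_true(is.na(ngtdm_strength(t0)))
  # two-voxel (1, 3) fixture: busyness = 1 by direct evaluation
  t1 <- build_ngtdm(make_disc(array(c(1L, 3L), c(1, 1, 2))))
  expect_equal(ngtdm_busyness(t1), 1)
  expect_gte(ngtdm_strength(t1), 0)
  set.seed(8)
  for (rep in 1:10) {
    lev <- random_roi(c(4, 4, 4), 4)
    tt <- build_ngtdm(make_disc(lev))
    ot <- oracle_ngtdm(lev, max(lev, na.rm = TRUE))
    expect_rel_equal(ngtdm_features(tt),
                     oracle_ngtdm_features(ot$p, ot$s, ot$n_valid))
  }
})

test_that("GLCM features match literal sums", {
  g1 <- list(p = matrix(1, 1, 1), ng = 1L)
  class(g1) <- "glcm"
  f1 <- glcm_features(g1)
  expect_equal(f1[["Acor"]], 1)
  expect_equal(f1[["Variance_CM"]], 0)
  g2 <- list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2), ng = 2L)
  class(g2) <- "glcm"
  f2 <- glcm_features(g2)
  expect_equal(f2[["Acor"]], 2)
  expect_equal(f2[["Variance_CM"]], 0.25)
  set.seed(13)
  for (rep in 1:10) {
    lev <- random_roi(c(4, 4, 4), 5)
    g <- build_glcm(make_disc(lev))
    expect_rel_equal(glcm_features(g), oracle_glcm_features(g$p))
  }
})

test_that("GLRLM features match closed forms and literal sums", {
  r1 <- list(counts = rbind(c(0, 0, 0), c(0, 0, 1)),
             p = rbind(c(0, 0, 0), c(0, 0, 1)), nr = 1, ng = 2L, n_voxels = 3)
  class(r1) <- "glrlm"
  f <- glrlm_features(r1)
  expect_equal(f[["HGRE"]], 4)
  expect_equal(f[["SRHGE"]], 4 / 9)
  expect_equal(f[["LRHGE"]], 36)
  expect_equal(f[["GLV"]], 0)
  # two equiprobable runs at levels 1 and 3, length 1: GLV = 1
  r2 <- list(counts = rbind(c(1), c(0), c(1)), p = rbind(c(0.5), c(0), c(0.5)),
             nr = 2, ng = 3L, n_voxels = 2)
  class(r2) <- "glrlm"
  expect_equal(glrlm_features(r2)[["GLV"]], 1)
  set.seed(14)
  for (rep in 1:10) {
    lev <- random_roi(c(4, 4, 4), 4)
    r <- build_glrlm(make_disc(lev))
    expect_rel_equal(glrlm_features(r), oracle_glrlm_features(r$counts))
  }
})

test_that("GLSZM features match closed forms, GLN2 bounded by 1", {
  z1 <- build_glszm(make_disc(array(1L, c(2, 2, 1))))
  f1 <- glszm_features(z1)
  expect_equal(f1[["HGZE"]], 1)
  expect_equal(f1[["GLN2"]], 1)
  lv <- array(NA_integer_, c(3, 3, 1))
  lv[1, , 1] <- c(1L, 1L, 2L); lv[2, , 1] <- c(1L, 2L, 2L); lv[3, , 1] <- c(3L, 3L, 3L)
  z2 <- build_glszm(make_disc(lv))
  expect_equal(glszm_features(z2)[["HGZE"]], 14 / 3)
  set.seed(15)
  for (rep in 1:10) {
    lev <- random_roi(c(4, 4, 4), 4)
    z <- build_glszm(make_disc(lev))
    f <- glszm_features(z)
    expect_rel_equal(f, oracle_glszm_features(z$counts, z$n_voxels))
    expect_gt(f[["GLN2"]], 0)
    expect_lte(f[["GLN2"]], 1)
  }
})

test_that("histogram features use population moments", {
  img <- suv_image(array(2, c(3, 3, 3)))
  f <- histogram_features(img, array(TRUE, c(3, 3, 3)))
  expect_equal(f[["SUV_min"]], 2)
  expect_equal(f[["SUV_max"]], 2)
  expect_equal(f[["SUV_mean"]], 2)
  expect_equal(f[["Variance"]], 0)
  expect_true(is.na(f[["Skewness"]]))
  img2 <- suv_image(array(c(1, 2, 3), c(3, 1, 1)))
  f2 <- histogram_features(img2, array(TRUE, c(3, 1, 1)))
  expect_equal(f2[["SUV_mean"]], 2)
  expect_equal(f2[["Variance"]], 2 / 3)
  # large Normal sample: skewness and excess kurtosis near zero
  set.seed(6)
  n <- 8000
  vals <- array(abs(rnorm(n, 10, 1)), c(20, 20, 20))
  f3 <- histogram_features(suv_image(vals), array(TRUE, c(20, 20, 20)))
  expect_lt(abs(f3[["Skewness"]]), 3 * sqrt(6 / n))
  expect_lt(abs(f3[["Kurtosis"]]), 3 * sqrt(24 / n))
})

test_that("shape features capture volume and anisotropy", {
  dims <- c(21, 21, 21); sp <- c(2, 2, 2)
  ball <- sphere_mask(dims, sp, c(11, 11, 11), 10)
  f <- shape_features(ball, sp)
  expect_lt(abs(f[["Volume_cc"]] - 4 / 3 * pi * 1000 / 1000) / (4 / 3 * pi), 0.05)
  expect_lt(f[["Eccentricity"]], 0.25)
  rod <- array(FALSE, c(3, 3, 11)); rod[2, 2, 2:10] <- TRUE
  fr <- shape_features(rod, sp)
  expect_gt(fr[["Eccentricity"]], 0.99)
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  fs <- shape_features(single, sp)
  expect_true(is.na(fs[["Eccentricity"]]))
  expect_equal(fs[["Volume_cc"]], 0.008)
})

test_that("the feature vector is complete, pure and matches its manifest", {
  sim <- gen_brain_pet(lesions = list(lesion_spec(c(13, 13, 13), 8, 3, 0.3, 4)),
                       scanner = scanner_profile(0, 0.03),
                       grid_shape = c(25, 25, 25), seed = 9)
  fv <- compute_feature_vector(sim$image, sim$lesion_mask)
  expect_identical(names(fv), feature_catalogue())
  expect_length(fv, 135)
  expect_true(all(is.finite(fv) | is.na(fv)))
  fv2 <- compute_feature_vector(sim$image, sim$lesion_mask)
  expect_identical(fv, fv2)
  # the shipped JSON manifest is in sync with the code
  mf <- jsonlite::read_json(system.file("extdata", "feature_manifest.json",
                                        package = "fetrad"),
                            simplifyVector = TRUE)
  expect_equal(mf$n_features, 135)
  expect_identical(mf$features$name, feature_catalogue())
  expect_identical(mf$features, feature_manifest(), ignore_attr = TRUE)
})

test_that("features are invariant under axis permutations of the grid", {
  sim <- gen_brain_pet(lesions = list(lesion_spec(c(13, 13, 13), 8, 3, 0.3, 4)),
                       scanner = scanner_profile(0, 0.03),
                       grid_shape = c(25, 25, 25), seed = 10)
  fv <- compute_feature_vector(sim$image, sim$lesion_mask)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    img_p <- suv_image(aperm(sim$image$values, perm), sim$image$spacing)
    fv_p <- compute_feature_vector(img_p, aperm(sim$lesion_mask, perm))
    expect_equal(fv_p, fv, tolerance = 1e-10)
  }
})
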