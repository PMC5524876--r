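test_that("constant samples give degenerate histogram statistics", {
  f <- first_order_features(rep(7, 25))
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["uniformity"]], 1)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["range"]], 0)
  expect_equal(f[["mean_absolute_deviation"]], 0)
  expect_true(is.na(f[["skewness"]]) && is.na(f[["kurtosis"]]))
  expect_error(first_order_features(numeric(0)), class = "lq_argument_error")
})

test_that("hand-computed values for {1,2,3} are reproduced", {
  f <- first_order_features(c(1, 2, 3))
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["median"]], 2)
  expect_equal(f[["range"]], 2)
  expect_equal(f[["energy"]], 14)
  expect_equal(f[["variance"]], 2 / 3)
  expect_equal(f[["mean_absolute_deviation"]], 2 / 3)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["rms"]], sqrt(14 / 3))
  expect_equal(f[["minimum"]], 1)
  expect_equal(f[["maximum"]], 3)
})

test_that("all 14 first-order features match the naive oracle", {
  set.seed(21)
  for (i in 1:30) {
    x <- switch(1 + i %% 3,
                rnorm(sample(5:400, 1), 100, 25),
                rlnorm(sample(5:400, 1), 3, 1),
                sample(1:20, sample(5:100, 1), replace = TRUE))
    got <- first_order_features(x)
    want <- oracle_first_order(x)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("first-order features transform correctly under intensity shifts", {
  set.seed(22)
  x <- rnorm(500, 50, 10)
  f0 <- first_order_features(x)
  f1 <- first_order_features(x + 13)
  for (nm in c("variance", "standard_deviation", "mean_absolute_deviation",
               "range", "entropy", "uniformity", "skewness", "kurtosis"))
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-9, label = nm)
  for (nm in c("mean", "median", "minimum", "maximum"))
    expect_equal(f1[[nm]], f0[[nm]] + 13, tolerance = 1e-9, label = nm)
})

test_that("digital spheres are near-spherical and cubes exact in face mode", {
  sph <- digital_sphere(10)
  sh <- shape_features(sph)
  expect_lt(abs(sh[["sphericity"]] - 1), 0.02)
  expect_lt(abs(sh[["spherical_disproportion"]] - 1), 0.02)
  cube <- array(FALSE, c(16, 16, 16))
  cube[4:13, 4:13, 4:13] <- TRUE  # 10 mm = 1 cm side
  shc <- shape_features(seg_mask(cube, c(1, 1, 1)), surface_mode = "faces")
  expect_equal(shc[["surface_to_volume_cm_inv"]], 6)
  expect_equal(shc[["surface_area_cm2"]], 6)
})

test_that("sphericity and spherical disproportion are exact reciprocals", {
  set.seed(23)
  for (i in 1:10) {
    m <- array(runif(10 * 10 * 10) > 0.6, c(10, 10, 10))
    m[5, 5, 5] <- TRUE
    sh <- shape_features(seg_mask(m, runif(3, 0.5, 3)))
    expect_equal(sh[["sphericity"]] * sh[["spherical_disproportion"]], 1,
                 tolerance = 1e-12)
  }
})

test_that("surface-to-volume scales inversely with isotropic size", {
  small <- digital_sphere(8)
  big <- digital_sphere(16)
  sh_s <- shape_features(small)
  sh_b <- shape_features(big)
  expect_equal(sh_s[["surface_to_volume_cm_inv"]] /
                 sh_b[["surface_to_volume_cm_inv"]], 2, tolerance = 0.05)
  expect_equal(sh_s[["sphericity"]], sh_b[["sphericity"]], tolerance = 0.02)
})

test_that("TLD follows the unit algebra of the printed scale", {
  expect_equal(compute_tld(1000, 10), 100)
  expect_identical(compute_tld(512, 0), 0)
  expect_error(compute_tld(-1, 5), class = "lq_argument_error")
})

test_that("feature vectors hold exactly the 22 canonical names per modality", {
  expect_length(feature_names("PET"), 22)
  expect_length(feature_names("MR"), 22)
  macro <- c(mtv_cc = 10, suv_mean_pvc = 5, suv_max = 8, tlg_g = 50)
  fo <- first_order_features(rnorm(100, 5))
  sh <- shape_features(digital_sphere(5))
  fv <- assemble_feature_vector(macro, fo, sh, "PET")
  expect_s3_class(fv, "feature_vector")
  expect_identical(names(fv), feature_names("PET"))
  # missing macro feature
  expect_error(assemble_feature_vector(macro[-1], fo, sh, "PET"),
               class = "lq_schema_error")
  # duplicated name
  expect_error(assemble_feature_vector(c(macro, energy = 1), fo, sh, "PET"),
               class = "lq_schema_error")
  # MR schema differs only in the macroscopic block
  macro_mr <- c(v_adc_cc = 10, adc_mean = 1000, adc_min = 300, tld_cm5_s = 100)
  fv_mr <- assemble_feature_vector(macro_mr, fo, sh, "MR")
  expect_identical(names(fv_mr), feature_names("MR"))
  df <- as.data.frame(fv_mr)
  expect_true(all(startsWith(names(df), "mr_")))
})
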