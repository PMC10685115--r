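test_that("spectral axis validates ordering, spacing and defaults", {
  ax <- default_spectral_axis()
  expect_length(ax$wavelengths_nm, 33L)
  expect_equal(ax$step_nm, 10)
  expect_error(spectral_axis(c(400, 410, 405)), "increasing")
  expect_error(spectral_axis(c(400, 410, 430)), "uniform")
})

test_that("Planckian SPD follows Planck's law, Wien peak and conventions", {
  ## Wien displacement: argmax within 1 nm of 2.8978e6 / T nm
  dense <- spectral_axis(seq(400, 720, by = 1))
  s <- planckian_spd(5000, dense)
  peak <- dense$wavelengths_nm[which.max(s$values)]
  expect_lt(abs(peak - 2.8978e6 / 5000), 1)

  ## 2000 K: peak far in the infrared, so values increase over 400-720 nm
  s2k <- planckian_spd(2000)
  expect_true(all(diff(s2k$values) > 0))

  ## normalization convention: value at 560 nm equals 1 for any T
  for (T in c(2000, 6500, 40000)) {
    s <- planckian_spd(T)
    expect_equal(s$values[s$axis$wavelengths_nm == 560], 1)
  }
  expect_true(all(planckian_spd(100000)$values > 0))
  expect_error(planckian_spd(-5), "positive")

  ## smoothness: second differences change sign at most once on the
  ## default axis for temperatures across the range
  for (T in c(2000, 5000, 10000, 100000)) {
    d2 <- diff(sign(diff(diff(planckian_spd(T)$values))))
    expect_lte(sum(d2 != 0), 1)
  }
})

test_that("temperature pairs are uniform in reciprocal temperature", {
  set.seed(42)
  Ts <- sample_temperature_pair(2000, 100000, n = 5000L)
  expect_true(all(Ts >= 2000 & Ts <= 100000))

  ## mean of 1/T within 3 standard errors of the uniform midpoint
  u <- 1 / as.vector(Ts)
  a <- 1 / 100000; b <- 1 / 2000
  se <- (b - a) / sqrt(12) / sqrt(length(u))
  expect_lt(abs(mean(u) - (a + b) / 2), 3 * se)

  ## KS test against Uniform(1/T_max, 1/T_min) not rejected at alpha = .01
  set.seed(7)
  u2 <- 1 / as.vector(sample_temperature_pair(2000, 100000, n = 5000L))
  expect_gt(ks.test(u2, "punif", a, b)$p.value, 0.01)

  ## degenerate interval
  expect_equal(sample_temperature_pair(5000, 5000), c(5000, 5000))
  expect_error(sample_temperature_pair(5000, 2000))
})

test_that("reflectance-to-radiance is the per-band product and is bilinear", {
  ax <- default_spectral_axis()
  ill <- planckian_spd(6500, ax)

  unit <- reflectance_cube(array(1, c(2, 2, 33)), ax)
  rad <- reflectance_to_radiance(unit, ill)
  expect_equal(as.numeric(rad$data[1, 2, ]), ill$values)

  set.seed(3)
  cube <- reflectance_cube(array(runif(4 * 3 * 33), c(4, 3, 33)), ax)
  r1 <- reflectance_to_radiance(cube, ill)
  cube2 <- reflectance_cube(cube$data * 0.25, ax)
  r2 <- reflectance_to_radiance(cube2, ill)
  expect_equal(r2$data, r1$data * 0.25)

  ill2 <- spd(ill$values * 2, ax)
  expect_equal(reflectance_to_radiance(cube, ill2)$data, r1$data * 2)

  bad <- spd(rep(1, 5), spectral_axis(seq(400, 440, 10)))
  expect_error(reflectance_to_radiance(cube, bad), "axis")
})

test_that("preprocessing block-averages, drops odd edges and excludes strips", {
  ax <- spectral_axis(c(500, 510))
  vals <- matrix(1:16, 4, 4)
  cube <- reflectance_cube(array(rep(vals, 2), c(4, 4, 2)), ax)
  out <- preprocess_cube(cube, block = 2, scale = 1)
  ## hand-computed 2x2 block means of matrix(1:16, 4, 4)
  expect_equal(out$data[, , 1], matrix(c(3.5, 5.5, 11.5, 13.5), 2, 2))

  ## constant cube unchanged under any block/scale
  cc <- reflectance_cube(array(0.4, c(10, 10, 2)), ax)
  out2 <- preprocess_cube(cc, block = 2, scale = 0.5)
  expect_equal(range(out2$data), c(0.4, 0.4))

  ## odd dimension: trailing row/column dropped
  odd <- reflectance_cube(array(runif(5 * 5 * 2), c(5, 5, 2)), ax)
  expect_equal(dim(preprocess_cube(odd, block = 2, scale = 1)$data), c(2, 2, 2))

  ## excluded strip removed before smoothing
  cube2 <- reflectance_cube(array(seq_len(6 * 4 * 2), c(6, 4, 2)) / 100, ax)
  out3 <- preprocess_cube(cube2, block = 1, scale = 1,
                          exclude_edge = list(edge = "left", width = 2))
  expect_equal(out3$data, cube2$data[, 3:4, , drop = FALSE])
  expect_error(preprocess_cube(cube2, exclude_edge = list(edge = "left",
                                                          width = 10)),
               "strip")
})

test_that("HDF5 cube round trip preserves data, axis and metadata", {
  skip_if_not_installed("rhdf5")
  tmp <- tempfile(fileext = ".h5")
  on.exit(unlink(tmp))
  cube <- generate_scene(scene_spec(height = 6, width = 5, seed = 2),
                         scene_id = "fixture")
  write_cube(cube, tmp)
  back <- read_cube(tmp)
  expect_s3_class(back, "reflectance_cube")
  expect_equal(back$data, cube$data, tolerance = 1e-12)
  expect_equal(back$scene_id, "fixture")

  rad <- reflectance_to_radiance(cube, planckian_spd(4000, cube$axis))
  write_cube(rad, tmp)
  back2 <- read_cube(tmp)
  expect_s3_class(back2, "radiance_cube")
  expect_equal(back2$illuminant$temperature_K, 4000)
  expect_equal(back2$data, rad$data, tolerance = 1e-12)
})

test_that("SPD and sensor files read from two-column / four-column text", {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  ax <- default_spectral_axis()
  s <- planckian_spd(6500, ax)
  writeLines(c("# test SPD", paste(ax$wavelengths_nm, s$values)), tmp)
  back <- read_spd(tmp)
  expect_equal(back$values, s$values, tolerance = 1e-12)

  f <- system.file("extdata", "cone_hpe_2deg_10nm.txt", package = "coneratios")
  sens <- read_sensor_functions(f)
  expect_equal(dim(sens$rows), c(3L, 33L))
  expect_true(all(sens$rows >= 0))
})

test_that("child seeds differ by key and are stable", {
  expect_equal(child_seed(1L, "illuminants"), child_seed(1L, "illuminants"))
  expect_false(child_seed(1L, "illuminants") == child_seed(1L, "trials"))
  expect_false(child_seed(1L, "trials") == child_seed(2L, "trials"))
  expect_true(child_seed(123456L, "pairs") < 2^31)
})
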