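test_that("cone excitations and tristimulus match a brute-force summation", {
  set.seed(5)
  ax <- default_spectral_axis()
  cube <- reflectance_cube(array(runif(3 * 3 * 33), c(3, 3, 33)), ax)
  rad <- reflectance_to_radiance(cube, planckian_spd(5000, ax))
  fund <- hpe_cone_fundamentals(ax)
  cmfs <- cie1931_cmfs(ax)

  q <- cone_excitations(rad, fund)
  q_oracle <- oracle_sensor_integrate(rad$data, fund$rows, ax$step_nm)
  expect_equal(unclass(q), q_oracle, tolerance = 1e-12, ignore_attr = TRUE)

  x <- tristimulus(rad, cmfs)
  x_oracle <- oracle_sensor_integrate(rad$data, cmfs$rows, ax$step_nm)
  expect_equal(unclass(x), x_oracle, tolerance = 1e-12, ignore_attr = TRUE)

  ## zero radiance and single-band radiance
  zero <- radiance_cube(array(0, c(2, 2, 33)), ax, planckian_spd(5000, ax))
  expect_true(all(cone_excitations(zero, fund) == 0))
  one <- array(0, c(2, 2, 33)); one[, , 7] <- 3.5
  rad1 <- radiance_cube(one, ax, planckian_spd(5000, ax))
  expect_equal(as.numeric(cone_excitations(rad1, fund)[1, 1, ]),
               3.5 * fund$rows[, 7] * 10, ignore_attr = TRUE)

  ## linearity in radiance (superposition)
  rad2 <- radiance_cube(rad$data * 2, ax, rad$illuminant)
  expect_equal(unclass(cone_excitations(rad2, fund)),
               2 * unclass(cone_excitations(rad, fund)), tolerance = 1e-12)
})

test_that("equal-energy spectrum gives X = Y = Z within tabulation tolerance", {
  ax <- default_spectral_axis()
  ee <- radiance_cube(array(1, c(2, 2, 33)), ax,
                      spd(rep(1, 33), ax))
  xyz <- tristimulus(ee)[1, 1, ]
  expect_lt(max(abs(xyz / xyz[2] - 1)), 0.02)
})

test_that("LMS<->XYZ least-squares map is consistent and near-exact", {
  ax <- default_spectral_axis()
  fund <- hpe_cone_fundamentals(ax)
  cmfs <- cie1931_cmfs(ax)
  tr <- lms_xyz_transform(fund, cmfs)

  ## round trip M then M^-1
  set.seed(8)
  lms <- matrix(runif(30, 0.1, 1), 10, 3)
  expect_equal(lms %*% t(tr$M) %*% t(tr$Minv), lms, tolerance = 1e-10,
               ignore_attr = TRUE)

  ## residual of the fit on the shipped tables < 1% relative Frobenius
  expect_lt(tr$relative_residual, 0.01)

  ## M applied to cone excitations ~ tristimulus on random cubes
  cube <- reflectance_cube(array(runif(4 * 4 * 33), c(4, 4, 33)), ax)
  rad <- reflectance_to_radiance(cube, planckian_spd(6500, ax))
  q <- cone_excitations(rad, fund)
  x1 <- apply_colour_map(q, tr$M)
  x2 <- tristimulus(rad, cmfs)
  expect_equal(unclass(x1), unclass(x2),
               tolerance = 2 * tr$relative_residual + 1e-8)
})

test_that("CIECAM02 reproduces the published worked example", {
  ## CIE 159:2004 verification case: sample XYZ (19.01, 20.00, 21.78),
  ## white (95.05, 100, 108.88), L_A = 318.31, Y_b = 20, average surround.
  vc <- viewing_conditions(c(95.05, 100, 108.88), L_A = 318.31, Y_b = 20,
                           surround = "average")
  cor <- ciecam02_correlates(matrix(c(19.01, 20, 21.78), 1), vc)
  expect_equal(cor$J, 41.7310, tolerance = 1e-4)
  expect_equal(cor$C, 0.1047, tolerance = 1e-3)
  expect_equal(cor$h, 219.0485, tolerance = 1e-4)
  expect_equal(cor$Q, 195.3713, tolerance = 1e-4)
  expect_equal(cor$M, 0.1088, tolerance = 1e-3)
  expect_equal(cor$s, 2.3603, tolerance = 1e-3)
})

test_that("vectorised CAM02-UCS agrees with a scalar transcription of the standard", {
  set.seed(13)
  whites <- list(c(95.05, 100, 108.88), c(109.85, 100, 35.58))
  for (w in whites) for (sur in c("average", "dim", "dark")) {
    xyz <- matrix(runif(15, 2, 90), 5, 3)
    vc <- viewing_conditions(w, L_A = 31.83, Y_b = 18, surround = sur)
    got <- cam02ucs(xyz, vc)
    for (i in 1:5) {
      ref <- oracle_cam02ucs(xyz[i, ], w, 31.83, 18, sur)
      expect_equal(as.numeric(got[i, ]), as.numeric(ref[1:3]),
                   tolerance = 1e-9)
    }
  }
})

test_that("CAM02-UCS invariances: joint rescaling, neutral white, J monotone", {
  w <- c(95.05, 100, 108.88)
  set.seed(21)
  xyz <- matrix(runif(30, 5, 80), 10, 3)

  ## relative colorimetry: scaling sample and white together is a no-op
  vc1 <- viewing_conditions(w, L_A = 20)
  vc2 <- viewing_conditions(w * 7.3, L_A = 20)
  expect_equal(unclass(cam02ucs(xyz, vc1)), unclass(cam02ucs(xyz * 7.3, vc2)),
               tolerance = 1e-10, ignore_attr = TRUE)

  ## neutral sample at the white point maps near the achromatic origin
  ## (residual bounded by the standard matrices' row-sum imprecision)
  app <- cam02ucs(matrix(w, 1), viewing_conditions(w, full_adaptation = TRUE))
  expect_lt(max(abs(app[1, 2:3])), 5e-3)

  ## J strictly increasing in luminance factor at fixed chromaticity
  lv <- seq(0.05, 1, length.out = 10)
  Js <- cam02ucs(t(sapply(lv, function(f) f * w)), vc1)[, 1]
  expect_true(all(diff(Js) > 0))
})

test_that("luminance scaling hits the target mean exactly", {
  ax <- default_spectral_axis()
  cube <- reflectance_cube(array(runif(5 * 4 * 33, 0.1, 0.9), c(5, 4, 33)), ax)
  xyz <- tristimulus(reflectance_to_radiance(cube, planckian_spd(6500, ax)))
  out <- scale_mean_luminance(xyz, 8)
  expect_equal(mean(matrix(out, ncol = 3)[, 2]), 8, tolerance = 1e-12)
  out2 <- scale_mean_luminance(out, 8)
  expect_equal(unclass(out2), unclass(out), tolerance = 1e-12)
  half <- scale_mean_luminance(out, 4)
  expect_equal(unclass(half), unclass(out) / 2, tolerance = 1e-12)
  zero <- structure(array(0, c(2, 2, 3)), class = "tristimulus_image")
  expect_error(scale_mean_luminance(zero), "luminance")
})

test_that("sRGB rendering flags out-of-gamut pixels and counts correctly", {
  ## sRGB white at Y = 1 maps to (255, 255, 255), in gamut
  m_srgb <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                     -0.9692660, 1.8760108, 0.0415560,
                     0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
  d65w <- as.numeric(solve(m_srgb, c(1, 1, 1)))
  img <- structure(array(rep(d65w, each = 4), c(2, 2, 3)),
                   class = "tristimulus_image")
  r <- srgb_render(img, peak_white_Y = 1)
  expect_true(all(r$rgb == 255L))
  expect_true(all(r$in_gamut))

  ## saturated out-of-gamut XYZ: flagged and clipped into range
  sat <- structure(array(rep(c(0.9, 0.2, 0.02), each = 4), c(2, 2, 3)),
                   class = "tristimulus_image")
  r2 <- srgb_render(sat, peak_white_Y = 1)
  expect_false(any(r2$in_gamut))
  expect_true(all(r2$rgb >= 0 & r2$rgb <= 255))

  ## gamut_fraction is a straight percentage
  flags <- matrix(c(rep(TRUE, 19), FALSE), 4, 5)
  expect_equal(gamut_fraction(flags), 95)
})
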