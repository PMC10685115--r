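test_that("ratio vectors are component-wise quotients", {
  expect_equal(ratio_vector(c(2, 4, 6), c(1, 2, 3)), c(2, 2, 2))
  expect_equal(ratio_vector(c(0.3, 1, 2), c(0.3, 1, 2)), c(1, 1, 1))
  set.seed(1)
  for (i in 1:20) {
    q1 <- runif(3, 0.01, 5); q2 <- runif(3, 0.01, 5)
    expect_identical(ratio_vector(q1, q2), q1 / q2)
  }
  expect_error(ratio_vector(c(1, 1, 1), c(1, 0, 1)), "positive")
})

test_that("relative deviation matches its formula, is symmetric and >= 0", {
  expect_equal(relative_deviation(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(relative_deviation(c(1, 1, 1), c(2, 2, 2)), 1)
  set.seed(2)
  for (i in 1:50) {
    r <- runif(3, 0.05, 4); rp <- runif(3, 0.05, 4)
    d <- relative_deviation(r, rp)
    expect_equal(d, sqrt(sum((rp - r)^2)) /
                   min(sqrt(sum(r^2)), sqrt(sum(rp^2))))
    expect_equal(d, relative_deviation(rp, r))
    expect_gte(d, 0)
  }
})

test_that("pixel-pair sampling is valid, deterministic, mask-aware", {
  set.seed(4)
  p <- sample_pixel_pairs(c(20, 30), 5000)
  expect_equal(dim(p), c(5000L, 2L))
  expect_true(all(p >= 1 & p <= 600))
  expect_true(all(p[, 1] != p[, 2]))

  set.seed(99); p1 <- sample_pixel_pairs(c(10, 10), 500)
  set.seed(99); p2 <- sample_pixel_pairs(c(10, 10), 500)
  expect_identical(p1, p2)

  ## 2-pixel image: only one unordered pair exists
  m <- matrix(FALSE, 3, 3); m[1, 1] <- m[3, 3] <- TRUE
  pp <- sample_pixel_pairs(c(3, 3), 100, mask = m)
  expect_true(all(sort(unique(as.vector(pp))) == c(1L, 9L)))
  expect_error(sample_pixel_pairs(c(3, 3), 10, mask = m & FALSE), "2 valid")
})

test_that("Monte-Carlo MRD with the full pair set equals the exhaustive oracle", {
  fx <- fixture_cone_pair(h = 3, w = 3, seed = 11)
  qa <- matrix(fx$A, ncol = 3); qb <- matrix(fx$B, ncol = 3)
  pairs <- all_ordered_pairs(9)
  est <- mean_relative_deviation(fx$A, fx$B, pairs = pairs)
  expect_equal(est$mean_deviation, oracle_exhaustive_mrd(qa, qb),
               tolerance = 1e-12)
  expect_equal(est$n_pairs, nrow(pairs))

  ## and on a slightly larger cube
  fx2 <- fixture_cone_pair(h = 4, w = 5, seed = 12, T1 = 20000, T2 = 3500)
  pairs2 <- all_ordered_pairs(20)
  est2 <- mean_relative_deviation(fx2$A, fx2$B, pairs = pairs2)
  expect_equal(est2$mean_deviation,
               oracle_exhaustive_mrd(matrix(fx2$A, ncol = 3),
                                     matrix(fx2$B, ncol = 3)),
               tolerance = 1e-12)
})

test_that("MRD is zero under von Kries transforms and identical images", {
  fx <- fixture_cone_pair(h = 8, w = 8, seed = 21)
  set.seed(31)
  pairs <- sample_pixel_pairs(c(8, 8), 2000)
  expect_equal(mean_relative_deviation(fx$A, fx$A, pairs = pairs)$mrd_percent, 0)
  for (i in 1:5) {
    k <- runif(3, 0.2, 4)
    vk <- apply_correction(fx$A, k)
    expect_lt(mean_relative_deviation(fx$A, vk, pairs = pairs)$mrd_percent,
              1e-10)
  }
})

test_that("MRD resampling is stable and increases with illuminant gap", {
  cube <- generate_scene(scene_spec(height = 128, width = 128,
                                    red_fraction = 0.3, seed = 5))
  fund <- hpe_cone_fundamentals(cube$axis)
  A <- cone_excitations(reflectance_to_radiance(
    cube, planckian_spd(6500, cube$axis)), fund)
  set.seed(6)
  mrds <- vapply(c(6000, 5000, 4000, 3000), function(T) {
    B <- cone_excitations(reflectance_to_radiance(
      cube, planckian_spd(T, cube$axis)), fund)
    mean_relative_deviation(A, B, n_pairs = 20000)$mrd_percent
  }, numeric(1))
  expect_true(all(diff(mrds) > 0))

  ## resampling SD < 5% of the mean on a >= 128x128 scene
  B <- cone_excitations(reflectance_to_radiance(
    cube, planckian_spd(3000, cube$axis)), fund)
  est <- mean_relative_deviation(A, B, n_pairs = 50000, resamples = 5)
  expect_lt(est$resample_sd, 0.05 * est$mean_deviation)
})

test_that("divisor guard rejects pairs with near-zero excitations", {
  fx <- fixture_cone_pair(h = 4, w = 4, seed = 41)
  A <- unclass(fx$A)
  A[1, 1, ] <- 1e-12  # effectively dark pixel
  A <- structure(A, class = "cone_image")
  pairs <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 4L))
  est <- mean_relative_deviation(A, fx$B, pairs = pairs)
  expect_equal(est$n_pairs, 1L)  # pairs touching pixel 1 are rejected
  expect_error(mean_relative_deviation(A, fx$B,
                                       pairs = rbind(c(1L, 2L), c(1L, 3L))),
               "rejected")
})

test_that("MRD bins are 1% half-open intervals with out-of-range signal", {
  expect_identical(mrd_bin(0.3), 0L)
  expect_identical(mrd_bin(6.99), 6L)
  expect_identical(mrd_bin(7.0), NA_integer_)
  expect_identical(mrd_bin(2.0), 2L)
  expect_equal(mrd_bin_centre(0:6), seq(0.5, 6.5, 1))
  expect_error(mrd_bin(-1), "non-negative")
})

test_that("correction gains are through-origin least squares and exact on scalings", {
  fx <- fixture_cone_pair(h = 6, w = 6, seed = 51)

  ## B = 2A recovers gains (2, 2, 2)
  twoA <- apply_correction(fx$A, c(2, 2, 2))
  expect_equal(as.numeric(fit_correction_gains(fx$A, twoA)), c(2, 2, 2),
               tolerance = 1e-12)

  ## generic least-squares-through-origin oracle
  a <- matrix(fx$A, ncol = 3); b <- matrix(fx$B, ncol = 3)
  k_oracle <- vapply(1:3, function(c)
    as.numeric(coef(lm(b[, c] ~ a[, c] + 0))), numeric(1))
  expect_equal(as.numeric(fit_correction_gains(fx$A, fx$B)), k_oracle,
               tolerance = 1e-10)

  ## invariant to pixel permutation
  set.seed(52)
  perm <- sample(36)
  Ap <- structure(array(a[perm, ], c(6, 6, 3)), class = "cone_image")
  Bp <- structure(array(b[perm, ], c(6, 6, 3)), class = "cone_image")
  expect_equal(as.numeric(fit_correction_gains(Ap, Bp)),
               as.numeric(fit_correction_gains(fx$A, fx$B)), tolerance = 1e-12)

  ## reversed regression direction still returns gains for the reference
  k2 <- fit_correction_gains(fx$A, fx$B, direction = "reference_on_test")
  expect_true(all(k2 > 0))
})

test_that("ratio correction preserves all spatial ratios exactly", {
  fx <- fixture_cone_pair(h = 8, w = 8, seed = 61, T1 = 25000, T2 = 3000)
  gains <- fit_correction_gains(fx$A, fx$B)
  C <- apply_correction(fx$A, gains, illuminant = attr(fx$B, "illuminant"))

  ## identity gains
  expect_equal(unclass(apply_correction(fx$A, c(1, 1, 1))), unclass(fx$A))

  ## every pair's ratio vector identical (spot-check all pairs of 64 pixels)
  qa <- matrix(fx$A, ncol = 3); qc <- matrix(C, ncol = 3)
  pairs <- all_ordered_pairs(64)
  ra <- qa[pairs[, 1], ] / qa[pairs[, 2], ]
  rc <- qc[pairs[, 1], ] / qc[pairs[, 2], ]
  expect_lt(max(abs(rc - ra) / ra), 1e-10)

  ## channel means scale by the gains
  expect_equal(colMeans(qc), colMeans(qa) * as.numeric(gains),
               tolerance = 1e-12)
})
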