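## Independent oracles used across the suite. These deliberately share no
## code with the package: scalar loops and step-by-step transcriptions.

## Brute-force sensor integration: triple loop over pixels and bands.
oracle_sensor_integrate <- function(rad_data, rows, step) {
  d <- dim(rad_data)
  out <- array(0, c(d[1], d[2], 3))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in 1:3) {
    s <- 0
    for (b in seq_len(d[3])) s <- s + rad_data[i, j, b] * rows[c, b] * step
    out[i, j, c] <- s
  }
  out
}

## Exhaustive all-pairs mean relative deviation, scalar arithmetic.
oracle_exhaustive_mrd <- function(qa, qb) {
  n <- nrow(qa)
  devs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- qa[i, ] / qa[j, ]
    rp <- qb[i, ] / qb[j, ]
    d1 <- sqrt(sum((rp - r)^2)) / min(sqrt(sum(r^2)), sqrt(sum(rp^2)))
    ## ordered pairs in both directions
    r2 <- qa[j, ] / qa[i, ]
    rp2 <- qb[j, ] / qb[i, ]
    d2 <- sqrt(sum((rp2 - r2)^2)) / min(sqrt(sum(r2^2)), sqrt(sum(rp2^2)))
    devs <- c(devs, d1, d2)
  }
  mean(devs)
}

## All ordered distinct pairs of n pixels, as a pair matrix.
all_ordered_pairs <- function(n) {
  g <- expand.grid(first = seq_len(n), second = seq_len(n))
  as.matrix(g[g$first != g$second, ])
}

## Scalar step-by-step CIECAM02 + CAM02-UCS transcription of the standard
## (single triplet at a time; written independently of the package's
## vectorised implementation).
oracle_cam02ucs <- function(xyz, white, L_A, Y_b, surround = "average",
                            full_adaptation = FALSE) {
  sur <- switch(surround,
                average = list(F = 1.0, c = 0.690, Nc = 1.0),
                dim     = list(F = 0.9, c = 0.590, Nc = 0.9),
                dark    = list(F = 0.8, c = 0.525, Nc = 0.8))
  Mcat <- matrix(c(0.7328, 0.4296, -0.1624,
                   -0.7036, 1.6975, 0.0061,
                   0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
  Mhpe <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0, 0, 1), 3, 3, byrow = TRUE)
  scale <- 100 / white[2]
  xyz <- xyz * scale; white <- white * scale
  D <- if (full_adaptation) 1 else
    sur$F * (1 - (1 / 3.6) * exp((-L_A - 42) / 92))
  D <- min(max(D, 0), 1)
  k <- 1 / (5 * L_A + 1)
  FL <- 0.2 * k^4 * (5 * L_A) + 0.1 * (1 - k^4)^2 * (5 * L_A)^(1 / 3)
  n <- Y_b / white[2]
  Nbb <- 0.725 * (1 / n)^0.2
  z <- 1.48 + sqrt(n)
  rgbw <- as.numeric(Mcat %*% white)
  rgb <- as.numeric(Mcat %*% xyz)
  rgbc <- (white[2] * D / rgbw + 1 - D) * rgb
  rgbwc <- (white[2] * D / rgbw + 1 - D) * rgbw
  rgbp <- as.numeric(Mhpe %*% solve(Mcat) %*% rgbc)
  rgbwp <- as.numeric(Mhpe %*% solve(Mcat) %*% rgbwc)
  f <- function(x) {
    t <- (FL * abs(x) / 100)^0.42
    sign(x) * 400 * t / (t + 27.13) + 0.1
  }
  ra <- f(rgbp); rwa <- f(rgbwp)
  a <- ra[1] - 12 * ra[2] / 11 + ra[3] / 11
  b <- (ra[1] + ra[2] - 2 * ra[3]) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  A <- (2 * ra[1] + ra[2] + ra[3] / 20 - 0.305) * Nbb
  Aw <- (2 * rwa[1] + rwa[2] + rwa[3] / 20 - 0.305) * Nbb
  J <- 100 * max(A / Aw, 0)^(sur$c * z)
  t <- (50000 / 13) * sur$Nc * Nbb * et * sqrt(a^2 + b^2) /
    (ra[1] + ra[2] + 21 * ra[3] / 20)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^n)^0.73
  M <- C * FL^0.25
  Jp <- 1.7 * J / (1 + 0.007 * J)
  Mp <- log(1 + 0.0228 * M) / 0.0228
  c(J = Jp, a = Mp * cos(h * pi / 180), b = Mp * sin(h * pi / 180),
    rawJ = J, rawC = C, rawh = h, rawM = M)
}

## Two-spectrum fixture: flat grey and a sloped surface on the default axis.
fixture_two_spectra <- function() {
  w <- seq(400, 720, by = 10)
  list(rep(0.5, length(w)), 0.2 + 0.5 * (w - 400) / 320)
}

## Tiny two-illuminant cone-image pair for MRD tests.
fixture_cone_pair <- function(h = 3, w = 3, seed = 11, T1 = 10000, T2 = 2900) {
  set.seed(seed)
  cube <- generate_scene(scene_spec(height = h, width = w, n_patches = 4,
                                    seed = seed))
  fund <- hpe_cone_fundamentals(cube$axis)
  A <- cone_excitations(reflectance_to_radiance(
    cube, planckian_spd(T1, cube$axis)), fund)
  B <- cone_excitations(reflectance_to_radiance(
    cube, planckian_spd(T2, cube$axis)), fund)
  list(A = A, B = B, cube = cube)
}
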