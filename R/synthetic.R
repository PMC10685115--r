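## Synthetic hyperspectral scenes with natural-scene-like statistics, exact
## Mondrian-style fixtures, and a synthetic 2AFC observer.

#' Specification of a synthetic natural-scene reflectance cube
#'
#' The generator emulates the statistical structure the analysis assumes
#' of natural scenes: spectrally smooth reflectances in [0, 1], patchwise
#' spatial structure (a Voronoi mosaic), larger variation in lightness
#' than in chromaticity, an optional chromatic bias toward the yellow-blue
#' axis, and a controllable fraction of saturated reddish surfaces, which
#' drive the largest deviations in spatial cone-excitation ratios.
#'
#' @param height,width image size in pixels (>= 2).
#' @param n_patches number of Voronoi patches.
#' @param smoothness standard deviation (nm) of the Gaussian-bump basis
#'   spectra; larger = spectrally smoother surfaces.
#' @param red_fraction proportion of patches drawn from a saturated
#'   long-wavelength-shoulder reflectance family.
#' @param chroma_bias_deg preferred chromatic axis of patch variation in
#'   degrees (0 = reddish-greenish, 90 = yellowish-bluish).
#' @param lightness_cv coefficient of variation of patch lightness levels.
#' @param chroma_cv coefficient of variation of patch chromatic contrast.
#' @param texture_amplitude SD of within-patch multiplicative log-normal
#'   texture.
#' @param seed optional integer; when given the cube is a deterministic
#'   function of the spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64L, width = 64L, n_patches = 40L,
                       smoothness = 60, red_fraction = 0.15,
                       chroma_bias_deg = 90, lightness_cv = 0.4,
                       chroma_cv = 0.15, texture_amplitude = 0.06,
                       seed = NULL) {
  stopifnot(height >= 2L, width >= 2L, n_patches >= 1L, smoothness > 0,
            red_fraction >= 0, red_fraction <= 1, lightness_cv >= 0,
            chroma_cv >= 0, texture_amplitude >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_patches = as.integer(n_patches), smoothness = smoothness,
                 red_fraction = red_fraction, chroma_bias_deg = chroma_bias_deg,
                 lightness_cv = lightness_cv, chroma_cv = chroma_cv,
                 texture_amplitude = texture_amplitude, seed = seed),
            class = "scene_spec")
}

## Smooth chromatic contrast directions on the wavelength axis:
## a "red-green" contrast (long vs middle wavelengths) and a
## "yellow-blue" contrast (long+middle vs short wavelengths).
chroma_directions <- function(w) {
  rg <- exp(-(w - 630)^2 / (2 * 55^2)) - exp(-(w - 530)^2 / (2 * 55^2))
  yb <- tanh((w - 520) / 70)
  list(rg = rg / max(abs(rg)), yb = yb / max(abs(yb)))
}

## Saturated reddish surface: low short-wavelength reflectance rising
## over a long-wavelength shoulder. The base and edge softness keep such
## surfaces displayable (within the sRGB gamut at warm illuminants) while
## still producing the largest ratio deviations in a scene.
red_shoulder_spectrum <- function(w, level, edge_nm) {
  level * (0.12 + 0.8 / (1 + exp(-(w - edge_nm) / 24)))
}

voronoi_labels <- function(h, w, n_patches) {
  cx <- runif(n_patches, 1, h); cy <- runif(n_patches, 1, w)
  px <- rep(seq_len(h), times = w); py <- rep(seq_len(w), each = h)
  lab <- max.col(-(outer(px, cx, `-`)^2 + outer(py, cy, `-`)^2))
  matrix(lab, h, w)
}

#' Generate a synthetic hyperspectral reflectance scene
#'
#' Builds a Voronoi-patch mosaic. Each ordinary patch's spectrum is a
#' convex combination of smooth Gaussian-bump basis spectra whose weights
#' are tilted along a chromatic contrast direction (angle drawn around
#' `chroma_bias_deg`), scaled by a log-normal lightness level; a
#' `red_fraction` of patches instead uses a saturated long-wavelength
#' shoulder family. Within-patch log-normal texture is applied to all
#' bands and the result clipped into [0, 1].
#'
#' @param spec a [scene_spec()].
#' @param axis a [spectral_axis()].
#' @param scene_id label for the cube.
#' @return a [reflectance_cube()].
#' @export
#' @examples
#' cube <- generate_scene(scene_spec(height = 16, width = 16, seed = 1))
generate_scene <- function(spec, axis = default_spectral_axis(),
                           scene_id = "synthetic") {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- axis$wavelengths_nm
  B <- length(w)
  n <- spec$n_patches

  labels <- voronoi_labels(spec$height, spec$width, n)

  ## Gaussian-bump basis, centres spread over the axis.
  centres <- seq(min(w), max(w), length.out = 9L)
  basis <- exp(-outer(w, centres, `-`)^2 / (2 * spec$smoothness^2)) # B x K
  dirs <- chroma_directions(w)

  n_red <- rbinom(1L, n, spec$red_fraction)
  is_red <- rep(FALSE, n)
  if (n_red > 0L) is_red[sample.int(n, n_red)] <- TRUE

  ## Patch lightness levels: log-normal with the requested CV around 0.35.
  sdlog_l <- sqrt(log(1 + spec$lightness_cv^2))
  levels <- 0.35 * exp(rnorm(n, -sdlog_l^2 / 2, sdlog_l))

  ## Chromatic tilt: direction around the bias axis, magnitude log-normal
  ## with CV chroma_cv so chromatic contrast disperses less than lightness.
  phi <- (spec$chroma_bias_deg + rnorm(n, 0, 20)) * pi / 180
  sdlog_c <- sqrt(log(1 + spec$chroma_cv^2))
  rho <- 0.4 * exp(rnorm(n, -sdlog_c^2 / 2, sdlog_c)) * sample(c(-1, 1), n, TRUE)

  spectra <- matrix(0, n, B)
  for (p in seq_len(n)) {
    if (is_red[p]) {
      spectra[p, ] <- red_shoulder_spectrum(w, levels[p] / 0.35,
                                            edge_nm = runif(1, 590, 620))
    } else {
      tilt <- rho[p] * (cos(phi[p]) * dirs$rg + sin(phi[p]) * dirs$yb)
      gw <- exp(approx(w, tilt, xout = centres)$y + rnorm(9L, 0, 0.05))
      shape <- as.numeric(basis %*% (gw / sum(gw)))
      spectra[p, ] <- levels[p] * shape / mean(shape)
    }
  }
  spectra[spectra < 1e-4] <- 1e-4
  spectra[spectra > 0.99] <- 0.99

  data <- array(t(spectra)[, as.vector(labels)],
                c(B, spec$height * spec$width))
  tex <- exp(rnorm(spec$height * spec$width, 0, spec$texture_amplitude))
  data <- sweep(data, 2L, tex, `*`)
  data[data > 1] <- 1
  cube <- aperm(array(data, c(B, spec$height, spec$width)), c(2L, 3L, 1L))
  reflectance_cube(cube, axis, scene_id = scene_id)
}

#' Exact Mondrian-style fixture cube
#'
#' Arranges explicitly given reflectance spectra as uniform rectangular
#' patches (down to one pixel per patch), for hand-checkable oracles.
#'
#' @param spectra list of length-B reflectance vectors, one per patch.
#' @param nrow number of patch rows in the mosaic (patches fill row-wise).
#' @param patch_px patch side length in pixels.
#' @param axis a [spectral_axis()].
#' @return a [reflectance_cube()].
#' @export
generate_mondrian_fixture <- function(spectra, nrow = 1L, patch_px = 1L,
                                      axis = default_spectral_axis()) {
  n <- length(spectra)
  B <- length(axis$wavelengths_nm)
  if (n < 1L || n %% nrow != 0L) stop("patch count must be a multiple of nrow")
  if (!all(vapply(spectra, length, 1L) == B))
    stop("each spectrum must match the axis length")
  ncol <- n %/% nrow
  h <- max(2L, nrow * patch_px); w <- max(2L, ncol * patch_px)
  prow <- pmin(((seq_len(h) - 1L) %/% patch_px) + 1L, nrow)
  pcol <- pmin(((seq_len(w) - 1L) %/% patch_px) + 1L, ncol)
  lab <- outer(prow, pcol, function(i, j) (i - 1L) * ncol + j)
  S <- do.call(rbind, spectra)
  data <- array(t(S[as.vector(lab), , drop = FALSE]), c(B, h, w))
  reflectance_cube(aperm(data, c(2L, 3L, 1L)), axis, scene_id = "mondrian")
}

#' Synthetic 2AFC observer
#'
#' An observer whose probability of misidentifying the ratio-corrected
#' image as the illuminant change, at MRD level x (percent), is
#' p(x) = 0.5 + (0.5 - lapse) * Phi((x - mu) / sigma): guessing floor 0.5,
#' ceiling 1 - lapse.
#'
#' @param mu psychometric midpoint (MRD %).
#' @param sigma spread (MRD %), > 0.
#' @param lapse lapse rate in [0, 0.06].
#' @return an object of class `observer_spec`.
#' @export
observer_spec <- function(mu = 3, sigma = 1.5, lapse = 0.02) {
  stopifnot(sigma > 0, lapse >= 0, lapse <= 0.06)
  structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = 0.5),
            class = "observer_spec")
}

#' @rdname observer_spec
#' @param x MRD level value(s) in percent.
#' @return `psychometric_prob()` returns p(x); `simulate_observer()` draws
#'   binary misidentification responses (1 = misidentified) from the
#'   current random stream.
#' @export
psychometric_prob <- function(x, mu, sigma, lapse = 0) {
  0.5 + (0.5 - lapse) * pnorm((x - mu) / sigma)
}

#' @rdname observer_spec
#' @param spec an `observer_spec`.
#' @export
simulate_observer <- function(x, spec) {
  p <- psychometric_prob(x, spec$mu, spec$sigma, spec$lapse)
  rbinom(length(x), 1L, p)
}
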