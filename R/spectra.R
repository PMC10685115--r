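## Spectral data model: axes, SPDs, reflectance/radiance cubes, Planckian
## illuminants, reciprocal-temperature sampling, preprocessing.

#' Spectral sampling axis
#'
#' A strictly increasing, uniformly spaced set of band centres in
#' nanometres. The default axis is 400-720 nm in 10 nm steps (33 bands),
#' the sampling used throughout the pipeline.
#'
#' @param wavelengths_nm numeric vector of band centres (nm).
#' @return an object of class `spectral_axis` with fields
#'   `wavelengths_nm` and `step_nm`.
#' @export
#' @examples
#' ax <- spectral_axis(seq(400, 720, by = 10))
#' ax$step_nm
spectral_axis <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L) stop("spectral axis needs at least 2 bands")
  d <- diff(w)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop("wavelengths must be uniformly spaced")
  structure(list(wavelengths_nm = w, step_nm = mean(d)), class = "spectral_axis")
}

#' @rdname spectral_axis
#' @export
default_spectral_axis <- function() spectral_axis(seq(400, 720, by = 10))

same_axis <- function(a, b) {
  length(a$wavelengths_nm) == length(b$wavelengths_nm) &&
    max(abs(a$wavelengths_nm - b$wavelengths_nm)) < 1e-9
}

#' Spectral power distribution
#'
#' @param values non-negative relative spectral power per band.
#' @param axis a [spectral_axis()].
#' @param temperature_K optional Planckian temperature tag (kelvin).
#' @return an object of class `spd`.
#' @export
spd <- function(values, axis = default_spectral_axis(), temperature_K = NA_real_) {
  values <- as.numeric(values)
  if (length(values) != length(axis$wavelengths_nm))
    stop("SPD length does not match axis")
  if (any(!is.finite(values)) || any(values < 0) || all(values == 0))
    stop("SPD values must be finite, non-negative, and not all zero")
  structure(list(axis = axis, values = values, temperature_K = temperature_K),
            class = "spd")
}

## CODATA first and second radiation constants (SI).
.c1 <- 3.741771852e-16 # W m^2
.c2 <- 1.438776877e-2  # m K

planck_radiance <- function(lambda_m, T) {
  .c1 / (lambda_m^5 * (exp(.c2 / (lambda_m * T)) - 1))
}

#' Planckian (blackbody) illuminant spectrum
#'
#' Evaluates Planck's law for spectral radiance per unit wavelength at the
#' axis band centres and normalizes so the value at 560 nm equals 1.
#' Illuminant intensity is irrelevant downstream (spatial ratios are
#' scale-invariant and displayed images are re-normalized to a target mean
#' luminance), so the normalization is only a convention.
#'
#' @param temperature_K blackbody temperature in kelvin (> 0).
#' @param axis a [spectral_axis()].
#' @return an [spd()] with `temperature_K` recorded.
#' @export
#' @examples
#' s <- planckian_spd(6500)
#' s$values[s$axis$wavelengths_nm == 560] # 1 by convention
planckian_spd <- function(temperature_K, axis = default_spectral_axis()) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature must be positive")
  v <- planck_radiance(axis$wavelengths_nm * 1e-9, temperature_K)
  v560 <- planck_radiance(560e-9, temperature_K)
  spd(v / v560, axis, temperature_K = temperature_K)
}

#' Sample a pair of Planckian temperatures uniform in reciprocal temperature
#'
#' Draws two independent temperatures T with 1/T ~ Uniform(1/T_max, 1/T_min),
#' which spaces illuminant colours approximately uniformly. Default range is
#' an orangish 2000 K to a blueish 100 000 K. Uses the current R random
#' stream.
#'
#' @param t_min,t_max temperature bounds in kelvin, 0 < t_min <= t_max.
#' @param n number of pairs to draw.
#' @return for `n = 1` a numeric vector of length 2; otherwise an `n` x 2
#'   matrix with one pair per row.
#' @export
#' @examples
#' set.seed(1)
#' sample_temperature_pair()
sample_temperature_pair <- function(t_min = 2000, t_max = 100000, n = 1L) {
  if (!is.finite(t_min) || !is.finite(t_max) || t_min <= 0 || t_min > t_max)
    stop("need 0 < t_min <= t_max")
  u <- matrix(runif(2L * n, min = 1 / t_max, max = 1 / t_min), ncol = 2L)
  T <- 1 / u
  if (n == 1L) as.numeric(T[1L, ]) else T
}

#' Hyperspectral reflectance and radiance cubes
#'
#' A cube is an H x W x B array with a spectral axis; reflectance values
#' are dimensionless in [0, 1] (effective spectral reflectance), radiance
#' values are relative spectral radiances carrying the illuminant tag.
#'
#' @param data H x W x B numeric array, B = number of axis bands.
#' @param axis a [spectral_axis()].
#' @param scene_id character label.
#' @return an object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(data, axis = default_spectral_axis(),
                             scene_id = "scene") {
  d <- dim(data)
  if (length(d) != 3L || d[3L] != length(axis$wavelengths_nm))
    stop("data must be H x W x B with B matching the axis")
  if (d[1L] < 2L || d[2L] < 2L) stop("image must be at least 2 x 2")
  if (any(!is.finite(data)) || any(data < 0))
    stop("reflectances must be finite and non-negative")
  structure(list(data = data, axis = axis, scene_id = scene_id),
            class = "reflectance_cube")
}

#' @rdname reflectance_cube
#' @param illuminant an [spd()] describing the global illuminant.
#' @export
radiance_cube <- function(data, axis, illuminant, scene_id = "scene") {
  d <- dim(data)
  if (length(d) != 3L || d[3L] != length(axis$wavelengths_nm))
    stop("data must be H x W x B with B matching the axis")
  if (any(!is.finite(data)) || any(data < 0))
    stop("radiances must be finite and non-negative")
  structure(list(data = data, axis = axis, illuminant = illuminant,
                 scene_id = scene_id), class = "radiance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("reflectance cube '%s': %d x %d pixels, %d bands (%g-%g nm)\n",
              x$scene_id, d[1], d[2], d[3],
              min(x$axis$wavelengths_nm), max(x$axis$wavelengths_nm)))
  invisible(x)
}

#' @export
print.radiance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("radiance cube '%s': %d x %d pixels, %d bands, illuminant %s K\n",
              x$scene_id, d[1], d[2], d[3],
              format(x$illuminant$temperature_K)))
  invisible(x)
}

#' Render a reflectance cube under a global illuminant
#'
#' Simulates an illumination change with a spatially uniform spectral
#' distribution: the radiance at each pixel and band is the product of the
#' effective reflectance and the illuminant spectral power.
#'
#' @param cube a [reflectance_cube()].
#' @param illuminant an [spd()] on the same axis.
#' @return a [radiance_cube()].
#' @export
reflectance_to_radiance <- function(cube, illuminant) {
  if (!same_axis(cube$axis, illuminant$axis)) stop("axis mismatch")
  out <- sweep(cube$data, 3L, illuminant$values, `*`)
  radiance_cube(out, cube$axis, illuminant, scene_id = cube$scene_id)
}

block_mean_2d <- function(m, block) {
  if (block == 1L) return(m)
  h <- nrow(m) %/% block; w <- ncol(m) %/% block
  m <- m[seq_len(h * block), seq_len(w * block), drop = FALSE]
  # average rows then columns within non-overlapping blocks
  rowg <- rep(seq_len(h), each = block)
  colg <- rep(seq_len(w), each = block)
  t(rowsum(t(rowsum(m, rowg)), colg)) / block^2
}

#' Preprocess a reflectance cube
#'
#' Mirrors the preparation applied to hyperspectral camera data: optional
#' removal of a narrow calibration strip at one edge, spatial smoothing by
#' non-overlapping block averaging (2 x 2 by default, to suppress
#' non-imaging noise and pixel-pixel correlations), then band-wise bilinear
#' downscaling to a fraction of full size. The spectral dimension is never
#' resampled. Odd trailing rows/columns under block averaging are dropped.
#'
#' @param cube a [reflectance_cube()].
#' @param block block size for spatial averaging (2 = 2 x 2 mean).
#' @param scale spatial resampling fraction in (0, 1]; 0.4 mirrors display
#'   preparation.
#' @param exclude_edge `NULL`, or `list(edge = "left"|"right"|"top"|"bottom",
#'   width = <pixels>)` naming a strip to remove before smoothing.
#' @return a [reflectance_cube()].
#' @export
preprocess_cube <- function(cube, block = 2L, scale = 0.4, exclude_edge = NULL) {
  stopifnot(block >= 1L, scale > 0, scale <= 1)
  x <- cube$data
  if (!is.null(exclude_edge)) {
    edge <- match.arg(exclude_edge$edge, c("left", "right", "top", "bottom"))
    k <- as.integer(exclude_edge$width)
    d <- dim(x)
    lim <- if (edge %in% c("top", "bottom")) d[1L] else d[2L]
    if (k < 0L || k >= lim) stop("excluded strip larger than image")
    x <- switch(edge,
      top    = x[(k + 1L):d[1L], , , drop = FALSE],
      bottom = x[seq_len(d[1L] - k), , , drop = FALSE],
      left   = x[, (k + 1L):d[2L], , drop = FALSE],
      right  = x[, seq_len(d[2L] - k), , drop = FALSE])
  }
  d <- dim(x)
  h <- d[1L] %/% block; w <- d[2L] %/% block
  if (h < 1L || w < 1L) stop("block larger than image")
  if (block > 1L) {
    y <- array(0, c(h, w, d[3L]))
    for (b in seq_len(d[3L])) y[, , b] <- block_mean_2d(x[, , b], block)
    x <- y
  }
  if (scale < 1) {
    nh <- max(2L, round(dim(x)[1L] * scale))
    nw <- max(2L, round(dim(x)[2L] * scale))
    x <- EBImage::resize(x, w = nh, h = nw) # first array dim is EBImage's x
    x[x < 0] <- 0
  }
  reflectance_cube(x, cube$axis, scene_id = cube$scene_id)
}
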