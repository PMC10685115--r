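## Cone excitations, tristimulus values, LMS<->XYZ linear maps, luminance
## normalization and sRGB gamut-checked rendering.

## Flatten an HxWx3 array to (H*W) x 3 and back.
flat3 <- function(a) matrix(a, ncol = 3L)
unflat3 <- function(m, dims) array(m, c(dims, 3L))

sensor_integrate <- function(radiance, sens) {
  if (!same_axis(radiance$axis, sens$axis)) stop("axis mismatch")
  d <- dim(radiance$data)
  m <- matrix(radiance$data, nrow = d[1L] * d[2L], ncol = d[3L])
  q <- m %*% t(sens$rows) * radiance$axis$step_nm
  unflat3(q, d[1:2])
}

#' Cone excitations from a radiance cube
#'
#' Per-pixel L, M, S excitations: the radiance spectrum weighted by the
#' cone fundamentals and summed over wavelength (rectangle rule at the
#' axis step).
#'
#' @param radiance a [radiance_cube()].
#' @param fundamentals cone-fundamental [sensor_functions()] on the same
#'   axis; defaults to [hpe_cone_fundamentals()].
#' @return an object of class `cone_image`: H x W x 3 array of (qL, qM, qS)
#'   with the illuminant recorded as attribute `illuminant`.
#' @export
cone_excitations <- function(radiance,
                             fundamentals = hpe_cone_fundamentals(radiance$axis)) {
  if (fundamentals$kind != "cone-fundamentals")
    stop("fundamentals must be of kind 'cone-fundamentals'")
  q <- sensor_integrate(radiance, fundamentals)
  structure(q, class = "cone_image", illuminant = radiance$illuminant,
            scene_id = radiance$scene_id)
}

#' Tristimulus values from a radiance cube
#'
#' As [cone_excitations()] but with colour-matching functions; absolute
#' luminance scaling is deferred to [scale_mean_luminance()].
#'
#' @param radiance a [radiance_cube()].
#' @param cmfs colour-matching [sensor_functions()]; defaults to
#'   [cie1931_cmfs()].
#' @return an H x W x 3 array of class `tristimulus_image` (X, Y, Z).
#' @export
tristimulus <- function(radiance, cmfs = cie1931_cmfs(radiance$axis)) {
  if (cmfs$kind != "colour-matching")
    stop("cmfs must be of kind 'colour-matching'")
  x <- sensor_integrate(radiance, cmfs)
  structure(x, class = "tristimulus_image", illuminant = radiance$illuminant,
            scene_id = radiance$scene_id)
}

#' Least-squares linear map between cone fundamentals and CMFs
#'
#' Fits the 3 x 3 matrix M minimizing ||cmfs - M fundamentals||_F over the
#' common axis, so that XYZ ~ M LMS. Colour-matching functions are (near)
#' linear combinations of cone fundamentals, so the relative residual is
#' small; it is reported so users can judge a supplied pair of tables.
#'
#' @param fundamentals cone-fundamental [sensor_functions()].
#' @param cmfs colour-matching [sensor_functions()] on the same axis.
#' @return list with `M` (LMS -> XYZ), `Minv` (XYZ -> LMS) and
#'   `relative_residual` (Frobenius norm ratio).
#' @export
lms_xyz_transform <- function(fundamentals, cmfs) {
  if (!same_axis(fundamentals$axis, cmfs$axis)) stop("axis mismatch")
  FF <- fundamentals$rows; CC <- cmfs$rows
  G <- FF %*% t(FF)
  if (abs(det(G)) < 1e-12 * norm(G, "F")^3) stop("singular fundamental set")
  M <- (CC %*% t(FF)) %*% solve(G)
  res <- norm(CC - M %*% FF, "F") / norm(CC, "F")
  list(M = M, Minv = solve(M), relative_residual = res)
}

#' Apply a 3 x 3 colour map to a 3-channel image
#'
#' @param img H x W x 3 array (e.g. a `cone_image`).
#' @param M 3 x 3 matrix applied to each pixel's channel triplet.
#' @param class_out class of the returned image.
#' @return an H x W x 3 array with attributes preserved.
#' @export
apply_colour_map <- function(img, M, class_out = "tristimulus_image") {
  d <- dim(img)
  out <- unflat3(flat3(unclass(img)) %*% t(M), d[1:2])
  structure(out, class = class_out, illuminant = attr(img, "illuminant"),
            scene_id = attr(img, "scene_id"))
}

#' Scale a tristimulus image to a target mean luminance
#'
#' Multiplies all channels by `target / mean(Y)` so the image's mean
#' luminance equals `target` (display convention: images shown at a mean
#' luminance of 8 cd m^-2).
#'
#' @param xyz a `tristimulus_image`.
#' @param target mean luminance in cd m^-2.
#' @return the rescaled `tristimulus_image`.
#' @export
scale_mean_luminance <- function(xyz, target = 8) {
  mY <- mean(flat3(unclass(xyz))[, 2L])
  if (!is.finite(mY) || mY <= 0) stop("image has non-positive mean luminance")
  out <- unclass(xyz) * (target / mY)
  attributes(out) <- attributes(xyz)
  out
}

## IEC 61966-2-1 sRGB primaries (D65), XYZ (Y in [0,1]) -> linear RGB.
.m_xyz2srgb <- matrix(c(
   3.2404542, -1.5371385, -0.4985314,
  -0.9692660,  1.8760108,  0.0415560,
   0.0556434, -0.2040259,  1.0572252), 3, 3, byrow = TRUE)

srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Render a tristimulus image to 8-bit sRGB with gamut flags
#'
#' XYZ is scaled so that `peak_white_Y` maps to unit display luminance,
#' converted with the standard sRGB matrix, flagged where any linear
#' channel leaves [0, 1] (out of the display gamut), clipped, and
#' transfer-encoded to 8 bits.
#'
#' @param xyz a `tristimulus_image`.
#' @param peak_white_Y luminance (same units as Y) that maps to display
#'   white.
#' @param tol numeric slack on the [0, 1] gamut bounds.
#' @return list with `rgb` (H x W x 3 integer array in 0..255) and
#'   `in_gamut` (H x W logical).
#' @export
srgb_render <- function(xyz, peak_white_Y = 1, tol = 1e-6) {
  d <- dim(xyz)
  lin <- flat3(unclass(xyz)) %*% t(.m_xyz2srgb) / peak_white_Y
  ok <- rowSums(lin < -tol | lin > 1 + tol) == 0L
  lin[lin < 0] <- 0; lin[lin > 1] <- 1
  bytes <- matrix(as.integer(round(255 * srgb_encode(lin))), ncol = 3L)
  list(rgb = array(bytes, c(d[1:2], 3L)),
       in_gamut = matrix(ok, d[1L], d[2L]))
}

#' Percentage of pixels inside the display gamut
#'
#' @param in_gamut logical matrix from [srgb_render()].
#' @return percentage in [0, 100]. Scenes are usable when at least 95% of
#'   their colours fall inside the gamut.
#' @export
gamut_fraction <- function(in_gamut) 100 * mean(in_gamut)
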