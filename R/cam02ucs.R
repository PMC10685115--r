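## CIECAM02 forward model and the CAM02-UCS uniform space.
##
## Notation follows the CIE 159:2004 step-by-step equations. Only the
## forward direction is implemented; the analysis needs appearance
## coordinates (J, a, b), never the inverse.

.cat02 <- matrix(c(
   0.7328, 0.4296, -0.1624,
  -0.7036, 1.6975,  0.0061,
   0.0030, 0.0136,  0.9834), 3, 3, byrow = TRUE)
.cat02_inv <- solve(.cat02)
.hpe_m <- matrix(c(
   0.38971, 0.68898, -0.07868,
  -0.22981, 1.18340,  0.04641,
   0.00000, 0.00000,  1.00000), 3, 3, byrow = TRUE)

.surrounds <- list(
  average = c(F = 1.0, c = 0.690, Nc = 1.0),
  dim     = c(F = 0.9, c = 0.590, Nc = 0.9),
  dark    = c(F = 0.8, c = 0.525, Nc = 0.8))

#' CIECAM02 viewing conditions
#'
#' The adopted white, adapting luminance and surround under which
#' appearance coordinates are computed. Sample and white tristimulus
#' values are normalized jointly so that the white has Y = 100 (relative
#' colorimetry); absolute level enters only through `L_A`.
#'
#' @param white_XYZ length-3 tristimulus of the adopted white.
#' @param L_A adapting field luminance in cd m^-2 (> 0). The pipeline
#'   default is one-fifth of the display mean luminance of 8 cd m^-2.
#' @param Y_b relative background luminance factor in (0, 100].
#' @param surround `"average"`, `"dim"` or `"dark"`.
#' @param full_adaptation if `TRUE` the degree of adaptation D is forced
#'   to 1 instead of the CIECAM02 formula.
#' @return an object of class `viewing_conditions`.
#' @export
viewing_conditions <- function(white_XYZ, L_A = 8 / 5, Y_b = 20,
                               surround = c("dim", "average", "dark"),
                               full_adaptation = FALSE) {
  surround <- match.arg(surround)
  white_XYZ <- as.numeric(white_XYZ)
  stopifnot(length(white_XYZ) == 3L, all(is.finite(white_XYZ)),
            white_XYZ[2L] > 0, L_A > 0, Y_b > 0, Y_b <= 100)
  structure(list(white_XYZ = white_XYZ, L_A = L_A, Y_b = Y_b,
                 surround = surround, full_adaptation = full_adaptation),
            class = "viewing_conditions")
}

## Post-adaptation cone nonlinearity, sign-symmetric.
cam02_nonlin <- function(x, FL) {
  t <- (FL * abs(x) / 100)^0.42
  sign(x) * 400 * t / (t + 27.13) + 0.1
}

## Forward CIECAM02 on an n x 3 matrix of XYZ; returns list of correlates.
ciecam02_forward <- function(xyz, vc) {
  sur <- .surrounds[[vc$surround]]
  w <- vc$white_XYZ * (100 / vc$white_XYZ[2L])
  xyz <- xyz * (100 / vc$white_XYZ[2L])

  D <- if (vc$full_adaptation) 1 else
    sur[["F"]] * (1 - (1 / 3.6) * exp((-vc$L_A - 42) / 92))
  D <- min(max(D, 0), 1)

  k <- 1 / (5 * vc$L_A + 1)
  FL <- 0.2 * k^4 * (5 * vc$L_A) + 0.1 * (1 - k^4)^2 * (5 * vc$L_A)^(1 / 3)
  n <- vc$Y_b / w[2L]
  Nbb <- 0.725 * (1 / n)^0.2
  Ncb <- Nbb
  z <- 1.48 + sqrt(n)

  rgb_w <- as.numeric(.cat02 %*% w)
  gain <- w[2L] * D / rgb_w + 1 - D
  rgb  <- xyz %*% t(.cat02)
  rgb_c <- sweep(rgb, 2L, gain, `*`)
  rgb_wc <- rgb_w * gain

  hpe_map <- .hpe_m %*% .cat02_inv
  rgb_p  <- rgb_c %*% t(hpe_map)
  rgb_wp <- as.numeric(hpe_map %*% rgb_wc)

  rgb_a  <- cam02_nonlin(rgb_p, FL)
  rgb_wa <- cam02_nonlin(rgb_wp, FL)

  a <- rgb_a[, 1L] - 12 * rgb_a[, 2L] / 11 + rgb_a[, 3L] / 11
  b <- (rgb_a[, 1L] + rgb_a[, 2L] - 2 * rgb_a[, 3L]) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360

  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  A  <- (2 * rgb_a[, 1L] + rgb_a[, 2L] + rgb_a[, 3L] / 20 - 0.305) * Nbb
  Aw <- (2 * rgb_wa[1L] + rgb_wa[2L] + rgb_wa[3L] / 20 - 0.305) * Nbb

  J <- 100 * pmax(A / Aw, 0)^(sur[["c"]] * z)
  t <- (50000 / 13) * sur[["Nc"]] * Ncb * et * sqrt(a^2 + b^2) /
    (rgb_a[, 1L] + rgb_a[, 2L] + 21 * rgb_a[, 3L] / 20)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^n)^0.73
  M <- C * FL^0.25
  Q <- (4 / sur[["c"]]) * sqrt(J / 100) * (Aw + 4) * FL^0.25
  s <- 100 * sqrt(M / pmax(Q, .Machine$double.eps))
  list(J = J, C = C, h = h, M = M, Q = Q, s = s)
}

## CAM02-UCS transform of CIECAM02 lightness/colourfulness/hue.
cam02ucs_from_JMh <- function(J, M, h) {
  Jp <- 1.7 * J / (1 + 0.007 * J)
  Mp <- (1 / 0.0228) * log(1 + 0.0228 * M)
  cbind(J = Jp, a = Mp * cos(h * pi / 180), b = Mp * sin(h * pi / 180))
}

#' CAM02-UCS appearance coordinates of a tristimulus image
#'
#' Runs the CIECAM02 forward model per pixel (chromatic adaptation with
#' degree D, cone nonlinearity, lightness J, colourfulness M, hue h) and
#' maps to the approximately uniform space CAM02-UCS. Coordinates are
#' reported as (J, a, b): J a correlate of lightness, a of
#' redness-greenness, b of yellowness-blueness.
#'
#' @param xyz a `tristimulus_image` (H x W x 3 array) or an n x 3 matrix.
#' @param vc a [viewing_conditions()].
#' @param max_flagged error if more than this proportion of pixels yields
#'   non-finite appearance coordinates.
#' @return an `appearance_image` of the same spatial shape (or n x 3
#'   matrix input -> matrix output) with attribute `flagged` (logical,
#'   non-finite pixels, set to NA).
#' @export
cam02ucs <- function(xyz, vc, max_flagged = 0.01) {
  is_img <- length(dim(xyz)) == 3L
  m <- if (is_img) flat3(unclass(xyz)) else as.matrix(unclass(xyz))
  cam <- ciecam02_forward(m, vc)
  ucs <- cam02ucs_from_JMh(cam$J, cam$M, cam$h)
  bad <- rowSums(!is.finite(ucs)) > 0L
  if (mean(bad) > max_flagged)
    stop(sprintf("%.1f%% of pixels outside the CIECAM02 domain", 100 * mean(bad)))
  ucs[bad, ] <- NA_real_
  if (is_img) {
    d <- dim(xyz)
    structure(unflat3(ucs, d[1:2]), class = "appearance_image",
              illuminant = attr(xyz, "illuminant"),
              scene_id = attr(xyz, "scene_id"),
              flagged = matrix(bad, d[1L], d[2L]))
  } else {
    structure(ucs, flagged = bad)
  }
}

#' @rdname cam02ucs
#' @return `ciecam02_correlates()` returns the raw CIECAM02 correlates
#'   (J, C, h, M, Q, s) as a data frame, mainly for validation.
#' @export
ciecam02_correlates <- function(xyz, vc) {
  m <- if (length(dim(xyz)) == 3L) flat3(unclass(xyz)) else as.matrix(unclass(xyz))
  as.data.frame(ciecam02_forward(m, vc))
}
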