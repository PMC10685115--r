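## Colour-difference vectors, generalized-metamerism change Delta E, mean
## Delta E over pixel pairs, linear regression summaries and the scene
## chromatic-axis statistic.

#' Vector colour difference between two points
#'
#' For CAM02-UCS coordinates p1 = (J1, a1, b1), p2 = (J2, a2, b2) under a
#' given illuminant, the colour relation between the points is represented
#' by the difference vector Delta c = p1 - p2.
#'
#' @param p1,p2 length-3 (J, a, b) coordinates.
#' @return length-3 difference vector (dJ, da, db).
#' @export
colour_difference <- function(p1, p2) as.numeric(p1) - as.numeric(p2)

#' Generalized-metamerism change between two difference vectors
#'
#' Delta E = |Delta c' - Delta c|: the Euclidean distance between a pair's
#' colour-difference vectors under two illuminants. Zero when the pair's
#' colour relation is perfectly preserved; grows as relational colour
#' constancy fails.
#'
#' @param dc,dc_prime length-3 colour-difference vectors.
#' @return non-negative scalar in CAM02-UCS units.
#' @export
#' @examples
#' metamerism_change(c(0, 0, 0), c(3, 4, 0)) # 5
metamerism_change <- function(dc, dc_prime) {
  sqrt(sum((as.numeric(dc_prime) - as.numeric(dc))^2))
}

#' Mean generalized-metamerism change over a pair sample
#'
#' Computes Delta E for every pixel pair and averages. By design the same
#' pair sample used for the MRD estimate of the condition is passed in, so
#' the two statistics describe identical point sets.
#'
#' @param app_A,app_B `appearance_image`s of identical shape (the scene
#'   under the two illuminants).
#' @param pairs pair matrix from [sample_pixel_pairs()].
#' @return list with `mean_delta_E`, `sd_delta_E` and `n_pairs` (pairs with
#'   finite appearance at all four points).
#' @export
mean_metamerism_change <- function(app_A, app_B, pairs) {
  if (!identical(dim(app_A), dim(app_B))) stop("shape mismatch")
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty pair set")
  a <- flat3(unclass(app_A)); b <- flat3(unclass(app_B))
  dc  <- a[pairs[, 1L], , drop = FALSE] - a[pairs[, 2L], , drop = FALSE]
  dcp <- b[pairs[, 1L], , drop = FALSE] - b[pairs[, 2L], , drop = FALSE]
  dE <- sqrt(rowSums((dcp - dc)^2))
  ok <- is.finite(dE)
  if (!any(ok)) stop("no finite pairs")
  list(mean_delta_E = mean(dE[ok]), sd_delta_E = sd(dE[ok]), n_pairs = sum(ok))
}

#' Ordinary least-squares line with adjusted goodness of fit
#'
#' Linear regression of y on x with R^2 adjusted for the degrees of
#' freedom of the regression: adj R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1).
#'
#' @param x predictor values (at least 3 distinct).
#' @param y response values.
#' @return an object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r2`, `adjusted_R2`, `dof` and the `lm` fit.
#' @export
regress_xy <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) <= 0) stop("degenerate predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = sm$r.squared, adjusted_R2 = sm$adj.r.squared,
                 dof = fit$df.residual, lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x  (adj R2 = %.3f, dof = %d)\n",
              x$intercept, x$slope, x$adjusted_R2, x$dof))
  invisible(x)
}

#' Direction of the major axis of scene chromatic variation
#'
#' Angle of the first principal axis of the mean-centred (a, b) scatter of
#' an appearance image, mapped to (-90, 90] degrees with 0 = the +a
#' (reddish-greenish) axis and 90 = the +b (yellowish-bluish) axis.
#'
#' @param app an `appearance_image`.
#' @param isotropy_tol flag the axis as ambiguous when the ratio of
#'   principal standard deviations is below `1 + isotropy_tol`.
#' @return list with `angle_deg`, `axis_ratio` (sd1/sd2) and `ambiguous`.
#' @export
scene_chromatic_axis <- function(app, isotropy_tol = 0.05) {
  m <- flat3(unclass(app))[, 2:3, drop = FALSE]
  m <- m[is.finite(m[, 1L]) & is.finite(m[, 2L]), , drop = FALSE]
  if (nrow(unique(m)) < 2L) stop("need at least 2 distinct chromaticities")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1L]
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ratio <- pc$sdev[1L] / max(pc$sdev[2L], .Machine$double.eps)
  list(angle_deg = unname(ang), axis_ratio = unname(ratio),
       ambiguous = ratio < 1 + isotropy_tol)
}
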