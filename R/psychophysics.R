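## Simulated 2AFC schedule, psychometric fitting, d-prime, BCa bootstrap
## confidence intervals, and locally weighted regression.

#' Build one session's randomized trial schedule
#'
#' One trial per (scene, MRD level) combination, presented in random order
#' with the corrected side assigned uniformly at random per trial. With
#' the standard design of 10 scenes and 7 levels a session has 70 trials.
#'
#' @param scene_ids character vector of scene labels.
#' @param bin_indices integer vector of MRD level bins (0-6).
#' @param session session id recorded on each row.
#' @return data frame with columns `session`, `trial`, `scene_id`,
#'   `bin_index`, `corrected_side`.
#' @export
build_session_schedule <- function(scene_ids, bin_indices = 0:6, session = 1L) {
  g <- expand.grid(scene_id = scene_ids, bin_index = bin_indices,
                   stringsAsFactors = FALSE)
  g <- g[sample.int(nrow(g)), , drop = FALSE]
  data.frame(session = session, trial = seq_len(nrow(g)),
             scene_id = g$scene_id, bin_index = g$bin_index,
             corrected_side = sample(c("left", "right"), nrow(g), TRUE),
             stringsAsFactors = FALSE)
}

neg_loglik_psy <- function(par, x, k, n, lapse_max) {
  mu <- par[1L]; sigma <- exp(par[2L]); lapse <- par[3L]
  if (lapse < 0 || lapse > lapse_max || !is.finite(sigma)) return(1e10)
  p <- pmin(pmax(psychometric_prob(x, mu, sigma, lapse), 1e-9), 1 - 1e-9)
  -sum(dbinom(k, n, p, log = TRUE))
}

#' Fit an inverse-cumulative-Gaussian psychometric function with lapse
#'
#' Maximum-likelihood fit of p(x) = 0.5 + (0.5 - lambda) Phi((x - mu) /
#' sigma) to per-level misidentification counts, with the lapse rate
#' lambda bounded in [0, `lapse_max`] and a multi-start optimizer
#' (quantile-based mu / sigma grid). The guessing rate is fixed at the
#' 2AFC floor of 0.5. `variance_accounted` is 100 (1 - SS_res / SS_tot)
#' on the observed level proportions, reported for comparability with
#' percentage-of-variance summaries.
#'
#' @param x level values (e.g. MRD bin centres, percent), >= 3 levels.
#' @param k misidentification counts per level.
#' @param n trials per level (scalar or vector).
#' @param lapse_max upper bound on the lapse rate.
#' @return an object of class `psychometric_fit`: list with `mu`, `sigma`,
#'   `lapse`, `guess`, `loglik`, `variance_accounted`, `fitted` and
#'   `predict` (function of x).
#' @export
fit_psychometric <- function(x, k, n, lapse_max = 0.06) {
  stopifnot(length(x) >= 3L, length(k) == length(x))
  n <- rep_len(n, length(x))
  stopifnot(all(n >= 1L), all(k >= 0L), all(k <= n))
  phat <- k / n
  rng <- diff(range(x))
  if (rng <= 0) stop("need at least 3 distinct levels")
  mu0 <- c(quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
           x[which.min(abs(phat - 0.75))])
  sig0 <- rng * c(1 / 8, 1 / 4, 1 / 2, 1)
  starts <- expand.grid(mu = mu0, sigma = sig0)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$mu[i], log(starts$sigma[i]), 0.01), neg_loglik_psy,
            x = x, k = k, n = n, lapse_max = lapse_max, method = "L-BFGS-B",
            lower = c(min(x) - 3 * rng, log(rng * 1e-3), 0),
            upper = c(max(x) + 3 * rng, log(rng * 20), lapse_max),
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed to converge from all starts")
  mu <- best$par[1L]; sigma <- exp(best$par[2L]); lapse <- best$par[3L]
  pred <- function(xx) psychometric_prob(xx, mu, sigma, lapse)
  fitted <- pred(x)
  ss_tot <- sum((phat - mean(phat))^2)
  va <- if (ss_tot > 0) 100 * (1 - sum((phat - fitted)^2) / ss_tot) else NA_real_
  structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = 0.5,
                 loglik = -best$value, variance_accounted = va,
                 fitted = fitted, predict = pred),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: mu = %.3f, sigma = %.3f, lapse = %.4f (logLik %.2f%s)\n",
    x$mu, x$sigma, x$lapse, x$loglik,
    if (is.finite(x$variance_accounted))
      sprintf(", %.1f%% variance accounted", x$variance_accounted) else ""))
  invisible(x)
}

#' Discrimination index d' from a 2AFC choice proportion
#'
#' d' = sqrt(2) Phi^-1(p) where p is the proportion of trials on which the
#' systematically preferred (corrected) side was chosen; p is clamped to
#' [1/(2n), 1 - 1/(2n)] before the transform so extreme proportions stay
#' finite.
#'
#' @param p choice proportion in [0, 1].
#' @param n trial count behind `p` (>= 1).
#' @return d' (0 at chance p = 0.5, increasing in p).
#' @export
#' @examples
#' dprime_from_proportion(0.76, 100)
dprime_from_proportion <- function(p, n) {
  stopifnot(n >= 1L, p >= 0, p <= 1)
  p <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  sqrt(2) * qnorm(p)
}

#' BCa bootstrap confidence interval
#'
#' Efron's bias-corrected and accelerated interval: bias correction z0
#' from the proportion of bootstrap replicates below the point estimate,
#' acceleration from jackknife skewness. Falls back to the percentile
#' interval (with `method = "percentile"`) when the bootstrap distribution
#' is degenerate.
#'
#' @param x numeric sample (length >= 2).
#' @param statistic function of a numeric vector returning a scalar.
#' @param B bootstrap replications.
#' @param level confidence level.
#' @return an object of class `bootstrap_ci`: list with `low`, `high`,
#'   `estimate`, `level`, `B`, `method` ("bca" or "percentile") and `z0`,
#'   `accel`.
#' @export
bca_ci <- function(x, statistic = mean, B = 1000L, level = 0.95) {
  n <- length(x)
  stopifnot(n >= 2L, B >= 1L)
  theta <- statistic(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  boots <- vapply(seq_len(B), function(b) statistic(x[idx[, b]]), numeric(1L))
  alpha <- (1 - level) / 2
  if (max(boots) - min(boots) < .Machine$double.eps * (1 + abs(theta))) {
    return(structure(list(low = theta, high = theta, estimate = theta,
                          level = level, B = B, method = "percentile",
                          z0 = 0, accel = 0), class = "bootstrap_ci"))
  }
  prop <- (sum(boots < theta) + 0.5 * sum(boots == theta)) / B
  if (prop <= 0 || prop >= 1) {
    q <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    return(structure(list(low = q[1L], high = q[2L], estimate = theta,
                          level = level, B = B, method = "percentile",
                          z0 = NA_real_, accel = NA_real_),
                     class = "bootstrap_ci"))
  }
  z0 <- qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1L))
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  q <- quantile(boots, adj, names = FALSE, type = 6)
  structure(list(low = q[1L], high = q[2L], estimate = theta, level = level,
                 B = B, method = "bca", z0 = z0, accel = a),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.0f%% %s bootstrap CI: [%.4g, %.4g] (estimate %.4g, B = %d)\n",
              100 * x$level, x$method, x$low, x$high, x$estimate, x$B))
  invisible(x)
}

#' Locally weighted polynomial regression evaluator
#'
#' Tricube-weighted local regression of the stated degree (degree 1:
#' locally weighted linear regression; degree 2: locally weighted
#' quadratic), exposed as a curve evaluator. Fitting is exact-surface
#' (no interpolation grid) so polynomial data of matching degree is
#' reproduced to numerical precision.
#'
#' @param x,y data points (at least `max(4, degree + 2)`).
#' @param degree 1 or 2.
#' @param span smoothing fraction in (0, 1].
#' @return a function mapping new x values to fitted values.
#' @export
loess_fit <- function(x, y, degree = 1L, span = 0.75) {
  stopifnot(degree %in% c(1L, 2L), length(x) == length(y),
            length(x) >= max(4L, degree + 2L), span > 0, span <= 1)
  if (span * length(x) < degree + 2L)
    stop("span too small for local fits of this degree")
  df <- data.frame(x = x, y = y)
  fit <- loess(y ~ x, data = df, degree = degree, span = span,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  function(newx) predict(fit, newdata = data.frame(x = newx))
}
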