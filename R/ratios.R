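## Spatial cone-excitation ratios, relative deviations, Monte-Carlo MRD
## estimation and binning, and the ratio-correction procedure.

#' Spatial cone-excitation ratio of a pair of points
#'
#' For excitations q(1), q(2) at two scene points the spatial ratio is the
#' component-wise quotient r = (qL(1)/qL(2), qM(1)/qM(2), qS(1)/qS(2)).
#' All divisors must be positive; pair validity during sampling is handled
#' by [mean_relative_deviation()]'s divisor guard rather than errors.
#'
#' @param q_first,q_second length-3 positive LMS excitations.
#' @return length-3 ratio vector.
#' @export
#' @examples
#' ratio_vector(c(2, 4, 6), c(1, 2, 3))
ratio_vector <- function(q_first, q_second) {
  if (any(q_second <= 0) || any(q_first <= 0))
    stop("excitations must be positive")
  as.numeric(q_first) / as.numeric(q_second)
}

#' Relative deviation between two ratio vectors
#'
#' Delta r = |r' - r| / min(|r'|, |r|) with Euclidean norms: a sensitive,
#' symmetric measure of how far spatial ratios move under an illuminant
#' change (0 when ratios are perfectly preserved).
#'
#' @param r,r_prime length-3 ratio vectors under the two illuminants.
#' @return non-negative scalar.
#' @export
#' @examples
#' relative_deviation(c(1, 1, 1), c(2, 2, 2)) # 1
relative_deviation <- function(r, r_prime) {
  nr <- sqrt(sum(r^2)); np <- sqrt(sum(r_prime^2))
  sqrt(sum((r_prime - r)^2)) / min(nr, np)
}

## Vectorised Delta r for n x 3 ratio matrices.
relative_deviation_rows <- function(r, rp) {
  sqrt(rowSums((rp - r)^2)) / pmin(sqrt(rowSums(r^2)), sqrt(rowSums(rp^2)))
}

#' Sample random pixel pairs from an image
#'
#' Draws `n` ordered pairs of distinct valid pixels uniformly with
#' replacement across pairs, deterministic given the R random stream.
#' Default sample size is 50 000 pairs, at which the Monte-Carlo mean
#' relative deviation is stable across resamplings.
#'
#' @param shape integer c(H, W).
#' @param n number of pairs.
#' @param mask optional H x W logical; only TRUE pixels are sampled.
#' @return an `n` x 2 integer matrix of linear (column-major) pixel indices.
#' @export
sample_pixel_pairs <- function(shape, n = 50000L, mask = NULL) {
  npix <- shape[1L] * shape[2L]
  valid <- if (is.null(mask)) seq_len(npix) else which(as.vector(mask))
  if (length(valid) < 2L) stop("need at least 2 valid pixels")
  i <- valid[sample.int(length(valid), n, replace = TRUE)]
  j <- valid[sample.int(length(valid), n, replace = TRUE)]
  clash <- which(i == j)
  while (length(clash) > 0L) {
    j[clash] <- valid[sample.int(length(valid), length(clash), replace = TRUE)]
    clash <- clash[i[clash] == j[clash]]
  }
  cbind(first = i, second = j)
}

## Delta r for every pair between two cone images, with divisor guard:
## pairs where any excitation falls below eps_factor x channel mean (in
## either image) are returned as NA.
pairwise_deviation <- function(qa, qb, pairs, eps_factor = 1e-6) {
  epsa <- eps_factor * colMeans(qa)
  epsb <- eps_factor * colMeans(qb)
  a1 <- qa[pairs[, 1L], , drop = FALSE]; a2 <- qa[pairs[, 2L], , drop = FALSE]
  b1 <- qb[pairs[, 1L], , drop = FALSE]; b2 <- qb[pairs[, 2L], , drop = FALSE]
  ok <- rowSums(sweep(a1, 2L, epsa, `<=`) | sweep(a2, 2L, epsa, `<=`) |
                sweep(b1, 2L, epsb, `<=`) | sweep(b2, 2L, epsb, `<=`)) == 0L
  out <- rep(NA_real_, nrow(pairs))
  if (any(ok))
    out[ok] <- relative_deviation_rows(a1[ok, , drop = FALSE] / a2[ok, , drop = FALSE],
                                       b1[ok, , drop = FALSE] / b2[ok, , drop = FALSE])
  out
}

#' Mean relative deviation (MRD) in spatial cone-excitation ratios
#'
#' Monte-Carlo estimate of the mean of Delta r over random pixel pairs
#' between two renderings of the same scene (the same pixel grid under two
#' illuminants). Pairs whose excitations fail the divisor guard in either
#' image are dropped. Optionally the sampling is repeated to report the
#' resampling SD of the estimate.
#'
#' @param A,B `cone_image`s of identical shape (reference and test).
#' @param pairs optional pair matrix from [sample_pixel_pairs()]; when
#'   `NULL`, `n_pairs` pairs are drawn from the current random stream.
#' @param n_pairs pairs per sample when `pairs` is `NULL`.
#' @param resamples number of additional independent pair samples used for
#'   `resample_sd` (0 = skip).
#' @param eps_factor divisor guard: excitations below `eps_factor` times
#'   the channel mean reject the pair.
#' @return an object of class `mrd_estimate`: list with `mean_deviation`
#'   (fraction), `mrd_percent`, `n_pairs` (valid pairs used), `resample_sd`
#'   (fraction, `NA` if not requested) and `pairs` (the sample used).
#' @export
mean_relative_deviation <- function(A, B, pairs = NULL, n_pairs = 50000L,
                                    resamples = 0L, eps_factor = 1e-6) {
  da <- dim(A); db <- dim(B)
  if (!identical(da, db)) stop("cone images must have identical shape")
  qa <- flat3(unclass(A)); qb <- flat3(unclass(B))
  if (is.null(pairs)) pairs <- sample_pixel_pairs(da[1:2], n_pairs)
  dev <- pairwise_deviation(qa, qb, pairs, eps_factor)
  if (all(is.na(dev))) stop("all pairs rejected by the divisor guard")
  est <- mean(dev, na.rm = TRUE)
  rs <- NA_real_
  if (resamples > 0L) {
    reps <- vapply(seq_len(resamples), function(k) {
      p <- sample_pixel_pairs(da[1:2], nrow(pairs))
      mean(pairwise_deviation(qa, qb, p, eps_factor), na.rm = TRUE)
    }, numeric(1L))
    rs <- sd(c(est, reps))
  }
  structure(list(mean_deviation = est, mrd_percent = 100 * est,
                 n_pairs = sum(!is.na(dev)), resample_sd = rs, pairs = pairs),
            class = "mrd_estimate")
}

#' @export
print.mrd_estimate <- function(x, ...) {
  cat(sprintf("MRD = %.4f%% over %d pairs%s\n", x$mrd_percent, x$n_pairs,
              if (is.finite(x$resample_sd))
                sprintf(" (resample SD %.4f%%)", 100 * x$resample_sd) else ""))
  invisible(x)
}

#' Classify an MRD estimate into a 1%-wide level bin
#'
#' Experimental MRD levels are half-open bins [k%, (k+1)%) of width 1%,
#' seven in all (indices 0-6, centres 0.5%-6.5%).
#'
#' @param mrd an `mrd_estimate` or an MRD value in percent.
#' @return the integer bin index 0-6, or `NA_integer_` when the MRD is
#'   >= 7% (out of range; callers resample illuminants).
#' @export
#' @examples
#' mrd_bin(0.3)  # 0
#' mrd_bin(6.99) # 6
mrd_bin <- function(mrd) {
  p <- if (inherits(mrd, "mrd_estimate")) mrd$mrd_percent else as.numeric(mrd)
  if (!is.finite(p) || p < 0) stop("MRD must be a non-negative percentage")
  if (p >= 7) return(NA_integer_)
  as.integer(floor(p))
}

#' @rdname mrd_bin
#' @param bin_index integer bin 0-6.
#' @return `mrd_bin_centre()` returns the bin centre in percent (0.5-6.5).
#' @export
mrd_bin_centre <- function(bin_index) bin_index + 0.5

#' Fit per-cone-class correction gains
#'
#' For each cone class c, the test excitations B_c(i) are regressed through
#' the origin on the reference excitations A_c(i) over all pixels i:
#' k_c = sum(B_c A_c) / sum(A_c^2). Replacing the test image by
#' k_c A_c(i) preserves every spatial cone-excitation ratio of the
#' reference exactly while best approximating the test rendering.
#'
#' @param reference,test `cone_image`s of identical shape (A and B).
#' @param direction `"test_on_reference"` (default; gains scale the
#'   reference to approximate the test) or `"reference_on_test"` (the
#'   transposed reading: gains are fitted with the roles swapped and
#'   inverted, so they still multiply the reference).
#' @return an object of class `correction_gains`: positive numeric length
#'   3 (kL, kM, kS).
#' @export
fit_correction_gains <- function(reference, test,
                                 direction = c("test_on_reference",
                                               "reference_on_test")) {
  direction <- match.arg(direction)
  if (!identical(dim(reference), dim(test))) stop("shape mismatch")
  a <- flat3(unclass(reference)); b <- flat3(unclass(test))
  k <- if (direction == "test_on_reference") {
    den <- colSums(a * a)
    if (any(den <= 0)) stop("zero denominator in gain fit")
    colSums(b * a) / den
  } else {
    den <- colSums(b * a)
    if (any(den <= 0)) stop("zero denominator in gain fit")
    colSums(b * b) / den
  }
  if (any(!is.finite(k)) || any(k <= 0)) stop("gains must be positive")
  structure(setNames(k, c("kL", "kM", "kS")), class = "correction_gains")
}

#' Apply correction gains to a reference cone image
#'
#' Produces the ratio-corrected image C with C_c(i) = k_c A_c(i); a von
#' Kries (diagonal) transform of the reference, so every pair's ratio
#' vector in C equals that in A and MRD(A, C) is zero up to floating-point
#' rounding.
#'
#' @param reference a `cone_image` (A).
#' @param gains a `correction_gains` (or positive length-3 numeric).
#' @param illuminant optional [spd()] tag for the corrected image (the
#'   test illuminant it approximates).
#' @return the corrected `cone_image`.
#' @export
apply_correction <- function(reference, gains, illuminant = NULL) {
  k <- as.numeric(gains)
  stopifnot(length(k) == 3L, all(k > 0))
  out <- sweep(unclass(reference), 3L, k, `*`)
  structure(out, class = "cone_image",
            illuminant = if (is.null(illuminant)) attr(reference, "illuminant") else illuminant,
            scene_id = attr(reference, "scene_id"))
}
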