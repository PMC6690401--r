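#' Sample Pearson correlation between two rasters
#'
#' Computes `(<LR> - <L><R>) / (sqrt(<L^2> - <L>^2) sqrt(<R^2> - <R>^2))`,
#' the averages running over all pixels. Invariant under independent affine
#' rescaling (positive gain) of either raster.
#'
#' @param left,right numeric matrices of identical shape.
#' @return a correlation in `[-1, 1]`.
#' @export
pearson_r <- function(left, right) {
  stopifnot(is.matrix(left), is.matrix(right), all(dim(left) == dim(right)))
  if (sd(left) == 0 || sd(right) == 0)
    stop("degenerate image: raster has zero variance")
  cor(as.vector(left), as.vector(right))
}

# Pearson r between left columns and right columns displaced by `disp`
# (left column c pairs with right column c - disp), over the overlapping
# region only: no wraparound, no zero padding.
pearson_r_at <- function(pair, disp) {
  W <- ncol(pair$left)
  cl <- max(1L, 1L + disp):min(W, W + disp)
  if (length(cl) < 2L) stop("range error: empty overlap region at displacement ", disp)
  pearson_r(pair$left[, cl, drop = FALSE],
            pair$right[, cl - disp, drop = FALSE])
}

new_correlation_profile <- function(displacement, mean_r, sd_r, n_patterns,
                                    kind = "cross") {
  structure(list(displacement_px = displacement, mean_r = mean_r, sd_r = sd_r,
                 n_patterns = n_patterns, kind = kind),
            class = "correlation_profile")
}

#' Interocular cross-correlation as a function of displacement
#'
#' For each horizontal displacement, computes the Pearson correlation
#' between left-eye pixels and right-eye pixels displaced by that amount
#' (evaluated over the overlapping pixel region only) for every pair in the
#' ensemble, and aggregates the mean and across-pattern SD. With the
#' package's disparity convention, a noise-free ensemble with uniform
#' disparity `D` peaks at displacement `D` with mean correlation ~1.
#'
#' @param pairs a list of normalized `"stereo_pair"` objects.
#' @param displacements integer displacements (pixels), `|disp| < width`.
#' @return a `"correlation_profile"`: displacement, mean r, across-pattern
#'   SD, and the ensemble size.
#' @export
cross_correlation_profile <- function(pairs, displacements = -10:10) {
  check_ensemble(pairs)
  rmat <- vapply(pairs, function(p)
    vapply(displacements, function(k) pearson_r_at(p, k), numeric(1)),
    numeric(length(displacements)))
  rmat <- matrix(rmat, nrow = length(displacements))
  new_correlation_profile(as.integer(displacements),
                          rowMeans(rmat), apply(rmat, 1, sd), length(pairs))
}

#' Monocular autocorrelation as a function of horizontal lag
#'
#' As [cross_correlation_profile()], but correlating one eye's image with a
#' horizontally displaced copy of itself. For freely scattered dots the
#' profile is a triangle vanishing at the dot width (the autocorrelation of
#' a single square dot); forbidding overlap produces negative side-lobes at
#' lags just beyond the dot width in same-polarity patterns.
#'
#' @inheritParams cross_correlation_profile
#' @param lags integer lags in pixels.
#' @param eye `"left"` or `"right"`.
#' @export
monocular_autocorrelation <- function(pairs, lags = 0:12,
                                      eye = c("left", "right")) {
  eye <- match.arg(eye)
  check_ensemble(pairs)
  one <- function(p, k) {
    z <- p[[eye]]
    W <- ncol(z)
    cl <- max(1L, 1L + k):min(W, W + k)
    if (length(cl) < 2L) stop("range error: empty overlap region at lag ", k)
    pearson_r(z[, cl, drop = FALSE], z[, cl - k, drop = FALSE])
  }
  rmat <- vapply(pairs, function(p)
    vapply(lags, function(k) one(p, k), numeric(1)),
    numeric(length(lags)))
  rmat <- matrix(rmat, nrow = length(lags))
  new_correlation_profile(as.integer(lags),
                          rowMeans(rmat), apply(rmat, 1, sd), length(pairs),
                          kind = "auto")
}

check_ensemble <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1,
            all(vapply(pairs, inherits, logical(1), "stereo_pair")))
  if (!all(vapply(pairs, `[[`, logical(1), "normalized")))
    stop("correlation profiles require normalized pairs; see normalize_pair()")
  invisible(TRUE)
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("%s-correlation profile over %d patterns\n",
              if (x$kind == "auto") "Auto" else "Cross", x$n_patterns))
  pk <- which.max(x$mean_r)
  cat(sprintf("  peak mean r = %.3f at displacement %+d px\n",
              x$mean_r[pk], x$displacement_px[pk]))
  invisible(x)
}

#' @export
as.data.frame.correlation_profile <- function(x, ...) {
  data.frame(displacement_px = x$displacement_px, mean_r = x$mean_r,
             sd_r = x$sd_r, n_patterns = x$n_patterns)
}

#' @export
plot.correlation_profile <- function(x, ...) {
  graphics::plot(x$displacement_px, x$mean_r, type = "b", pch = 16,
                 xlab = "displacement (px)", ylab = "mean Pearson r", ...)
  graphics::arrows(x$displacement_px, x$mean_r - x$sd_r,
                   x$displacement_px, x$mean_r + x$sd_r,
                   angle = 90, code = 3, length = 0.02, col = "gray60")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Matched/unmatched pixel-pair statistics of a stereogram
#'
#' Iterates over the pixel pairs aligned at the ensemble's mean disparity
#' and classifies each as MATCHED (background in both eyes, or both pixels
#' covered by the same correlated dot carrying zero disparity noise) or
#' UNMATCHED (everything else: monocular dots, decorrelated or
#' noise-displaced dots, and chance dot coincidences). Returns the
#' empirical probabilities of the closed-form correlation theory:
#'
#' * `d` - probability a monocular pixel is covered by a dot (left/right
#'   symmetrized),
#' * `m`, `u = 1 - m` - probability a pixel pair is matched / unmatched,
#' * `d_m`, `d_u` - conditional dot probabilities given matched / unmatched,
#' * `x` - probability the right pixel holds a dot given an unmatched left
#'   dot.
#'
#' The left/right symmetrization makes the identities
#' `d = m*d_m + u*d_u` and `x*d_u = 2*d_u - 1` hold exactly on counts.
#' When the pattern has no unmatched pairs, `d_u` and `x` are `NA`.
#'
#' @param pair a `"stereo_pair"` with provenance (id) maps.
#' @return a list of class `"pixel_pair_stats"` with fields `d`, `m`, `u`,
#'   `d_m`, `d_u`, `x` and the pair counts `n_pairs`.
#' @export
classify_pixel_pairs <- function(pair) {
  stopifnot(inherits(pair, "stereo_pair"))
  if (is.null(pair$left_ids) || is.null(pair$right_ids))
    stop("provenance required: pair carries no dot-id maps")
  D <- pair$params$mean_disparity_px
  W <- ncol(pair$left_ids)
  cl <- max(1L, 1L + D):min(W, W + D)
  if (length(cl) < 2L) stop("range error: empty overlap region at mean disparity")
  lid <- pair$left_ids[, cl, drop = FALSE]
  rid <- pair$right_ids[, cl - D, drop = FALSE]
  ldot <- lid != 0L
  rdot <- rid != 0L
  same_id <- ldot & rdot & (lid == rid)
  matched_dot <- same_id
  if (any(same_id)) {
    ids <- lid[same_id]
    matched_dot[same_id] <- !pair$uncorrelated &
      pair$dots$correlated[ids] & pair$dots$noise_disp_px[ids] == 0L &
      pair$dots$eye[ids] == "both"
  }
  matched <- (!ldot & !rdot) | matched_dot

  n <- length(lid)
  n_m <- sum(matched)
  n_u <- n - n_m
  amm <- sum(matched_dot)                      # matched, dot in both eyes
  a <- sum(ldot & rdot) - amm                  # unmatched, dot in both eyes
  bL <- sum(ldot & !rdot)                      # dot left only
  bR <- sum(rdot & !ldot)                      # dot right only
  d <- (sum(ldot) + sum(rdot)) / (2 * n)
  m <- n_m / n
  d_m <- if (n_m > 0) amm / n_m else NA_real_
  d_u <- if (n_u > 0) (a + (bL + bR) / 2) / n_u else NA_real_
  x <- if (n_u > 0 && d_u > 0) a / (d_u * n_u) else NA_real_
  structure(list(d = d, m = m, u = 1 - m, d_m = d_m, d_u = d_u, x = x,
                 n_pairs = n), class = "pixel_pair_stats")
}

#' Construct pixel-pair statistics directly
#'
#' Builds a `"pixel_pair_stats"` object from given probabilities, for use
#' with the closed-form predictors ([expected_r()]) without simulating.
#'
#' @param d,m,d_m,d_u probabilities in `[0, 1]`; `u` is derived as `1 - m`
#'   and `x` from `x*d_u = 2*d_u - 1`.
#' @export
pixel_pair_stats <- function(d, m, d_m, d_u) {
  stopifnot(d >= 0, d <= 1, m >= 0, m <= 1, d_m >= 0, d_m <= 1,
            is.na(d_u) || (d_u >= 0 && d_u <= 1))
  structure(list(d = d, m = m, u = 1 - m, d_m = d_m, d_u = d_u,
                 x = if (is.na(d_u) || d_u == 0) NA_real_ else (2 * d_u - 1) / d_u,
                 n_pairs = NA_integer_), class = "pixel_pair_stats")
}

#' @export
print.pixel_pair_stats <- function(x, ...) {
  cat("Pixel-pair statistics:\n")
  cat(sprintf("  d = %.4f  (dot coverage)\n", x$d))
  cat(sprintf("  m = %.4f, u = %.4f  (matched / unmatched pair probability)\n",
              x$m, x$u))
  cat(sprintf("  d_m = %.4f, d_u = %.4f, x = %.4f\n", x$d_m, x$d_u, x$x))
  invisible(x)
}
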