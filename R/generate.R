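#' Generate a random-dot stereogram pair
#'
#' Dots are placed one after another at positions drawn uniformly over the
#' image; the dot's disparity (mean plus per-dot noise) is applied to the x
#' coordinate before drawing, splitting it between the eyes (left gets
#' `+ceiling(delta/2)`, right `-floor(delta/2)`). In overlap mode the dot is
#' drawn regardless, occluding earlier dots; in no-overlap mode a candidate
#' that would overwrite any existing dot pixel (by default in either eye,
#' after the disparity shift) is abandoned and redrawn, up to
#' `max_rejections` consecutive failures. Dot footprints are clipped at the
#' image borders.
#'
#' The returned pair is **not** normalized; call [normalize_pair()] (after
#' any [to_same_polarity()] conversion) before computing correlations or
#' neural responses. Per-eye id rasters record which dot occupies each
#' pixel (0 = background), giving full provenance for
#' [classify_pixel_pairs()].
#'
#' Randomness is split across three deterministic streams derived from
#' `params$seed` (dot luminances; per-dot disparity noise; positions and
#' rejection resampling), so that e.g. a Gaussian noise model with sd 0
#' yields rasters bit-identical to a noise-free run with the same seed, and
#' mixed and dark/darker patterns with the same seed share dot positions.
#'
#' @param params a [stim_params()] specification.
#' @return a list of class `"stereo_pair"` with elements `left`, `right`
#'   (numeric rasters, height x width), `left_ids`, `right_ids` (integer
#'   dot-id rasters), `dots` (data frame of dot records: nominal `x`, `y`,
#'   `lum`, `noise_disp_px`, `correlated`, `eye`), `params`, `normalized`
#'   and `uncorrelated` flags.
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  W <- params$width_px; H <- params$height_px; k <- params$dot_size_px
  N <- params$dot_count %||%
    required_dot_count(params$density, W * H, k * k, params$overlap)
  if (N == 0L) {
    z <- matrix(0, H, W); zi <- matrix(0L, H, W)
    return(new_stereo_pair(z, z, zi, zi, empty_dots(), params))
  }

  nd <- params$noise
  n_dec <- if (nd$type == "decorrelate") as.integer(round(nd$fraction * N)) else 0L

  # stream 1: per-dot luminances (plus per-eye replacement luminances)
  set.seed(derive_seed(params$seed, 1L))
  lum <- draw_lum(params$polarity, N)
  lum_rep_l <- if (n_dec > 0) draw_lum(params$polarity, n_dec) else numeric(0)
  lum_rep_r <- if (n_dec > 0) draw_lum(params$polarity, n_dec) else numeric(0)

  # stream 2: per-dot disparity noise, fixed per dot slot so that rejection
  # resampling redraws only the position
  set.seed(derive_seed(params$seed, 2L))
  noise_disp <- switch(nd$type,
    none = integer(N),
    gaussian = as.integer(round(rnorm(N, 0, nd$sd_px))),
    two_planes = as.integer(sample(c(nd$disp_a_px, nd$disp_b_px), N, replace = TRUE)),
    decorrelate = integer(N))

  # stream 3: positions, decorrelated-slot selection, rejection resampling
  set.seed(derive_seed(params$seed, 3L))
  dec <- logical(N)
  if (n_dec > 0) dec[sample.int(N, n_dec)] <- TRUE
  delta <- params$mean_disparity_px + noise_disp
  sl <- as.integer(ceiling(delta / 2))
  sr <- as.integer(-floor(delta / 2))
  pl <- place_dots_cpp(W, H, k, sl, sr, dec,
                       params$overlap == "no_overlap",
                       params$overlap_check == "nominal",
                       n_dec > 0 && identical(nd$scope, "both_eyes"),
                       params$max_rejections)

  # dot records: rows 1..N are correlated dots (decorrelated slots become
  # the left-eye replacement), rows N+1.. are right-eye replacements
  dots <- data.frame(
    x = pl$x, y = pl$y, lum = lum, noise_disp_px = noise_disp,
    correlated = !dec,
    eye = rep("both", N), stringsAsFactors = FALSE)
  if (n_dec > 0) {
    di <- which(dec)
    dots$x[di] <- pl$xl; dots$y[di] <- pl$yl
    dots$lum[di] <- lum_rep_l
    dots$noise_disp_px[di] <- 0L
    dots$eye[di] <- "left"
    dots <- rbind(dots, data.frame(
      x = pl$xr, y = pl$yr, lum = lum_rep_r, noise_disp_px = 0L,
      correlated = FALSE, eye = "right", stringsAsFactors = FALSE))
  }

  left <- matrix(0, H, W); right <- matrix(0, H, W)
  il <- pl$left_ids != 0L
  left[il] <- dots$lum[pl$left_ids[il]]
  ir <- pl$right_ids != 0L
  right[ir] <- dots$lum[pl$right_ids[ir]]

  new_stereo_pair(left, right, pl$left_ids, pl$right_ids, dots, params)
}

draw_lum <- function(polarity, n) {
  switch(polarity,
    mixed = sample(c(-1, 1), n, replace = TRUE),
    white = rep(1, n),
    black = rep(-1, n),
    dark_darker = sample(c(-1, -0.5), n, replace = TRUE))
}

empty_dots <- function() {
  data.frame(x = integer(0), y = integer(0), lum = numeric(0),
             noise_disp_px = integer(0), correlated = logical(0),
             eye = character(0), stringsAsFactors = FALSE)
}

new_stereo_pair <- function(left, right, left_ids, right_ids, dots, params,
                            normalized = FALSE, uncorrelated = FALSE) {
  structure(list(left = left, right = right,
                 left_ids = left_ids, right_ids = right_ids,
                 dots = dots, params = params,
                 normalized = normalized, uncorrelated = uncorrelated),
            class = "stereo_pair")
}

#' Generate a binocularly uncorrelated stereogram pair
#'
#' Draws two independent monocular dot patterns with identical parameters
#' but independent derived seeds and packages the left eye of one with the
#' right eye of the other. Used as the baseline stimulus when normalizing
#' model-neuron tuning curves; the pair is flagged `uncorrelated = TRUE`.
#'
#' @inheritParams generate_pair
#' @return a `"stereo_pair"` with `uncorrelated = TRUE`.
#' @export
generate_uncorrelated_pair <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  pa <- params; pa$seed <- derive_seed(params$seed, 101L)
  pb <- params; pb$seed <- derive_seed(params$seed, 102L)
  a <- generate_pair(pa)
  b <- generate_pair(pb)
  na <- nrow(a$dots)
  dots <- rbind(
    transform(a$dots, eye = "left", correlated = FALSE),
    transform(b$dots, eye = "right", correlated = FALSE))
  rid <- b$right_ids
  rid[rid != 0L] <- rid[rid != 0L] + na
  new_stereo_pair(a$left, b$right, a$left_ids, rid, dots, params,
                  uncorrelated = TRUE)
}

#' Convert a mixed-polarity pair to same polarity
#'
#' Takes the elementwise absolute value of both rasters, turning every dot
#' white (`target = "white"`), then optionally inverts the sign so every
#' dot is black (`target = "black"`). Dot positions and provenance maps are
#' unchanged: the same dot pattern underlies both polarity conditions.
#' Conversion must precede normalization.
#'
#' @param pair an unnormalized mixed-polarity `"stereo_pair"`.
#' @param target `"white"` or `"black"`.
#' @return the converted `"stereo_pair"`.
#' @export
to_same_polarity <- function(pair, target = c("white", "black")) {
  target <- match.arg(target)
  stopifnot(inherits(pair, "stereo_pair"))
  if (pair$normalized)
    stop("sequencing error: polarity conversion must precede normalization")
  if (pair$params$polarity != "mixed")
    stop("to_same_polarity() expects a mixed-polarity pair")
  s <- if (target == "white") 1 else -1
  pair$left <- s * abs(pair$left)
  pair$right <- s * abs(pair$right)
  pair$dots$lum <- s * abs(pair$dots$lum)
  pair$params$polarity <- target
  pair
}

#' Normalize a stereogram pair to zero mean and unit variance
#'
#' Each monocular image is independently shifted and scaled so its pixel
#' mean is 0 and its pixel mean square is 1, representing low-level
#' luminance and contrast adaptation and ensuring all images have the same
#' contrast energy. Idempotent; errors on a constant raster.
#'
#' @param pair a `"stereo_pair"`.
#' @return the pair with `normalized = TRUE`.
#' @export
normalize_pair <- function(pair) {
  stopifnot(inherits(pair, "stereo_pair"))
  pair$left <- norm01(pair$left)
  pair$right <- norm01(pair$right)
  pair$normalized <- TRUE
  pair
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf("Stereo pair: %d x %d px, %d dot records (%s, %s)%s%s\n",
              ncol(x$left), nrow(x$left), nrow(x$dots),
              x$params$polarity, gsub("_", "-", x$params$overlap),
              if (x$normalized) ", normalized" else "",
              if (x$uncorrelated) ", uncorrelated eyes" else ""))
  cat(sprintf("  coverage L %.3f / R %.3f, interocular r at mean disparity: %.3f\n",
              mean(x$left_ids != 0L), mean(x$right_ids != 0L),
              tryCatch(pearson_r_at(x, x$params$mean_disparity_px),
                       error = function(e) NA_real_)))
  invisible(x)
}

#' @export
plot.stereo_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (eye in c("left", "right")) {
    z <- x[[eye]]
    graphics::image(t(z)[, nrow(z):1], col = gray.colors(64), axes = FALSE,
                    main = eye, asp = nrow(z) / ncol(z), ...)
  }
  invisible(x)
}

#' Export a stereogram pair as PNG images with a JSON sidecar
#'
#' Writes `<prefix>_left.png` and `<prefix>_right.png` (8-bit grayscale,
#' both rasters mapped linearly onto `[0, 1]` with a shared scale) and
#' `<prefix>_params.json` holding the generating parameters and seed.
#'
#' @param pair a `"stereo_pair"`.
#' @param prefix file path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_stereo_pair <- function(pair, prefix) {
  stopifnot(inherits(pair, "stereo_pair"))
  rng <- range(pair$left, pair$right)
  scale01 <- function(z) if (diff(rng) == 0) z * 0 + 0.5 else (z - rng[1]) / diff(rng)
  paths <- paste0(prefix, c("_left.png", "_right.png", "_params.json"))
  png::writePNG(scale01(pair$left), paths[1])
  png::writePNG(scale01(pair$right), paths[2])
  p <- pair$params
  p$noise <- unclass(p$noise)
  jsonlite::write_json(unclass(p), paths[3], auto_unbox = TRUE, null = "null")
  invisible(paths)
}
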