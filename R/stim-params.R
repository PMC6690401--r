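#' Disparity-noise models for stereogram generation
#'
#' Four noise models control how individual dots are displaced or
#' decorrelated between the two eyes:
#'
#' * `noise_none()`: every dot carries exactly the mean disparity.
#' * `noise_gaussian(sd_px)`: each dot receives an independent disparity
#'   offset drawn from a zero-mean Gaussian with standard deviation `sd_px`
#'   pixels, rounded to the nearest integer pixel (rasters admit only
#'   integer shifts).
#' * `noise_two_planes(disp_a_px, disp_b_px)`: each dot is assigned, with
#'   equal probability, one of two disparity offsets, depicting two
#'   transparent planes.
#' * `noise_decorrelate(fraction, scope)`: a fraction of the dots is deleted
#'   and replaced by independently positioned dots in each eye. `scope`
#'   controls where replacement dots may land when overlap is forbidden:
#'   `"own_eye"` (default) rejects a replacement only if it would overwrite
#'   a dot in its own eye; `"both_eyes"` additionally rejects locations
#'   covered by a dot in the other eye, so replacements land only on
#'   double background (the limiting regime of the closed-form theory).
#'
#' @param sd_px Gaussian disparity-noise standard deviation in pixels (>= 0).
#' @param disp_a_px,disp_b_px integer disparity offsets of the two planes.
#' @param fraction fraction of dots decorrelated, in `[0, 1]`.
#' @param scope rejection scope for replacement dots in no-overlap mode.
#' @return a list of class `"noise_model"`.
#' @name noise_models
NULL

#' @rdname noise_models
#' @export
noise_none <- function() {
  structure(list(type = "none"), class = "noise_model")
}

#' @rdname noise_models
#' @export
noise_gaussian <- function(sd_px) {
  stopifnot(is.numeric(sd_px), length(sd_px) == 1, sd_px >= 0)
  structure(list(type = "gaussian", sd_px = sd_px), class = "noise_model")
}

#' @rdname noise_models
#' @export
noise_two_planes <- function(disp_a_px, disp_b_px) {
  stopifnot(disp_a_px == round(disp_a_px), disp_b_px == round(disp_b_px))
  structure(list(type = "two_planes", disp_a_px = as.integer(disp_a_px),
                 disp_b_px = as.integer(disp_b_px)), class = "noise_model")
}

#' @rdname noise_models
#' @export
noise_decorrelate <- function(fraction, scope = c("own_eye", "both_eyes")) {
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction >= 0, fraction <= 1)
  structure(list(type = "decorrelate", fraction = fraction,
                 scope = match.arg(scope)), class = "noise_model")
}

#' Specify a random-dot stereogram ensemble
#'
#' Bundles the full specification of a stereogram: geometry, dot density,
#' polarity, overlap rule, disparity signal, disparity-noise model and seed.
#' Disparity follows the convention *left-eye position minus right-eye
#' position*: a dot with disparity `delta` is drawn at its nominal x plus
#' `ceiling(delta/2)` in the left eye and minus `floor(delta/2)` in the
#' right eye, mirroring the `x0/2` receptive-field split used by the model
#' neurons so that a stimulus of disparity `delta` drives the neuron with
#' position disparity `x0 = delta` maximally.
#'
#' @param width_px,height_px image size in pixels (positive integers).
#' @param dot_size_px side of the square dots, in pixels.
#' @param density probability `d` in `[0, 1)` that a monocular pixel is
#'   covered by a dot. The number of dots is computed with
#'   [required_dot_count()] unless `dot_count` overrides it.
#' @param overlap `"no_overlap"` (dots are rejected and redrawn if they
#'   would overwrite an existing dot in either eye) or `"overlap"` (dots
#'   are scattered freely, occluding one another).
#' @param polarity `"mixed"` (dots are +1 or -1 with equal probability on a
#'   0 background), `"white"` (+1), `"black"` (-1), or `"dark_darker"`
#'   (equal numbers of -1 and -0.5 dots: two contrasts, one polarity).
#' @param mean_disparity_px integer mean disparity applied to every dot.
#' @param noise a [noise model][noise_models]; default `noise_none()`.
#' @param dot_count optional explicit dot count, overriding the density
#'   formula (used e.g. to draw the *same number* of dots in overlap and
#'   no-overlap conditions).
#' @param overlap_check `"shifted"` (default) tests the no-overlap rule on
#'   the drawn, disparity-shifted footprints in both eyes; `"nominal"`
#'   tests it on the pre-shift nominal footprint only.
#' @param max_rejections abort threshold: this many consecutive rejected
#'   placements raises a packing-infeasible error instead of hanging.
#' @param seed integer seed; all randomness in [generate_pair()] derives
#'   from it.
#' @return a list of class `"stim_params"`.
#' @seealso [generate_pair()], [required_dot_count()]
#' @export
stim_params <- function(width_px, height_px = width_px, dot_size_px, density,
                        overlap = c("no_overlap", "overlap"),
                        polarity = c("mixed", "white", "black", "dark_darker"),
                        mean_disparity_px = 0L,
                        noise = noise_none(),
                        dot_count = NULL,
                        overlap_check = c("shifted", "nominal"),
                        max_rejections = 10000L,
                        seed = 1L) {
  overlap <- match.arg(overlap)
  polarity <- match.arg(polarity)
  overlap_check <- match.arg(overlap_check)
  stopifnot(width_px >= 1, height_px >= 1, width_px == round(width_px),
            height_px == round(height_px),
            dot_size_px >= 1, dot_size_px == round(dot_size_px),
            is.numeric(density), length(density) == 1,
            mean_disparity_px == round(mean_disparity_px),
            inherits(noise, "noise_model"),
            max_rejections >= 1)
  if (density < 0 || density >= 1)
    stop("infeasible density: 'density' must lie in [0, 1)")
  if (dot_size_px > min(width_px, height_px))
    stop("geometry error: dot_size_px exceeds the image size")
  if (!is.null(dot_count))
    stopifnot(dot_count >= 0, dot_count == round(dot_count))
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    dot_size_px = as.integer(dot_size_px), density = density,
    overlap = overlap, polarity = polarity,
    mean_disparity_px = as.integer(mean_disparity_px),
    noise = noise, dot_count = if (is.null(dot_count)) NULL else as.integer(dot_count),
    overlap_check = overlap_check,
    max_rejections = as.integer(max_rejections),
    seed = as.integer(seed)
  ), class = "stim_params")
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf("Random-dot stereogram spec: %d x %d px, %d px %s dots, density %.3g (%s)\n",
              x$width_px, x$height_px, x$dot_size_px, x$polarity,
              x$density, gsub("_", "-", x$overlap)))
  nd <- x$noise
  ndesc <- switch(nd$type,
    none = "none",
    gaussian = sprintf("Gaussian, sd %.3g px", nd$sd_px),
    two_planes = sprintf("two planes at %+d and %+d px", nd$disp_a_px, nd$disp_b_px),
    decorrelate = sprintf("%.0f%% of dots decorrelated", 100 * nd$fraction))
  cat(sprintf("  mean disparity %+d px, disparity noise: %s, seed %d\n",
              x$mean_disparity_px, ndesc, x$seed))
  invisible(x)
}

#' Number of dots needed to reach a target coverage
#'
#' Returns the dot count for which each monocular pixel is covered with
#' probability `density`. When overlap is forbidden every dot contributes
#' fresh area, so the count is linear:
#' `N = density * image_area / dot_area`. When dots are scattered freely
#' they occlude each other, and the count solving
#' `1 - (1 - dot_area/image_area)^N = density` is
#' `N = log(1 - density) / log(1 - dot_area/image_area)`.
#'
#' @param density target coverage probability in `[0, 1)`.
#' @param image_area_px total image area in pixels.
#' @param dot_area_px area of one dot in pixels (`dot_size_px^2`).
#' @param overlap `"no_overlap"` or `"overlap"`.
#' @return the formula value rounded to the nearest integer.
#' @examples
#' required_dot_count(0.4, 100 * 100, 4 * 4, "no_overlap") # 250
#' @export
required_dot_count <- function(density, image_area_px, dot_area_px,
                               overlap = c("no_overlap", "overlap")) {
  overlap <- match.arg(overlap)
  stopifnot(is.numeric(density), length(density) == 1,
            image_area_px > 0, dot_area_px > 0)
  if (density < 0 || density >= 1)
    stop("infeasible density: 'density' must lie in [0, 1)")
  if (dot_area_px > image_area_px)
    stop("geometry error: dot area exceeds image area")
  n <- if (overlap == "no_overlap") {
    density * image_area_px / dot_area_px
  } else {
    if (density == 0) 0 else log1p(-density) / log1p(-dot_area_px / image_area_px)
  }
  as.integer(round(n))
}
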