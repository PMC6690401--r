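#' Gabor receptive-field parameters
#'
#' Defaults are the V1 model-cell values used throughout the package's
#' population simulations: envelope SD `sigma = 32` pixels and carrier
#' period `lambda = 128` pixels (at the simulated scale of 2 pixels per
#' arcmin, 16 arcmin and ~1.1 degrees respectively).
#'
#' @param sigma_px Gaussian envelope standard deviation, pixels (> 0).
#' @param lambda_px carrier spatial period, pixels (> 0).
#' @export
gabor_params <- function(sigma_px = 32, lambda_px = 128) {
  stopifnot(is.numeric(sigma_px), sigma_px > 0,
            is.numeric(lambda_px), lambda_px > 0)
  structure(list(sigma_px = sigma_px, lambda_px = lambda_px),
            class = "gabor_params")
}

#' Evaluate a Gabor receptive field on a pixel grid
#'
#' `f_e(x, y) = exp(-(x^2 + y^2) / 2 sigma^2) * cos(2 pi x / lambda)` for
#' the even phase and the sine counterpart for the odd phase, evaluated on
#' an integer pixel grid centered on the image center (pixel
#' `((W+1)/2, (H+1)/2)`), with the horizontal coordinate shifted by
#' `center_shift_px` (which may be half-integer: an odd position disparity
#' splits into exact half-pixel RF shifts). Support is truncated to zero
#' beyond a radius of 4 sigma around the shifted center, where the envelope
#' has fallen below 3.4e-4.
#'
#' @param gabor a [gabor_params()] object.
#' @param width_px,height_px grid size in pixels.
#' @param phase `"even"` or `"odd"`.
#' @param center_shift_px horizontal RF-center shift in pixels.
#' @return a `height_px x width_px` numeric kernel.
#' @export
gabor_rf <- function(gabor, width_px, height_px = width_px,
                     phase = c("even", "odd"), center_shift_px = 0) {
  phase <- match.arg(phase)
  stopifnot(inherits(gabor, "gabor_params"))
  xs <- seq_len(width_px) - (width_px + 1) / 2 - center_shift_px
  ys <- seq_len(height_px) - (height_px + 1) / 2
  env_x <- outer(ys^2, xs^2, `+`)
  kern <- exp(-env_x / (2 * gabor$sigma_px^2)) *
    matrix(if (phase == "even") cos(2 * pi * xs / gabor$lambda_px)
           else sin(2 * pi * xs / gabor$lambda_px),
           nrow = height_px, ncol = width_px, byrow = TRUE)
  kern[env_x > (4 * gabor$sigma_px)^2] <- 0
  kern
}

#' Monocular inner product of a Gabor RF with one eye's image
#'
#' For a binocular neuron with position disparity `x0`, the left-eye
#' receptive field is centered at `+x0/2` relative to the image center and
#' the right-eye field at `-x0/2` (the field is evaluated at
#' `x - x0/2` for the left eye and `x + x0/2` for the right). The response
#' is the exact inner product of the truncated kernel with the raster.
#'
#' @param raster a (normalized) monocular image matrix.
#' @param gabor a [gabor_params()] object.
#' @param phase `"even"` or `"odd"`.
#' @param eye `"left"` or `"right"`.
#' @param x0 position disparity of the neuron, pixels.
#' @return a scalar response.
#' @export
monocular_response <- function(raster, gabor, phase = c("even", "odd"),
                               eye = c("left", "right"), x0 = 0) {
  phase <- match.arg(phase)
  eye <- match.arg(eye)
  shift <- if (eye == "left") x0 / 2 else -x0 / 2
  kern <- gabor_rf(gabor, ncol(raster), nrow(raster), phase, shift)
  if (all(kern == 0))
    stop("kernel support entirely outside the image")
  sum(kern * raster)
}

#' Binocular model-neuron output nonlinearities
#'
#' Combines the four monocular inner products (`v_Le`, `v_Re` even phase;
#' `v_Lo`, `v_Ro` odd phase, all at a common position disparity) into the
#' response of one model V1 cell:
#'
#' * `odf_te`: `(v_Le + v_Re)^2` - classic energy-model tuned-excitatory
#'   subunit (same-phase RFs, peaked tuning);
#' * `odf_ti`: `(v_Le - v_Re)^2` - tuned-inhibitory (opposite-phase RFs,
#'   central trough);
#' * `odf_odd`: `(v_Le + v_Ro)^2` - quarter-cycle phase offset,
#'   odd-symmetric tuning;
#' * `rpc_te`: `(hw(v_Le) + hw(v_Re))^2` - monocular half-wave
#'   rectification before binocular combination;
#' * `rpc_odd`: `hw(hw(v_Lo) - hw(v_Re))^2`;
#' * `complex_odf_te`: `(v_Le + v_Re)^2 + (v_Lo + v_Ro)^2` - phase-invariant
#'   complex cell summing a quadrature pair of `odf_te` subunits,
#'
#' where `hw(x) = max(x, 0)`. All responses are nonnegative; inputs may be
#' vectors (e.g. one value per position disparity).
#'
#' @param v_le,v_re,v_lo,v_ro monocular inner products.
#' @param model one of `"odf_te"`, `"odf_ti"`, `"odf_odd"`, `"rpc_te"`,
#'   `"rpc_odd"`, `"complex_odf_te"`.
#' @return nonnegative response(s).
#' @export
neuron_response <- function(v_le, v_re, v_lo, v_ro,
                            model = c("odf_te", "odf_ti", "odf_odd",
                                      "rpc_te", "rpc_odd", "complex_odf_te")) {
  model <- match.arg(model)
  hw <- function(x) pmax(x, 0)
  switch(model,
    odf_te = (v_le + v_re)^2,
    odf_ti = (v_le - v_re)^2,
    odf_odd = (v_le + v_ro)^2,
    rpc_te = (hw(v_le) + hw(v_re))^2,
    rpc_odd = hw(hw(v_lo) - hw(v_re))^2,
    complex_odf_te = (v_le + v_re)^2 + (v_lo + v_ro)^2)
}

#' @export
neuron_models <- c("odf_te", "odf_ti", "odf_odd", "rpc_te", "rpc_odd",
                   "complex_odf_te")

# Precompute the bank of shifted Gabor kernels for a set of position
# disparities, flattened for a single crossprod() pass per image. Returns
# four (W*H) x n_x0 matrices: left/right eye x even/odd phase.
gabor_bank <- function(width_px, height_px, gabor, x0) {
  mk <- function(phase, eye) {
    vapply(x0, function(d)
      as.vector(gabor_rf(gabor, width_px, height_px, phase,
                         if (eye == "left") d / 2 else -d / 2)),
      numeric(width_px * height_px))
  }
  list(le = mk("even", "left"), re = mk("even", "right"),
       lo = mk("odd", "left"), ro = mk("odd", "right"), x0 = x0)
}

# All four monocular inner-product vectors for one normalized pair.
bank_responses <- function(pair, bank) {
  L <- as.vector(pair$left); R <- as.vector(pair$right)
  list(v_le = drop(crossprod(bank$le, L)), v_re = drop(crossprod(bank$re, R)),
       v_lo = drop(crossprod(bank$lo, L)), v_ro = drop(crossprod(bank$ro, R)))
}

#' Population disparity-tuning curves of model V1 neurons
#'
#' Simulates, for each requested model-cell type, a population of neurons
#' with position disparities `x0`, each responding to `n_trials` freshly
#' generated random-dot stereograms. Each neuron's trial-averaged raw
#' response is divided by its own mean response to `n_trials` binocularly
#' uncorrelated stereograms generated with the same parameters (and the
#' same polarity conversion), so a normalized response of 1 marks the
#' uncorrelated baseline.
#'
#' If `params$polarity` is `"white"` or `"black"`, each trial generates a
#' mixed-polarity pattern and converts it, so mixed- and same-polarity runs
#' with equal seeds share identical dot patterns.
#'
#' @param params a [stim_params()] specification (its `seed` seeds trial 1).
#' @param models character vector of model-cell types (see
#'   [neuron_response()]).
#' @param x0 integer position disparities, pixels.
#' @param n_trials stereograms per neuron.
#' @param seed top-level seed (overrides `params$seed` streams per trial).
#' @param gabor receptive-field parameters.
#' @return a named list of `"tuning_curve"` objects, one per model: fields
#'   `model`, `x0`, `mean_norm` (baseline-normalized mean response), `sd_norm`
#'   (across-trial SD / baseline), `baseline`, `n_trials`.
#' @export
population_tuning <- function(params, models = neuron_models, x0 = -20:20,
                              n_trials = 100, seed = 1,
                              gabor = gabor_params()) {
  stopifnot(inherits(params, "stim_params"))
  models <- match.arg(models, neuron_models, several.ok = TRUE)
  bank <- gabor_bank(params$width_px, params$height_px, gabor, x0)

  run <- function(generator, off) {
    s <- matrix(0, length(models), length(x0))
    s2 <- s
    for (i in seq_len(n_trials)) {
      p <- params
      p$seed <- derive_seed(seed, off + i)
      pair <- trial_pair(p, generator)
      v <- bank_responses(pair, bank)
      for (j in seq_along(models)) {
        r <- neuron_response(v$v_le, v$v_re, v$v_lo, v$v_ro, models[j])
        s[j, ] <- s[j, ] + r
        s2[j, ] <- s2[j, ] + r^2
      }
    }
    list(mean = s / n_trials,
         sd = sqrt(pmax(s2 / n_trials - (s / n_trials)^2, 0)))
  }
  stim <- run(generate_pair, 0L)
  base <- run(generate_uncorrelated_pair, 500000L)

  out <- lapply(seq_along(models), function(j) {
    b <- base$mean[j, ]
    if (any(b <= 0))
      stop("normalization error: uncorrelated baseline response is not positive")
    structure(list(model = models[j], x0 = x0,
                   mean_norm = stim$mean[j, ] / b,
                   sd_norm = stim$sd[j, ] / b,
                   baseline = b, n_trials = n_trials),
              class = "tuning_curve")
  })
  names(out) <- models
  out
}

# generate one trial pair per the requested polarity condition: same-polarity
# conditions are derived from a mixed pattern, as in the stimulus-construction
# procedure the package emulates
trial_pair <- function(p, generator) {
  pol <- p$polarity
  if (pol %in% c("white", "black")) {
    p$polarity <- "mixed"
    pair <- to_same_polarity(generator(p), pol)
  } else {
    pair <- generator(p)
  }
  normalize_pair(pair)
}

#' @export
print.tuning_curve <- function(x, ...) {
  pk <- which.max(x$mean_norm)
  cat(sprintf("Disparity tuning (%s), %d trials/neuron, %d position disparities\n",
              x$model, x$n_trials, length(x$x0)))
  cat(sprintf("  peak normalized response %.3f at x0 = %+d px; amplitude above baseline %.3f\n",
              x$mean_norm[pk], x$x0[pk], max(x$mean_norm) - 1))
  invisible(x)
}

#' @export
as.data.frame.tuning_curve <- function(x, ...) {
  data.frame(model = x$model, x0 = x$x0, mean_norm = x$mean_norm,
             sd_norm = x$sd_norm, baseline = x$baseline,
             n_trials = x$n_trials)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$x0, x$mean_norm, type = "l", lwd = 2,
                 xlab = "position disparity x0 (px)",
                 ylab = "response / uncorrelated baseline",
                 main = x$model, ...)
  graphics::abline(h = 1, col = "gray")
  invisible(x)
}
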