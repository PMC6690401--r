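#' Neuron/anti-neuron front/back discrimination task
#'
#' Simulates a two-alternative forced-choice depth judgment with a single
#' pair of model neurons. On each trial one stereogram with mean disparity
#' `+disparity_px` is generated under `params` (noise model, density,
#' overlap rule and polarity condition included; same-polarity conditions
#' are derived from a mixed pattern exactly as in [population_tuning()]).
#' The simulated observer answers correctly when the response of the
#' neuron with position disparity `+disparity_px` exceeds that of the
#' "anti-neuron" at `-disparity_px`; exact ties are broken by a fair coin.
#'
#' @param params a [stim_params()] specification; its `mean_disparity_px`
#'   is overridden by `disparity_px`.
#' @param model a model-cell type (see [neuron_response()]).
#' @param disparity_px stimulus (and neuron) disparity magnitude, pixels.
#' @param n_trials number of trials (a warning is issued below 100, where
#'   the binomial SE is too large for condition comparisons).
#' @param seed top-level seed.
#' @param gabor receptive-field parameters.
#' @param uncorrelated present binocularly uncorrelated stimuli instead
#'   (no disparity signal; performance should sit at chance).
#' @return a list of class `"task_result"`: `condition` (polarity),
#'   `model`, `n_trials`, `pc` (proportion correct), `n_correct`, `seed`.
#' @export
run_task <- function(params, model = "odf_te", disparity_px = 6,
                     n_trials = 1000, seed = 1, gabor = gabor_params(),
                     uncorrelated = FALSE) {
  stopifnot(inherits(params, "stim_params"), n_trials >= 1)
  model <- match.arg(model, neuron_models)
  if (n_trials < 100)
    warning("n_trials < 100: percent-correct SE too large for comparisons")
  params$mean_disparity_px <- as.integer(disparity_px)
  bank <- gabor_bank(params$width_px, params$height_px, gabor,
                     c(disparity_px, -disparity_px))
  n_correct <- 0L
  for (i in seq_len(n_trials)) {
    p <- params
    p$seed <- derive_seed(seed, i)
    pair <- trial_pair(p, if (uncorrelated) generate_uncorrelated_pair
                          else generate_pair)
    v <- bank_responses(pair, bank)
    r <- neuron_response(v$v_le, v$v_re, v$v_lo, v$v_ro, model)
    if (r[1] > r[2] || (r[1] == r[2] && coin_flip(seed, i))) {
      n_correct <- n_correct + 1L
    }
  }
  structure(list(condition = params$polarity, model = model,
                 n_trials = as.integer(n_trials), pc = n_correct / n_trials,
                 n_correct = n_correct, seed = as.integer(seed)),
            class = "task_result")
}

coin_flip <- function(seed, i) {
  set.seed(derive_seed(seed, 900000L + i))
  runif(1) < 0.5
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("Front/back task (%s, %s polarity): %.1f%% correct over %d trials (binomial SE %.1f%%)\n",
              x$model, x$condition, 100 * x$pc, x$n_trials,
              100 * sqrt(x$pc * (1 - x$pc) / x$n_trials)))
  invisible(x)
}

#' Statistical efficiency ratio between two percent-correct values
#'
#' The squared ratio of observer sensitivities, with sensitivity taken as
#' the probit (inverse normal CDF) of the proportion correct:
#' `(qnorm(pc_a) / qnorm(pc_b))^2`. In a dot-averaging ideal-observer
#' account this is the ratio of the numbers of dots the two conditions'
#' observers would need to reach the observed performance. Defined only
#' for above-chance, below-ceiling performance.
#'
#' @param pc_a,pc_b proportions correct, both strictly in `(0.5, 1)`.
#'   `"task_result"` objects are also accepted.
#' @return the efficiency of condition a relative to condition b;
#'   `efficiency_ratio(a, b) * efficiency_ratio(b, a) = 1`.
#' @examples
#' efficiency_ratio(0.83, 0.70) # ~3.3
#' @export
efficiency_ratio <- function(pc_a, pc_b) {
  if (inherits(pc_a, "task_result")) pc_a <- pc_a$pc
  if (inherits(pc_b, "task_result")) pc_b <- pc_b$pc
  stopifnot(is.numeric(pc_a), is.numeric(pc_b))
  if (any(c(pc_a, pc_b) <= 0.5) || any(c(pc_a, pc_b) >= 1))
    stop("domain error: efficiency ratio requires 0.5 < pc < 1")
  (qnorm(pc_a) / qnorm(pc_b))^2
}
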