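#' Interocular correlation versus disparity noise
#'
#' For each combination of dot density and overlap rule, sweeps Gaussian
#' disparity-noise SD (expressed as a fraction of the dot size) and records
#' the mean and across-pattern SD of the interocular Pearson correlation
#' for mixed- and same-polarity stereograms. Mixed-polarity patterns are
#' generated first and converted, so identical dot patterns underlie all
#' polarity conditions of a given pattern index; dark/darker patterns are
#' drawn with the same derived seed and therefore also share dot positions.
#' The same number of dots (the no-overlap count) is drawn in both overlap
#' conditions by default.
#'
#' @param densities dot coverage levels to test.
#' @param overlap_modes subset of `c("no_overlap", "overlap")`.
#' @param noise_fracs Gaussian noise SD as a fraction of the dot size.
#' @param polarities subset of `c("mixed", "white", "black")`.
#' @param include_dark_darker also run the two-contrast same-polarity
#'   condition (black and dark-gray dots).
#' @param width_px,height_px,dot_size_px stimulus geometry.
#' @param n_patterns patterns per condition.
#' @param match_dot_count draw the no-overlap dot count in both modes.
#' @param seed top-level seed.
#' @return a data frame: `density`, `overlap`, `noise_frac`, `noise_sd_px`,
#'   `polarity`, `mean_r`, `sd_r`, `n_patterns`.
#' @export
run_correlation_sweep <- function(densities = c(0.1, 0.4),
                                  overlap_modes = c("no_overlap", "overlap"),
                                  noise_fracs = seq(0, 2, by = 0.25),
                                  polarities = c("mixed", "white", "black"),
                                  include_dark_darker = FALSE,
                                  width_px = 200, height_px = 200,
                                  dot_size_px = 4,
                                  n_patterns = 100,
                                  match_dot_count = TRUE,
                                  seed = 1) {
  overlap_modes <- match.arg(overlap_modes, several.ok = TRUE)
  polarities <- match.arg(polarities, several.ok = TRUE)
  rows <- list()
  for (dd in densities) for (ov in overlap_modes) for (fr in noise_fracs) {
    sd_px <- fr * dot_size_px
    nd <- if (sd_px > 0) noise_gaussian(sd_px) else noise_none()
    count <- if (match_dot_count)
      required_dot_count(dd, width_px * height_px, dot_size_px^2, "no_overlap")
    else NULL
    base <- stim_params(width_px, height_px, dot_size_px, dd, overlap = ov,
                        noise = nd, dot_count = count)
    conds <- polarities
    if (include_dark_darker) conds <- c(conds, "dark_darker")
    rvals <- matrix(NA_real_, n_patterns, length(conds),
                    dimnames = list(NULL, conds))
    for (i in seq_len(n_patterns)) {
      p <- base
      p$seed <- derive_seed(seed, i)
      raw <- generate_pair(p)
      for (cond in conds) {
        pair <- switch(cond,
          mixed = raw,
          white = to_same_polarity(raw, "white"),
          black = to_same_polarity(raw, "black"),
          dark_darker = {
            pdd <- p; pdd$polarity <- "dark_darker"
            generate_pair(pdd)
          })
        pair <- normalize_pair(pair)
        rvals[i, cond] <- pearson_r(pair$left, pair$right)
      }
    }
    for (cond in conds) {
      rows[[length(rows) + 1L]] <- data.frame(
        density = dd, overlap = ov, noise_frac = fr, noise_sd_px = sd_px,
        polarity = cond, mean_r = mean(rvals[, cond]),
        sd_r = sd(rvals[, cond]), n_patterns = n_patterns,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cross-correlation profiles under different disparity-noise types
#'
#' Computes ensemble cross-correlation functions (correlation versus
#' horizontal displacement) for three noise conditions - none (uniform
#' disparity), two transparent planes, and Gaussian per-dot noise - under
#' both overlap rules and both polarity conditions.
#'
#' @param overlap_modes subset of `c("no_overlap", "overlap")`.
#' @param noise_types subset of `c("none", "two_planes", "gaussian")`.
#' @param width_px,height_px,dot_size_px,density stimulus geometry; the
#'   same (no-overlap) dot count is drawn in both overlap modes.
#' @param disparity_px uniform disparity of the none/gaussian conditions.
#' @param plane_disps_px the two disparities of the transparent planes.
#' @param gaussian_sd_px Gaussian noise SD, pixels.
#' @param displacements displacements at which to evaluate the profile.
#' @param n_patterns ensemble size per condition.
#' @param seed top-level seed.
#' @return a data frame: `noise_type`, `overlap`, `polarity`,
#'   `displacement_px`, `mean_r`, `sd_r`, `n_patterns`.
#' @export
run_profile_experiment <- function(overlap_modes = c("no_overlap", "overlap"),
                                   noise_types = c("none", "two_planes", "gaussian"),
                                   width_px = 100, height_px = 100,
                                   dot_size_px = 4, density = 0.4,
                                   disparity_px = 2,
                                   plane_disps_px = c(0, 4),
                                   gaussian_sd_px = 2,
                                   displacements = -8:12,
                                   n_patterns = 100, seed = 1) {
  overlap_modes <- match.arg(overlap_modes, several.ok = TRUE)
  noise_types <- match.arg(noise_types, several.ok = TRUE)
  count <- required_dot_count(density, width_px * height_px, dot_size_px^2,
                              "no_overlap")
  rows <- list()
  for (ov in overlap_modes) for (nt in noise_types) {
    nd <- switch(nt,
      none = noise_none(),
      two_planes = noise_two_planes(plane_disps_px[1], plane_disps_px[2]),
      gaussian = noise_gaussian(gaussian_sd_px))
    md <- if (nt == "two_planes") 0L else as.integer(disparity_px)
    base <- stim_params(width_px, height_px, dot_size_px, density,
                        overlap = ov, mean_disparity_px = md, noise = nd,
                        dot_count = count)
    raws <- lapply(seq_len(n_patterns), function(i) {
      p <- base
      p$seed <- derive_seed(seed, i)
      generate_pair(p)
    })
    for (pol in c("mixed", "white")) {
      ens <- lapply(raws, function(raw) {
        pair <- if (pol == "mixed") raw else to_same_polarity(raw, "white")
        normalize_pair(pair)
      })
      prof <- cross_correlation_profile(ens, displacements)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(noise_type = nt, overlap = ov, polarity = pol,
                   stringsAsFactors = FALSE),
        as.data.frame(prof))
    }
  }
  do.call(rbind, rows)
}

#' Population tuning curves across noise and overlap conditions
#'
#' Reproduces the package's headline population simulation: disparity
#' tuning of model V1 cells to mixed- and same-polarity random-dot
#' stereograms (241 x 241 px, 6 px dots, density 0.28 when overlap is
#' forbidden and the same dot count when it is allowed, mean disparity
#' 6 px) in three stimulus regimes: no noise / no overlap, Gaussian noise /
#' no overlap, and Gaussian noise / overlap.
#'
#' @param conditions subset of `c("no_noise_no_overlap", "noise_no_overlap",
#'   "noise_overlap")`.
#' @param models model-cell types to simulate.
#' @param x0 neuron position disparities.
#' @param n_trials stereograms per neuron and condition.
#' @param noise_sd_px Gaussian disparity-noise SD in the noisy regimes.
#' @param width_px,height_px,dot_size_px,density,disparity_px stimulus
#'   geometry.
#' @param gabor receptive-field parameters.
#' @param seed top-level seed.
#' @return a data frame: `condition`, `polarity`, `model`, `x0`,
#'   `mean_norm`, `sd_norm`, `baseline`, `n_trials`.
#' @export
run_tuning_experiment <- function(conditions = c("no_noise_no_overlap",
                                                 "noise_no_overlap",
                                                 "noise_overlap"),
                                  models = neuron_models,
                                  x0 = -20:20, n_trials = 10000,
                                  noise_sd_px = 12,
                                  width_px = 241, height_px = 241,
                                  dot_size_px = 6, density = 0.28,
                                  disparity_px = 6,
                                  gabor = gabor_params(), seed = 1) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  count <- required_dot_count(density, width_px * height_px, dot_size_px^2,
                              "no_overlap")
  rows <- list()
  for (cond in conditions) {
    ov <- if (cond == "noise_overlap") "overlap" else "no_overlap"
    nd <- if (cond == "no_noise_no_overlap") noise_none()
          else noise_gaussian(noise_sd_px)
    for (pol in c("mixed", "white")) {
      params <- stim_params(width_px, height_px, dot_size_px, density,
                            overlap = ov, polarity = pol,
                            mean_disparity_px = disparity_px, noise = nd,
                            dot_count = count)
      curves <- population_tuning(params, models = models, x0 = x0,
                                  n_trials = n_trials,
                                  seed = derive_seed(seed, match(cond, conditions)),
                                  gabor = gabor)
      for (cv in curves) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(condition = cond, polarity = pol,
                     stringsAsFactors = FALSE),
          as.data.frame(cv))
      }
    }
  }
  do.call(rbind, rows)
}

#' Headline front/back task: percent correct and efficiency by polarity
#'
#' Runs the neuron/anti-neuron front/back discrimination for the simple
#' tuned-excitatory energy-model cell (`odf_te`) and the quadrature-pair
#' complex cell (`complex_odf_te`), in the mixed- and same-polarity
#' conditions, with every condition scored on the *same* generated dot
#' patterns: each trial draws one noisy mixed-polarity stereogram at
#' `+disparity_px`, scores both models on it, converts it to same polarity,
#' renormalizes, and scores both models again. Defaults are the
#' no-overlap, density 0.28, 241 x 241 px, 6 px dot, 6 px disparity
#' stimulus with sigma 32 px / lambda 128 px Gabor receptive fields and
#' 4 px disparity-noise SD (the 2 arcmin noise of the emulated
#' psychophysics at 2 px/arcmin; see the methods vignette for the choice
#' and for the 12 px sensitivity run).
#'
#' @param n_trials trials per condition.
#' @param noise_sd_px Gaussian disparity-noise SD, pixels.
#' @param models model-cell types to score.
#' @param width_px,height_px,dot_size_px,density,overlap,disparity_px
#'   stimulus geometry.
#' @param gabor receptive-field parameters.
#' @param seed top-level seed.
#' @return a list of class `"task_experiment"`: `results` (data frame of
#'   model x condition percent correct) and `efficiency` (data frame of
#'   mixed-vs-same efficiency ratios per model, with 95% bootstrap CIs
#'   over trials).
#' @export
run_task_experiment <- function(n_trials = 10000, noise_sd_px = 4,
                                models = c("odf_te", "complex_odf_te"),
                                width_px = 241, height_px = 241,
                                dot_size_px = 6, density = 0.28,
                                overlap = "no_overlap", disparity_px = 6,
                                gabor = gabor_params(), seed = 1) {
  models <- match.arg(models, neuron_models, several.ok = TRUE)
  params <- stim_params(width_px, height_px, dot_size_px, density,
                        overlap = overlap,
                        mean_disparity_px = disparity_px,
                        noise = noise_gaussian(noise_sd_px))
  bank <- gabor_bank(width_px, height_px, gabor,
                     c(disparity_px, -disparity_px))
  conds <- c("mixed", "same")
  correct <- matrix(0L, length(models), length(conds),
                    dimnames = list(models, conds))
  for (i in seq_len(n_trials)) {
    p <- params
    p$seed <- derive_seed(seed, i)
    raw <- generate_pair(p)
    for (ci in seq_along(conds)) {
      pair <- if (conds[ci] == "mixed") raw else to_same_polarity(raw, "white")
      v <- bank_responses(normalize_pair(pair), bank)
      for (mi in seq_along(models)) {
        r <- neuron_response(v$v_le, v$v_re, v$v_lo, v$v_ro, models[mi])
        if (r[1] > r[2] || (r[1] == r[2] && coin_flip(seed, i)))
          correct[mi, ci] <- correct[mi, ci] + 1L
      }
    }
  }
  pc <- correct / n_trials
  results <- data.frame(
    model = rep(models, times = length(conds)),
    condition = rep(conds, each = length(models)),
    n_trials = n_trials,
    pc = as.vector(pc),
    stringsAsFactors = FALSE)
  set.seed(derive_seed(seed, 999999L))
  ci <- t(vapply(models, function(m)
    efficiency_boot_ci(correct[m, "mixed"], correct[m, "same"], n_trials),
    numeric(2)))
  eff <- data.frame(
    model = models,
    pc_mixed = pc[, "mixed"], pc_same = pc[, "same"],
    efficiency_ratio = vapply(models, function(m)
      efficiency_ratio(pc[m, "mixed"], pc[m, "same"]), numeric(1)),
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, efficiency = eff,
                 noise_sd_px = noise_sd_px, n_trials = n_trials,
                 seed = seed),
            class = "task_experiment")
}

# 95% parametric-bootstrap CI for the probit efficiency ratio, resampling
# the per-condition correct counts; draws with either proportion at or
# below chance are dropped (the ratio is undefined there)
efficiency_boot_ci <- function(k_mixed, k_same, n, n_boot = 2000) {
  pm <- rbinom(n_boot, n, k_mixed / n) / n
  ps <- rbinom(n_boot, n, k_same / n) / n
  ok <- pm > 0.5 & ps > 0.5 & pm < 1 & ps < 1
  if (sum(ok) < n_boot / 2) return(c(NA_real_, NA_real_))
  r <- (qnorm(pm[ok]) / qnorm(ps[ok]))^2
  stats::quantile(r, c(0.025, 0.975), names = FALSE)
}

#' @export
print.task_experiment <- function(x, ...) {
  cat(sprintf("Front/back task, %d trials/condition, disparity noise SD %g px\n",
              x$n_trials, x$noise_sd_px))
  for (i in seq_len(nrow(x$efficiency))) {
    e <- x$efficiency[i, ]
    cat(sprintf("  %-15s mixed %.1f%%  same %.1f%%  efficiency ratio %.2f (95%% CI %.2f-%.2f)\n",
                e$model, 100 * e$pc_mixed, 100 * e$pc_same,
                e$efficiency_ratio, e$ci_lo, e$ci_hi))
  }
  invisible(x)
}

#' Write an experiment's tables to a directory
#'
#' Writes `results.csv` (the data frame), `params.json` (the resolved
#' parameter list) and `summary.json` (any summary list) into `dir`.
#'
#' @param results a data frame of results.
#' @param dir output directory (created if needed).
#' @param params named list of resolved parameters.
#' @param summary named list of summary quantities.
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(results, dir, params = list(), summary = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("results.csv", "params.json", "summary.json"))
  write.csv(results, paths[1], row.names = FALSE)
  jsonlite::write_json(params, paths[2], auto_unbox = TRUE, null = "null")
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
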