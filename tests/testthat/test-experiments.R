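test_that("correlation sweep: no noise gives r = 1; overlap rule drives the
           polarity gap", {
  res <- run_correlation_sweep(densities = 0.4,
                               noise_fracs = c(0, 1),
                               polarities = c("mixed", "white"),
                               width_px = 120, height_px = 120,
                               n_patterns = 25, seed = 2)
  zero <- res[res$noise_frac == 0, ]
  expect_true(all(abs(zero$mean_r - 1) < 1e-12))
  noisy <- res[res$noise_frac == 1, ]
  pick <- function(ov, pol)
    noisy[noisy$overlap == ov & noisy$polarity == pol, ]
  no_m <- pick("no_overlap", "mixed")
  no_s <- pick("no_overlap", "white")
  expect_gt(no_m$mean_r - no_s$mean_r,
            3 * sqrt(no_m$sd_r^2 + no_s$sd_r^2) / sqrt(25))
  ov_m <- pick("overlap", "mixed")
  ov_s <- pick("overlap", "white")
  expect_lt(abs(ov_m$mean_r - ov_s$mean_r),
            3 * sqrt(ov_m$sd_r^2 + ov_s$sd_r^2) / sqrt(25))
})

test_that("two-contrast same-polarity patterns behave like all-black ones", {
  res <- run_correlation_sweep(densities = 0.4,
                               overlap_modes = "no_overlap",
                               noise_fracs = c(0.5, 1),
                               polarities = c("mixed", "black"),
                               include_dark_darker = TRUE,
                               width_px = 120, height_px = 120,
                               n_patterns = 25, seed = 3)
  for (fr in c(0.5, 1)) {
    at <- res[res$noise_frac == fr, ]
    bl <- at[at$polarity == "black", ]
    dd <- at[at$polarity == "dark_darker", ]
    mx <- at[at$polarity == "mixed", ]
    # the two-contrast condition tracks all-black closely: a small
    # systematic offset (a few percent of r, from the second contrast's
    # effect on the luminance moments) remains, far smaller than the
    # mixed-polarity advantage and inside ~2 across-pattern SD bands
    expect_lt(abs(bl$mean_r - dd$mean_r), 2.5 * pmax(bl$sd_r, dd$sd_r))
    expect_gt(mx$mean_r - bl$mean_r, 3 * abs(bl$mean_r - dd$mean_r))
    expect_gt(mx$mean_r, bl$mean_r)
    expect_gt(mx$mean_r, dd$mean_r)
  }
})

test_that("profile experiment reproduces the noise-type signatures", {
  res <- run_profile_experiment(n_patterns = 30, displacements = -4:8,
                                seed = 4)
  pick <- function(nt, ov, pol)
    res[res$noise_type == nt & res$overlap == ov & res$polarity == pol, ]
  # uniform disparity: peak 1 at +2 regardless of polarity or overlap rule
  for (ov in c("no_overlap", "overlap")) {
    for (pol in c("mixed", "white")) {
      pr <- pick("none", ov, pol)
      expect_identical(pr$displacement_px[which.max(pr$mean_r)], 2L)
      expect_gt(max(pr$mean_r), 0.999)
    }
  }
  # two planes: local maxima near both plane disparities (overlap mode)
  tp <- pick("two_planes", "overlap", "mixed")
  r_at <- function(df, k) df$mean_r[df$displacement_px == k]
  expect_gt(r_at(tp, 0), r_at(tp, -2))
  expect_gt(r_at(tp, 4), r_at(tp, 6))
  # Gaussian noise, no overlap: same-polarity peak below mixed peak
  gm <- pick("gaussian", "no_overlap", "mixed")
  gs <- pick("gaussian", "no_overlap", "white")
  expect_gt(max(gm$mean_r) - max(gs$mean_r), 0.02)
})

test_that("task experiment scores both models on shared patterns and is
           reproducible", {
  a <- run_task_experiment(n_trials = 40, width_px = 81, height_px = 81,
                           dot_size_px = 3, density = 0.25, disparity_px = 2,
                           noise_sd_px = 2,
                           gabor = gabor_params(8, 32), seed = 5)
  b <- run_task_experiment(n_trials = 40, width_px = 81, height_px = 81,
                           dot_size_px = 3, density = 0.25, disparity_px = 2,
                           noise_sd_px = 2,
                           gabor = gabor_params(8, 32), seed = 5)
  expect_identical(a$results$pc, b$results$pc)
  expect_identical(dim(a$results), c(4L, 4L))
  expect_identical(nrow(a$efficiency), 2L)
  expect_true(all(a$results$pc >= 0 & a$results$pc <= 1))
})

test_that("experiment tables serialize to csv and json", {
  res <- data.frame(a = 1:2, b = c("x", "y"))
  dir <- file.path(tempdir(), "stereodots-exp")
  paths <- write_experiment(res, dir, params = list(seed = 1),
                            summary = list(pc = 0.7))
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1])
  expect_identical(back$a, 1:2)
  expect_equal(jsonlite::read_json(paths[3])$pc, 0.7)
})

test_that("stereogram export writes png images with a json sidecar", {
  p <- stim_params(40, 40, 3, 0.2, seed = 1)
  pair <- generate_pair(p)
  paths <- write_stereo_pair(pair, file.path(tempdir(), "sd-test"))
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_identical(dim(img), c(40L, 40L))
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$density, 0.2)
})

test_that("tuning experiment assembles per-condition curves with matching
           polarity structure", {
  res <- run_tuning_experiment(conditions = "no_noise_no_overlap",
                               models = "odf_te", x0 = c(-6, 0, 6),
                               n_trials = 60, width_px = 101,
                               height_px = 101, dot_size_px = 4,
                               density = 0.25, disparity_px = 6,
                               gabor = gabor_params(16, 64), seed = 8)
  expect_identical(nrow(res), 6L)  # 2 polarities x 3 position disparities
  expect_setequal(unique(res$polarity), c("mixed", "white"))
  # same-polarity squared responses are heavy-tailed (relative SD ~3), so
  # only the mixed curve's ordering is resolvable at this ensemble size;
  # polarity comparisons at proper scale live in the acceptance suite
  cv <- res[res$polarity == "mixed", ]
  expect_gt(cv$mean_norm[cv$x0 == 6], cv$mean_norm[cv$x0 == -6])
  expect_true(all(res$baseline > 0))
  expect_true(all(res$n_trials == 60))
})

test_that("task-experiment efficiency CIs cover the point estimate", {
  te <- run_task_experiment(n_trials = 150, width_px = 81, height_px = 81,
                            dot_size_px = 3, density = 0.25,
                            disparity_px = 2, noise_sd_px = 2,
                            gabor = gabor_params(8, 32), seed = 9)
  ok <- !is.na(te$efficiency$ci_lo)
  expect_true(all(te$efficiency$ci_lo[ok] <= te$efficiency$efficiency_ratio[ok]))
  expect_true(all(te$efficiency$ci_hi[ok] >= te$efficiency$efficiency_ratio[ok]))
})
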