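test_that("zero density yields empty rasters and no dots", {
  p <- stim_params(32, 32, 4, 0)
  pr <- generate_pair(p)
  expect_true(all(pr$left == 0) && all(pr$right == 0))
  expect_identical(nrow(pr$dots), 0L)
})

test_that("empirical coverage matches the requested density", {
  p <- stim_params(200, 200, 4, 0.1, overlap = "no_overlap")
  cov <- vapply(1:50, function(i) {
    q <- p
    q$seed <- derive_seed(11, i)
    pr <- generate_pair(q)
    (mean(pr$left_ids != 0L) + mean(pr$right_ids != 0L)) / 2
  }, numeric(1))
  expect_lt(abs(mean(cov) - 0.1), 0.005)
})

test_that("no-overlap placement never overwrites an existing dot", {
  # with disparity noise the constraint is enforced per eye after the shift;
  # every id's pixel count must equal its clipped footprint area
  p <- stim_params(120, 100, 4, 0.3, overlap = "no_overlap",
                   mean_disparity_px = 3, noise = noise_gaussian(4), seed = 8)
  pr <- generate_pair(p)
  k <- p$dot_size_px
  for (eye in c("left", "right")) {
    ids <- pr[[paste0(eye, "_ids")]]
    counts <- tabulate(ids[ids != 0L], nbins = nrow(pr$dots))
    for (id in seq_len(nrow(pr$dots))) {
      dot <- pr$dots[id, ]
      delta <- p$mean_disparity_px + dot$noise_disp_px
      x <- dot$x + ceiling(delta / 2) * (eye == "left") -
        floor(delta / 2) * (eye == "right")
      # clipped footprint area; a strongly shifted dot may leave one eye
      # entirely, in which case it covers zero pixels there
      wx <- max(0, min(ncol(ids), x + k - 1) - max(1, x) + 1)
      wy <- max(0, min(nrow(ids), dot$y + k - 1) - max(1, dot$y) + 1)
      expect_identical(counts[id], as.integer(wx * wy))
    }
  }
})

test_that("infeasible packing fails loudly instead of hanging", {
  p <- stim_params(50, 50, 4, 0.8, overlap = "no_overlap",
                   max_rejections = 2000, seed = 1)
  expect_error(generate_pair(p), "packing infeasible")
})

test_that("polarity conversion takes absolute values and preserves provenance", {
  p <- stim_params(60, 60, 3, 0.25, seed = 4)
  raw <- generate_pair(p)
  w <- to_same_polarity(raw, "white")
  b <- to_same_polarity(raw, "black")
  expect_identical(sort(unique(as.vector(w$left))), c(0, 1))
  expect_identical(sort(unique(as.vector(b$left))), c(-1, 0))
  expect_identical(w$left_ids, raw$left_ids)
  expect_identical(b$right_ids, raw$right_ids)
  expect_equal(w$left, abs(raw$left))
  expect_equal(b$left, -abs(raw$left))
  expect_error(to_same_polarity(normalize_pair(raw), "white"), "sequencing")
  expect_error(to_same_polarity(w, "black"), "mixed")
})

test_that("white and black conversions give identical interocular correlation", {
  # the global sign flip cancels in the correlation coefficient
  p <- stim_params(80, 80, 4, 0.3, noise = noise_gaussian(3))
  for (i in 1:20) {
    q <- p
    q$seed <- derive_seed(21, i)
    raw <- generate_pair(q)
    w <- normalize_pair(to_same_polarity(raw, "white"))
    b <- normalize_pair(to_same_polarity(raw, "black"))
    expect_equal(pearson_r(w$left, w$right), pearson_r(b$left, b$right),
                 tolerance = 1e-12)
  }
})

test_that("normalization achieves zero mean and unit variance and is idempotent", {
  p <- stim_params(90, 70, 4, 0.35, seed = 2)
  nm <- normalize_pair(generate_pair(p))
  for (eye in c("left", "right")) {
    expect_lt(abs(mean(nm[[eye]])), 1e-9)
    expect_lt(abs(mean(nm[[eye]]^2) - 1), 1e-9)
  }
  again <- normalize_pair(nm)
  expect_equal(again$left, nm$left, tolerance = 1e-12)
  # positive-affine inputs normalize to the same image
  for (i in 1:10) {
    q <- p
    q$seed <- derive_seed(31, i)
    raw <- generate_pair(q)
    shifted <- raw
    shifted$left <- 2.5 * raw$left + 7
    shifted$right <- 0.3 * raw$right - 1
    expect_equal(normalize_pair(shifted)$left, normalize_pair(raw)$left,
                 tolerance = 1e-9)
    expect_equal(normalize_pair(shifted)$right, normalize_pair(raw)$right,
                 tolerance = 1e-9)
  }
  const <- generate_pair(stim_params(32, 32, 4, 0))
  expect_error(normalize_pair(const), "degenerate")
})

test_that("degenerate noise models are bitwise-identical to their limits", {
  base <- stim_params(100, 100, 4, 0.3, mean_disparity_px = 2, seed = 5)
  g0 <- base
  g0$noise <- noise_gaussian(0)
  expect_identical(generate_pair(g0)$left, generate_pair(base)$left)
  expect_identical(generate_pair(g0)$right_ids, generate_pair(base)$right_ids)
  tp <- stim_params(100, 100, 4, 0.3, mean_disparity_px = 0,
                    noise = noise_two_planes(2, 2), seed = 5)
  expect_identical(generate_pair(tp)$left, generate_pair(base)$left)
  expect_identical(generate_pair(tp)$right, generate_pair(base)$right)
})

test_that("generation is reproducible from the seed", {
  p <- stim_params(64, 64, 4, 0.2, noise = noise_gaussian(2), seed = 9)
  a <- generate_pair(p)
  b <- generate_pair(p)
  expect_identical(a$left, b$left)
  expect_identical(a$dots, b$dots)
  p2 <- p
  p2$seed <- 10L
  expect_false(identical(generate_pair(p2)$left, a$left))
})

test_that("mixed and dark/darker patterns share dot positions at equal seeds", {
  pm <- stim_params(80, 80, 4, 0.3, seed = 12)
  pd <- pm
  pd$polarity <- "dark_darker"
  m <- generate_pair(pm)
  d <- generate_pair(pd)
  expect_identical(m$left_ids, d$left_ids)
  expect_true(all(d$dots$lum %in% c(-1, -0.5)))
})

test_that("uncorrelated pairs have zero mean correlation and normal coverage", {
  p <- stim_params(200, 200, 4, 0.1)
  rs <- cov <- numeric(60)
  for (i in 1:60) {
    q <- p
    q$seed <- derive_seed(41, i)
    u <- generate_uncorrelated_pair(q)
    cov[i] <- mean(u$left_ids != 0L)
    rs[i] <- pearson_r(normalize_pair(u)$left, normalize_pair(u)$right)
  }
  expect_true(all(vapply(1:3, function(i) {
    q <- p
    q$seed <- derive_seed(41, i)
    generate_uncorrelated_pair(q)$uncorrelated
  }, logical(1))))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(60))
  expect_lt(abs(mean(cov) - 0.1), 0.005)
  # polarity conversion applies to uncorrelated pairs too
  q <- p
  q$seed <- 77L
  w <- to_same_polarity(generate_uncorrelated_pair(q), "white")
  expect_true(all(w$left >= 0))
})
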