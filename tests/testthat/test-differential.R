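test_that("assign_bins cuts by rank with the trailing-bin merge rule", {
  cfg <- differential_config(bin_target = 5, bin_min = 3)
  b <- assign_bins(1:10, cfg)
  expect_equal(as.integer(table(b)), c(5L, 5L))
  expect_true(all(b[1:5] == 1) && all(b[6:10] == 2))

  # remainder below the minimum is merged into the last full bin
  cfg <- differential_config(bin_target = 150, bin_min = 50)
  b <- assign_bins(seq_len(160), cfg)
  expect_equal(length(unique(b)), 1)

  # fewer proteins than one bin -> single bin
  b <- assign_bins(seq_len(40), cfg)
  expect_equal(length(unique(b)), 1)

  # remainder at or above the minimum becomes its own bin
  cfg <- differential_config(bin_target = 100, bin_min = 50)
  b <- assign_bins(seq_len(160), cfg)
  expect_equal(as.integer(table(b)), c(100L, 60L))

  # bins are contiguous in intensity order and deterministic under ties
  set.seed(1)
  x <- sample(rep(1:20, each = 10))
  ids <- sprintf("P%03d", seq_along(x))
  cfg <- differential_config(bin_target = 50, bin_min = 20)
  b1 <- assign_bins(x, cfg, ids)
  perm <- sample(seq_along(x))
  b2 <- assign_bins(x[perm], cfg, ids[perm])
  expect_equal(b2, b1[perm])
})

test_that("trimmed_bin_stats matches direct arithmetic", {
  cfg <- differential_config(consistency_correction = FALSE)
  s <- trimmed_bin_stats(c(0, 0, 0, 0, 1), cfg)
  expect_equal(s$n_trimmed, 5)  # floor(0.025 * 5) = 0 trimmed
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd_raw, sqrt(0.2), tolerance = 1e-12)
  expect_equal(s$sd, s$sd_raw)

  # trimming removes floor(f n) per side; recompute by hand
  cfg <- differential_config(trim_fraction = 0.1,
                             consistency_correction = FALSE)
  x <- c(-50, 1, 2, 3, 4, 5, 6, 7, 8, 100)  # n = 10, k = 1 per side
  s <- trimmed_bin_stats(x, cfg)
  kept <- 1:8
  expect_equal(s$n_trimmed, 8)
  expect_equal(s$mean, mean(kept))
  expect_equal(s$sd_raw, sd(kept))

  # all-equal ratios: zero spread, flagged for the degenerate fallback
  s <- trimmed_bin_stats(rep(0.7, 20), differential_config())
  expect_equal(s$mean, 0.7)
  expect_equal(s$sd_raw, 0)
})

test_that("the consistency correction calibrates the trimmed SD", {
  expect_equal(trim_consistency_factor(0), 1)
  set.seed(7)
  x <- rnorm(10000)
  s <- trimmed_bin_stats(x, differential_config())
  expect_lt(abs(s$sd - 1), 0.03)
  # uncorrected trimmed SD is biased low by the known factor
  s_raw <- trimmed_bin_stats(x, differential_config(
    consistency_correction = FALSE))
  expect_lt(abs(s_raw$sd / trim_consistency_factor(0.025) - 1), 0.03)
})

test_that("single-bin z matches the normal-CDF oracle", {
  cfg <- differential_config(consistency_correction = FALSE,
                             normalize_depth = FALSE)
  res <- binned_z_test(rep(1, 5), c(0, 0, 0, 0, 1), cfg)
  z <- res$records$z[5]
  expect_equal(z, 0.8 / sqrt(0.2), tolerance = 1e-12)
  expect_equal(res$records$p_value[5], 2 * (1 - pnorm(z)),
               tolerance = 1e-12)
  # a protein at the bin mean has z = 0 and p = 1
  res0 <- binned_z_test(rep(1, 5), c(0.2, 0, 0, 0.4, 0.4), cfg)
  expect_equal(res0$records$z[1], 0)
  expect_equal(res0$records$p_value[1], 1)
})

test_that("z-scores equal an independent per-bin recomputation", {
  set.seed(11)
  n <- 500
  intensity <- runif(n, 0, 10)
  ratio <- rnorm(n, 0, 0.5)
  cfg <- differential_config(bin_target = 80, bin_min = 40)
  res <- binned_z_test(intensity, ratio, cfg)
  cf <- trim_consistency_factor(cfg$trim_fraction)
  for (b in unique(res$records$bin)) {
    r <- ratio[res$records$bin == b]
    k <- floor(cfg$trim_fraction * length(r))
    kept <- sort(r)[(k + 1):(length(r) - k)]
    z_oracle <- (r - mean(kept)) / (sd(kept) / cf)
    expect_equal(res$records$z[res$records$bin == b], z_oracle,
                 tolerance = 1e-12)
  }
})

test_that("z is shift-equivariant within a bin", {
  set.seed(3)
  ratio <- rnorm(100)
  a <- binned_z_test(rep(1, 100), ratio)
  b <- binned_z_test(rep(1, 100), ratio + 5)
  expect_equal(a$records$z, b$records$z, tolerance = 1e-10)
})

test_that("degenerate bins fall back to the pooled SD, then to p = 1", {
  # one constant bin among normal bins borrows the pooled scale
  set.seed(5)
  intensity <- c(rep(0, 60), rep(10, 60))
  ratio <- c(rep(0.5, 60), rnorm(60, 0, 1))
  cfg <- differential_config(bin_target = 60, bin_min = 30)
  res <- binned_z_test(intensity, ratio, cfg)
  expect_true(any(res$bins$degenerate))
  expect_true(all(is.finite(res$records$p_value)))
  expect_true(all(res$records$p_value[1:60] == 1))  # z = 0 in flat bin

  # everything constant: warning and p = 1 throughout
  expect_warning(
    res2 <- binned_z_test(rep(1, 10), rep(0.3, 10), cfg),
    "degenerate")
  expect_true(all(res2$records$p_value == 1))
})

test_that("differential_test flags by the dual threshold and direction", {
  set.seed(9)
  n <- 300
  d <- rpois(n, 60) + 1L
  p <- rpois(n, 60) + 1L
  rec <- tibble::tibble(protein_id = sprintf("P%03d", 1:n),
                        differentiating = d, proliferating = p)
  res <- differential_test(rec)
  r <- res$records
  expect_equal(r$differential,
               r$p_value < 0.1 & abs(r$log2_ratio) > 0.5)
  expect_true(all(r$direction[r$log2_ratio > 0] == "up-in-differentiation"))
  expect_true(all(r$direction[r$log2_ratio < 0] == "up-in-maintenance"))
  # the fold-change filter only removes calls relative to the p filter
  expect_true(all(which(r$differential) %in% which(r$p_value < 0.1)))
  # depth normalization equalizes totals
  expect_equal(sum(r$norm_differentiating), sum(r$norm_proliferating),
               tolerance = 1e-9)
})

test_that("differential_test is invariant to protein order", {
  set.seed(13)
  n <- 200
  rec <- tibble::tibble(protein_id = sprintf("P%03d", 1:n),
                        differentiating = rpois(n, 40) + 1L,
                        proliferating = rpois(n, 40) + 1L)
  res1 <- differential_test(rec)$records
  perm <- sample(n)
  res2 <- differential_test(rec[perm, ])$records
  res2 <- res2[match(res1$protein_id, res2$protein_id), ]
  expect_equal(res2$z, res1$z)
  expect_equal(res2$differential, res1$differential)
})

test_that("differential_test rejects non-positive counts, passes empty", {
  expect_error(differential_test(tibble::tibble(
    protein_id = "A", differentiating = 0L, proliferating = 3L)),
    "positive")
  res <- differential_test(tibble::tibble(
    protein_id = character(0), differentiating = integer(0),
    proliferating = integer(0)))
  expect_equal(nrow(res$records), 0)
})

test_that("binning restores calibration under heteroscedastic noise", {
  set.seed(21)
  n <- 4000
  intensity <- runif(n, 1, 9)
  ratio <- rnorm(n, 0, 0.1 + 1.5 / sqrt(2^intensity))
  binned <- binned_z_test(intensity, ratio, differential_config())
  single <- binned_z_test(intensity, ratio, differential_config(
    bin_target = n, bin_min = n))
  fpr_binned <- mean(binned$records$p_value < 0.1)
  fpr_single <- mean(single$records$p_value < 0.1)
  expect_lt(abs(fpr_binned - 0.1), 0.02)
  # one global scale miscalibrates the intensity extremes
  low <- intensity < 3
  expect_gt(mean(single$records$p_value[low] < 0.1), 0.15)
  expect_gt(abs(fpr_single - 0.1) + 0.01, abs(fpr_binned - 0.1))
})
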