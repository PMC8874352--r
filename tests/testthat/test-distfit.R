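test_that("binning follows half-open 20-ms bins and normalizes to 1", {
  d <- bin_and_smooth(c(10))
  expect_identical(nrow(d), 175L)
  expect_equal(d$freq_raw[1], 1)
  expect_equal(sum(d$freq_raw), 1)
  # exact edges go to the right-hand bin of each boundary
  d2 <- bin_and_smooth(c(20, 40))
  expect_equal(d2$count[2:3], c(1L, 1L))
  expect_error(bin_and_smooth(c(-1)), "outside")
  expect_error(bin_and_smooth(c(3500)), "outside")
  d0 <- bin_and_smooth(numeric(0))
  expect_true(attr(d0, "empty"))
  expect_true(all(d0$freq_raw == 0))
})

test_that("large uniform samples flatten toward 1/175 after smoothing", {
  set.seed(7)
  d <- bin_and_smooth(runif(10000, 0, 3500))
  expect_equal(mean(d$freq_smooth), 1 / 175, tolerance = 0.02)
  expect_lt(max(abs(d$freq_smooth - 1 / 175)), 0.35 / 175)
})

test_that("the moving median matches a hand-rolled shrinking-window oracle", {
  set.seed(8)
  x <- rpois(30, 3) / 10
  sm <- blinkhazard:::smooth_curve(x, 5, "median")
  oracle <- numeric(30)
  for (i in 1:30) {
    w <- x[max(1, i - 2):min(30, i + 2)]
    oracle[i] <- median(w)
  }
  expect_equal(sm, oracle)
  sm_mean <- blinkhazard:::smooth_curve(x, 5, "mean")
  for (i in 1:30) oracle[i] <- mean(x[max(1, i - 2):min(30, i + 2)])
  expect_equal(sm_mean, oracle)
})

test_that("group median is the pointwise median with the even-count convention", {
  m <- rbind(c(1, 5, 2), c(3, 1, 2), c(2, 3, 9))
  med <- group_median_distribution(m)
  expect_equal(med$freq, c(2, 3, 2))
  m4 <- rbind(m, c(10, 10, 10))
  med4 <- group_median_distribution(m4)
  expect_equal(med4$freq, c(2.5, 4, 5.5))
})

test_that("noiseless five-Gaussian curves are recovered from the midpoint start", {
  amp <- c(0.05, 0.03, 0.04, 0.02, 0.06)
  curve <- gauss_curve(amp)
  fit <- fit_five_gaussians(curve)
  expect_lt(mean(abs(sort(fit$components$mean) - c(375, 1125, 1875, 2625, 3375))), 5)
  expect_equal(sort(fit$components$amplitude), sort(amp), tolerance = 0.01)
  # all-zero curve: zero amplitudes, zero residual
  z <- gauss_curve(rep(0, 5))
  fz <- fit_five_gaussians(z)
  expect_equal(fz$mean_residual, 0)
  expect_true(all(fz$components$amplitude == 0))
})

test_that("a single-bump curve loads one dominant component", {
  curve <- gauss_curve(c(0, 0, 0.08, 0, 0), sigma = 30)
  fit <- fit_five_gaussians(curve, max_restarts = 8)
  amps <- abs(fit$components$amplitude)
  expect_gt(max(amps), 0.06)
  expect_lt(sort(amps, decreasing = TRUE)[2], 0.25 * max(amps))
})

test_that("chi-square distance matches hand evaluation and its metric properties", {
  expect_equal(chi2_distance(c(2, 0), c(0, 2)), 2)
  expect_equal(chi2_distance(c(1, 0), c(0, 0)), 0.5)
  expect_equal(chi2_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(chi2_distance(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(chi2_distance(c(-1, 2), c(1, 2)), "non-negative")
  set.seed(9)
  for (i in 1:200) {
    x <- rgamma(20, 1); y <- rgamma(20, 1)
    expect_equal(chi2_distance(x, y), chi2_distance(y, x))
    expect_gte(chi2_distance(x, y), 0)
    expect_identical(chi2_distance(x, y) == 0, identical(x, y))
  }
})

test_that("the distance permutation test behaves at its logical extremes", {
  set.seed(10)
  a <- matrix(runif(6 * 20), 6)
  dup <- bootstrap_distance_test(a, a, n_boot = 199, seed = 1)
  expect_equal(dup$distance, 0)
  expect_equal(dup$p, 1)
  # disjoint concentrations: observed distance at the top of the null
  g1 <- cbind(matrix(rexp(6 * 10, 10), 6), matrix(0, 6, 10)) + 1e-4
  g2 <- cbind(matrix(0, 6, 10), matrix(rexp(6 * 10, 10), 6)) + 1e-4
  dd <- bootstrap_distance_test(g1, g2, n_boot = 199, seed = 2)
  expect_lt(dd$p, 0.05)
  expect_error(bootstrap_distance_test(a[1, , drop = FALSE], a), "2 participants")
})

test_that("per-interval peak tests flag only the interval built to differ", {
  set.seed(11)
  mk_group <- function(n, s3_scale) {
    purrr::map(1:n, function(i) {
      lat <- c(runif(60, 0, 3500),
               rnorm(round(40 * s3_scale), 1875, 60))
      bin_and_smooth(lat[lat >= 0 & lat < 3500])
    })
  }
  ga <- mk_group(12, 1)
  gb <- mk_group(12, 0.15)
  fit_a <- fit_five_gaussians(group_median_distribution(ga), max_restarts = 4)
  res <- per_interval_peak_tests(ga, gb, fit_a)
  expect_identical(nrow(res), 5L)
  s3 <- res$interval == 3
  expect_lt(res$p_fdr[s3], 0.05)
  expect_true(all(res$p_fdr[!s3] > 0.05))
  # the FDR column is Benjamini-Hochberg of the raw column (independent check)
  ord <- order(res$p)
  bh <- numeric(5)
  prev <- 1
  for (k in 5:1) {
    prev <- min(prev, res$p[ord[k]] * 5 / k)
    bh[ord[k]] <- prev
  }
  expect_equal(res$p_fdr, bh)
  # identical groups show nothing
  res0 <- per_interval_peak_tests(ga, ga, fit_a)
  expect_true(all(res0$p_fdr > 0.9))
})
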