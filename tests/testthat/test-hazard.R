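test_that("peri-stimulus binning is aligned to the potential target onsets", {
  # blinks only in [450, 750) of each sequence: all mass in position-2 pre bins
  lat <- runif(200, 450, 749.9)
  ps <- build_peristim(lat, n_total = 200)
  expect_identical(nrow(ps), 90L)  # 3 positions x 30 bins
  expect_equal(sum(ps$freq[ps$position == 2 & ps$rel_lo_ms < 0]), 1)
  expect_equal(sum(ps$freq[ps$position != 2]), 0)
  expect_equal(range(ps$rel_lo_ms), c(-300, 280))
  expect_equal(sum(ps$rel_lo_ms < 0) / 3, 15)  # 15 pre bins per position
})

test_that("robust slopes are exact on lines, zero on constants, and sign-coherent", {
  expect_equal(as.numeric(robust_slope(c(3, 2, 1))), -1)
  expect_equal(as.numeric(robust_slope(c(7, 7, 7))), 0)
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(1); b <- rnorm(1)
    y <- a + b * (-1:1)
    # zero residuals: robust fit must equal the closed-form OLS slope
    ols <- sum((-1:1) * (y - mean(y))) / 2
    expect_equal(as.numeric(robust_slope(y)), ols, tolerance = 1e-10)
    yr <- rnorm(3)
    expect_equal(as.numeric(robust_slope(-yr)), -as.numeric(robust_slope(yr)),
                 tolerance = 1e-10)
  }
})

test_that("slope profiles flip sign with the frequencies", {
  set.seed(4)
  lat <- runif(300, 0, 3500)
  ps <- build_peristim(lat, n_total = 300)
  prof <- slope_profile(ps)
  ps_neg <- dplyr::mutate(ps, freq = -.data$freq)
  prof_neg <- slope_profile(ps_neg)
  expect_equal(prof_neg$slope, -prof$slope, tolerance = 1e-10)
})

test_that("zero slopes yield no clusters; permutation count warnings fire", {
  s <- matrix(0, 10, 30)
  ct <- cluster_permutation_test(s, n_perm = 200, seed = 1)
  expect_identical(nrow(ct$clusters), 0L)
  expect_warning(cluster_permutation_test(matrix(rnorm(60), 6), n_perm = 50,
                                          seed = 1),
                 "100 permutations")
})

test_that("exhaustive sign-flip p-values match brute-force enumeration at n = 6", {
  set.seed(5)
  s <- matrix(rnorm(6 * 12, -0.3, 1), 6, 12)
  ct <- cluster_permutation_test(s, n_perm = 100, seed = 1)
  expect_true(ct$exhaustive)
  skip_if(nrow(ct$clusters) == 0)

  # independent oracle: enumerate all 64 sign patterns, per-bin t via t.test,
  # clusters by a simple scan
  tcrit <- qt(0.05, df = 5)
  t_of <- function(m) apply(m, 2, function(col) unname(t.test(col)$statistic))
  clusters_of <- function(tv) {
    masses <- c(); cur <- 0; inside <- FALSE
    for (j in seq_along(tv)) {
      if (tv[j] < tcrit) { cur <- cur + tv[j]; inside <- TRUE }
      else if (inside) { masses <- c(masses, cur); cur <- 0; inside <- FALSE }
    }
    if (inside) masses <- c(masses, cur)
    masses
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  null_min <- apply(signs, 1, function(sg) {
    m <- clusters_of(t_of(s * sg))
    if (length(m)) min(m) else 0
  })
  obs_masses <- clusters_of(t_of(s))
  p_oracle <- vapply(obs_masses, function(m) {
    mean(null_min <= m + 1e-9 * (1 + abs(m)))
  }, numeric(1))
  expect_equal(ct$clusters$mass, obs_masses, tolerance = 1e-10)
  expect_equal(ct$clusters$p, p_oracle, tolerance = 1e-12)
})

test_that("synthetic suppression produces a pre-stimulus negative cluster", {
  p <- generate_protocol(240, 60, 750, seed = 6)
  eps <- purrr::map(1:15, function(i) {
    tm <- timing_model(kappa = 0.6, beta = -1, seed = test_seed(21, i))
    extract_epochs(sample_blink_times(tm, p)$time_ms, p)
  })
  cs <- cohort_slopes(eps)
  expect_lt(mean(cs$slopes[, 1:15]), 0)  # mean pre-stimulus slope negative
  ct <- cluster_permutation_test(cs$slopes, n_perm = 500, seed = 7,
                                 rel_lo_ms = cs$rel_lo_ms)
  sig <- dplyr::filter(ct$clusters, .data$p <= 0.05)
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$start_ms < 0))
})

test_that("slope magnitude tracks the injected suppression strength", {
  p <- generate_protocol(240, 60, 750, seed = 8)
  mean_pre_slope <- function(beta) {
    mean(vapply(1:8, function(i) {
      tm <- timing_model(beta = beta, seed = test_seed(beta * 10, i))
      ps <- build_peristim(extract_epochs(sample_blink_times(tm, p)$time_ms, p))
      prof <- slope_profile(ps)
      mean(prof$slope[prof$rel_lo_ms < 0])
    }, numeric(1)))
  }
  s0 <- mean_pre_slope(0); s5 <- mean_pre_slope(-0.5); s10 <- mean_pre_slope(-1)
  expect_lt(s10, s5)
  expect_lt(s5, s0)
  expect_lt(abs(s0), 5e-4)  # centered near zero without suppression
})
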