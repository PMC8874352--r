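fake_records <- function(pd_shift = 0, seed = 1, n = 10) {
  set.seed(seed)
  hc <- round(rnorm(n, 160, 25))
  pd <- round(rnorm(n, 160 + pd_shift, 25))
  tibble::tibble(
    id = c(sprintf("hc%02d", 1:n), sprintf("pd%02d", 1:n)),
    group = rep(c("hc", "pd"), each = n),
    pair = rep(1:n, 2),
    age = rep(round(runif(n, 55, 75)), 2),
    blink_count = c(hc, pd),
    median_ibi_ms = c(rnorm(n, 1100, 150), rnorm(n, 1400, 150)))
}

test_that("an extreme blink count removes the participant and its matched partner", {
  rec <- fake_records()
  rec$blink_count[rec$id == "pd03"] <- 556
  out <- outlier_exclusion(rec)
  expect_true(out$excluded[out$id == "pd03"])
  expect_true(out$excluded[out$id == "hc03"])
  expect_identical(sum(out$excluded), 2L)
  expect_match(out$exclusion_reason[out$id == "hc03"], "partner")
  # without outliers (or with all-equal counts) nothing is excluded
  expect_identical(sum(outlier_exclusion(fake_records())$excluded), 0L)
  eq <- dplyr::mutate(fake_records(), blink_count = 150)
  expect_identical(sum(outlier_exclusion(eq)$excluded), 0L)
  expect_error(outlier_exclusion(dplyr::select(rec, -"pair")), "pair")
})

test_that("cohort tests detect a built-in blink deficit and not its absence", {
  rep_null <- cohort_tests(fake_records(0, seed = 2))
  expect_gt(rep_null$rank_tests$p[rep_null$rank_tests$what == "blink_count"],
            0.05)
  rep_def <- cohort_tests(fake_records(-60, seed = 3))
  expect_lt(rep_def$rank_tests$p[rep_def$rank_tests$what == "blink_count"],
            0.05)
  expect_s3_class(rep_def$pair_regression, "tbl_df")
  expect_identical(rep_def$age_correlation$n, 10L)
  # self-comparison: regression slope near 1
  rec <- fake_records(0, seed = 4)
  rec$blink_count[rec$group == "pd"] <- rec$blink_count[rec$group == "hc"]
  rep_same <- cohort_tests(rec)
  expect_equal(rep_same$pair_regression$slope, 1, tolerance = 1e-6)
})

test_that("age uncorrelated by construction stays uncorrelated on average", {
  set.seed(5)
  rhos <- vapply(1:30, function(i) {
    cohort_tests(fake_records(0, seed = 100 + i))$age_correlation$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("the pipeline runs end to end and is byte-reproducible from its seed", {
  cfg <- pipeline_config(out_dir = withr::local_tempdir(), seed = 42,
                         n_per_group = 4, n_sequences = 60,
                         n_target_sequences = 15, n_boot = 100, n_perm = 200)
  res <- suppressWarnings(run_pipeline(cfg))
  files <- c("events.tsv", "blinks.tsv", "histograms.tsv",
             "gaussian_fits.tsv", "report.json", "manifest.json")
  expect_true(all(file.exists(file.path(cfg$out_dir, files))))
  expect_s3_class(res$distance_test, "dist_test")
  expect_identical(nrow(res$records), 8L)

  cfg2 <- cfg
  cfg2$out_dir <- withr::local_tempdir()
  suppressWarnings(run_pipeline(cfg2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(cfg$out_dir, f))),
                     unname(tools::md5sum(file.path(cfg2$out_dir, f))),
                     label = f)
  }
})

test_that("tidiers and autoplot methods produce the documented shapes", {
  fit <- fit_five_gaussians(gauss_curve(c(0.05, 0.03, 0.04, 0.02, 0.06)),
                            max_restarts = 2)
  td <- tidy(fit)
  expect_identical(nrow(td), 5L)
  expect_named(glance(fit), c("iterations", "mean_residual", "converged"))
  expect_s3_class(autoplot(fit), "ggplot")

  set.seed(6)
  s <- matrix(rnorm(8 * 30, -0.01, 0.01), 8, 30)
  ct <- cluster_permutation_test(s, n_perm = 300, seed = 1)
  expect_s3_class(tidy(ct), "tbl_df")
  expect_identical(glance(ct)$n_clusters, nrow(ct$clusters))
  expect_s3_class(autoplot(ct), "ggplot")

  a <- matrix(runif(4 * 20), 4); b <- matrix(runif(4 * 20), 4)
  dt <- bootstrap_distance_test(a, b, n_boot = 99, seed = 1)
  expect_named(glance(dt), c("distance", "p", "n_boot"))

  rep <- cohort_tests(fake_records())
  td_rep <- tidy(rep)
  expect_true(all(c("rank_sum", "robust_regression", "spearman",
                    "kolmogorov_smirnov") %in% td_rep$test))

  sp <- suppressWarnings(fft_power(numeric(8192)))
  expect_s3_class(autoplot(sp), "ggplot")
  d <- bin_and_smooth(runif(100, 0, 3500))
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(plot_hazard(hazard(c(1, 1, 1) / 3)), "ggplot")
})
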