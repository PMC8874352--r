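test_that("preprocessing rejects drift below the passband and standardizes", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  drift <- sin(2 * pi * 0.5 * t) * 10
  z <- preprocess_trace(drift + rnorm(length(t), 0, 0.1), fs)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  # a pure sub-band drift carries almost no in-band power, so after
  # standardization the trace is dominated by the noise, not the drift
  zd <- signal::filtfilt(signal::butter(2, c(1, 20) / 250, "pass"), drift)
  expect_lt(sd(zd), 0.15 * sd(drift))
  expect_error(preprocess_trace(rnorm(100), fs), "3 filter lengths")
})

test_that("candidate intervals obey the length and separation rules", {
  fs <- 500
  expect_identical(nrow(find_candidates(numeric(5000), fs)), 0L)
  # two 60-ms pulses 40 ms apart are merged; an isolated 20-ms pulse is dropped
  z <- numeric(5000)
  z[1000:1030] <- 10   # 60 ms
  z[1051:1081] <- 10   # 40 ms later, 60 ms
  z[3000:3009] <- 10   # 20 ms, too short
  z <- (z - mean(z)) / sd(z)
  iv <- find_candidates(z, fs)
  expect_identical(nrow(iv), 1L)
  expect_lte(iv$start[1], 1000L)
  expect_gte(iv$end[1], 1081L)
})

test_that("landmark fitting is exact on a triangle and grades a half-sine lower", {
  z <- c(numeric(100), seq(0, 5, length.out = 50), seq(5, 0, length.out = 50),
         numeric(100))
  tri <- fit_landmarks(z, 105, 195, fs = 500)
  expect_equal(tri$r2_up, 1)
  expect_equal(tri$r2_down, 1)
  expect_identical(tri$max_value, 5)
  zs <- c(numeric(100), 5 * sin(seq(0, pi, length.out = 100)), numeric(100))
  half <- fit_landmarks(zs, 105, 195, fs = 500)
  expect_lt(half$r2_up, 1)
  expect_lt(half$r2_up, tri$r2_up)
  # trace that never returns to zero: candidate rejected with a reason
  zr <- c(numeric(100), seq(0, 5, length.out = 50), rep(5, 1000))
  out <- fit_landmarks(zr, 105, 1100, fs = 500)
  expect_null(out)
})

test_that("BAR arithmetic matches the definition at the acceptance boundaries", {
  z <- rep(0.25, 2000)
  z[800] <- 0; z[900] <- 0
  z[801:899] <- 5 * 101 / 99  # in-blink mean over [800, 900] is exactly 5
  cand <- fake_candidate(800L, 900L, max_value = 5 * 101 / 99)
  kept <- compute_bar(cand, z)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$bar, 20)           # boundary value retained
  kept25 <- compute_bar(cand, ifelse(z == 0.25, 0.2, z))
  expect_identical(nrow(kept25), 0L)   # BAR 25 excluded
  kept2 <- compute_bar(cand, ifelse(z == 0.25, 2.5, z))
  expect_identical(nrow(kept2), 0L)    # BAR 2 excluded
  # no positive surround: BAR infinite, excluded
  zneg <- z; zneg[z == 0.25] <- -0.25
  expect_identical(nrow(compute_bar(cand, zneg)), 0L)
})

test_that("tiers follow the stroke R-squared thresholds", {
  cands <- dplyr::bind_rows(
    fake_candidate(100L, 200L, 5, r2 = c(0.96, 0.97)),
    fake_candidate(400L, 500L, 5, r2 = c(0.91, 0.94)),
    fake_candidate(700L, 800L, 5, r2 = c(0.99, 0.985)),
    fake_candidate(1000L, 1100L, 5, r2 = c(0.80, 0.99)))
  used <- apply_quality_filters(dplyr::mutate(cands, bar = 10), fs = 500)
  expect_identical(used$tier, c("better", "good", "best"))
})

test_that("amplitude outliers are removed relative to the best-blink median", {
  base <- purrr::map(1:8, function(i) {
    fake_candidate(i * 1000L, i * 1000L + 100L, 5 + 0.01 * i)
  })
  outl <- fake_candidate(9000L, 9100L, 50, r2 = c(0.92, 0.92))
  cands <- dplyr::mutate(dplyr::bind_rows(c(base, list(outl))), bar = 10)
  used <- apply_quality_filters(cands, fs = 500)
  expect_identical(nrow(used), 8L)
  expect_true(all(used$max_value < 10))
})

test_that("saccadic steps fail the amplitude-by-velocity criterion", {
  fs <- 500
  tpl <- blink_template(blink_shape(), fs)
  z_b <- c(numeric(500), tpl * 6, numeric(500))
  fl_b <- fit_landmarks(z_b, 505, 504 + length(tpl), fs)
  pavr_blink <- blinkhazard:::pavr_value(fl_b$max_value, fl_b$max_up_velocity, fs)
  expect_gt(pavr_blink, 3)
  # a step displacement band-passed to 1-20 Hz: sharp rise, high velocity
  raw <- c(numeric(2000), rep(6, 2000))
  z_s <- preprocess_trace(raw, fs)
  iv <- find_candidates(z_s, fs)
  fl_s <- fit_landmarks(z_s, iv$start[1], iv$end[1], fs)
  pavr_sacc <- blinkhazard:::pavr_value(fl_s$max_value, fl_s$max_up_velocity, fs)
  expect_lt(pavr_sacc, 3)
})

test_that("channel selection prefers the channel with most good blinks", {
  p <- small_protocol(24, 6, seed = 5)
  b <- sample_blink_times(timing_model(seed = 6), p)
  rec <- render_recording(b, duration_s = 90, seed = 7)
  cat_full <- suppressWarnings(select_best_signal(rec, participant = "x"))
  expect_identical(attr(cat_full, "channel"), "upperV")
  cat_fz <- suppressWarnings(select_best_signal(rec, channels = "Fz"))
  expect_identical(attr(cat_fz, "channel"), "Fz")
  expect_lte(nrow(cat_fz), nrow(cat_full))
})

test_that("sparse catalogs are flagged unstable", {
  ct <- catalog_from_times(seq(0, 14) * 4000)
  expect_true(attr(ct, "unstable"))
  ct2 <- catalog_from_times(seq(0, 24) * 4000)
  expect_false(attr(ct2, "unstable"))
})

test_that("the detector recovers ground truth with ordered, physiological intervals", {
  p <- suppressWarnings(generate_protocol(64, 16, 750, seed = 8))
  b <- sample_blink_times(timing_model(seed = 9), p)
  rec <- render_recording(b, duration_s = 240, seed = 10)
  used <- suppressWarnings(detect_blinks(rec$signal$upperV))
  err <- vapply(b$time_ms, function(t) min(abs(used$max_ms - t)), numeric(1))
  # at this reduced recording length the amplitude filter's tail trim weighs
  # more per blink; the full-scale recovery bound is asserted on the 15-min
  # recording in the acceptance suite
  expect_gte(mean(err <= 20), 0.90)
  fp <- sum(vapply(used$max_ms,
                   function(t) min(abs(b$time_ms - t)) > 20, logical(1)))
  expect_lte(fp, 0.05 * nrow(b))
  expect_true(all(diff(used$max_ms) > 0))
  expect_gt(median(diff(used$max_ms)), 3000)
  expect_lt(median(diff(used$max_ms)), 5000)
})
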