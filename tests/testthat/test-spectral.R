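test_that("epoching keeps only target-free sequences and in-window blinks", {
  p <- generate_protocol(240, 60, 750, seed = 1)
  # one blink inside the first target-free sequence, one 3.6 s after its onset
  seqs <- protocol_sequences(p)
  free <- seqs$onset_ms[!seqs$has_target]
  ep <- extract_epochs(c(free[1] + 100, free[1] + 3600), p)
  expect_identical(nrow(ep$epochs), 180L)
  expect_identical(ep$n_blinks, 1L)
  expect_equal(ep$latencies$latency_ms, 100)
  # blinks during target sequences never enter the epoch set
  tgt <- seqs$onset_ms[seqs$has_target]
  ep2 <- extract_epochs(tgt + 100, p)
  expect_identical(ep2$n_blinks, 0L)
  # zero blinks is a valid epoch set
  ep3 <- extract_epochs(numeric(0), p)
  expect_identical(nrow(ep3$latencies), 0L)
})

test_that("concatenation conserves impulse count and sample placement", {
  p <- generate_protocol(240, 60, 750, seed = 1)
  b <- sample_blink_times(timing_model(seed = 2), p)
  ep <- extract_epochs(b$time_ms, p)
  v_ab <- concatenate_epochs(ep, pad_to_ms = NULL)   # plain abutted windows
  expect_identical(length(v_ab), 180L * 1750L)
  expect_identical(sum(v_ab), as.numeric(ep$n_blinks))
  v_pad <- concatenate_epochs(ep)                    # phase-preserving default
  expect_identical(length(v_pad), 180L * 1875L)
  expect_identical(sum(v_pad), as.numeric(ep$n_blinks))
  # single blink at 750 ms lands on sample 375 (0-based) of its epoch
  seqs <- protocol_sequences(p)
  free1 <- seqs$onset_ms[!seqs$has_target][1]
  v1 <- concatenate_epochs(extract_epochs(free1 + 750, p), pad_to_ms = NULL)
  expect_identical(which(v1 == 1), 376L)
  expect_error(concatenate_epochs(ep, pad_to_ms = 3000), "at least")
})

test_that("spectra have the fs/N grid, non-negative power, and detect the tone comb", {
  v <- numeric(3 * 8192)
  v[seq(1, length(v), by = 375)] <- 1
  sp <- fft_power(v)
  expect_equal(diff(sp$freq_hz[1:2]), 500 / 8192)
  expect_true(all(sp$power >= 0))
  expect_identical(attr(sp, "n_windows"), 3L)
  expect_equal(dominant_frequency(sp), 22 * 500 / 8192)
  expect_equal(round(dominant_frequency(sp), 2), 1.34)
  expect_warning(sp0 <- fft_power(numeric(0)), "empty")
  expect_true(all(sp0$power == 0))
  expect_warning(fft_power(rep(1, 100)), "zero-padding")
})

test_that("temporal jitter weakens the stimulus-rate peak", {
  set.seed(11)
  n <- 4 * 8192
  clean <- numeric(n); clean[seq(1, n, by = 375)] <- 1
  jit_pos <- seq(1, n, by = 375) + round(runif(length(seq(1, n, by = 375)), -50, 50))
  jit_pos <- jit_pos[jit_pos >= 1 & jit_pos <= n]
  jit <- numeric(n); jit[jit_pos] <- 1
  p_clean <- spectrum_peak(fft_power(clean), 1.34)$peak
  p_jit <- spectrum_peak(fft_power(jit), 1.34)$peak
  expect_lt(p_jit, p_clean)
})

test_that("probe bins resolve to the nearest grid frequency with a local reference", {
  sp <- suppressWarnings(fft_power(numeric(8192)))
  sp$power <- rep(1, nrow(sp))
  sp$power[23] <- 100  # bin 22 (0-based), 1.3428 Hz
  pk <- spectrum_peak(sp, 1.34)
  expect_equal(pk$bin_hz, 22 * 500 / 8192)
  expect_equal(pk$peak, 100)
  expect_equal(pk$reference, 1)  # neighborhood median excludes the peak
})

test_that("entrainment statistics separate groups built to differ", {
  base <- suppressWarnings(fft_power(numeric(8192)))
  mk <- function(peak_power, seed) {
    set.seed(seed)
    s <- base
    s$power <- stats::rexp(nrow(s), 1e4)
    k <- which.min(abs(s$freq_hz - 1.34))
    s$power[k] <- peak_power
    s
  }
  strong <- purrr::map(1:8, function(i) mk(5e-3, i))
  flat <- purrr::map(1:8, function(i) mk(1e-4, 100 + i))
  st <- entrainment_stats(strong, flat, freqs = 1.34)
  expect_lt(st$p[st$test == "A vs reference"], 0.01)
  expect_lt(st$p[st$test == "A vs B"], 0.01)
  expect_gt(st$r[st$test == "A vs B"], 0)
  # identical groups: no between-group evidence, effect size near zero
  st0 <- entrainment_stats(strong, strong, freqs = 1.34)
  expect_gt(st0$p[st0$test == "A vs B"], 0.4)
  expect_equal(st0$r[st0$test == "A vs B"], 0, tolerance = 0.05)
  expect_error(entrainment_stats(strong[1], flat), "2 participants")
})

test_that("stimulus-rate power grows with entrainment strength in expectation", {
  p <- generate_protocol(60, 15, seed = 3)
  mean_peak <- function(kappa) {
    mean(vapply(1:10, function(s) {
      tm <- timing_model(base_interval_s = c(0.8, 1.6), kappa = kappa,
                         seed = test_seed(kappa * 100, s))
      b <- sample_blink_times(tm, p)
      sp <- fft_power(concatenate_epochs(extract_epochs(b$time_ms, p)))
      spectrum_peak(sp, 1.34)$peak
    }, numeric(1)))
  }
  pow <- c(mean_peak(0), mean_peak(0.5), mean_peak(1))
  expect_true(pow[2] > pow[1] && pow[3] > pow[2])
})
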