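# Shared fixtures, built in code at test time.

# A small feasible protocol; warnings about positional balance are expected
# when n_targets is not divisible by 3.
small_protocol <- function(n_seq = 24, n_tgt = 6, seed = 1) {
  generate_protocol(n_seq, n_tgt, 750, seed = seed)
}

# Sum-of-Gaussians curve on the 175-bin grid.
gauss_curve <- function(amp, mu = c(375, 1125, 1875, 2625, 3375), sigma = 20,
                        n_bins = 175, bin_ms = 20) {
  t_mid <- (seq_len(n_bins) - 0.5) * bin_ms
  freq <- rowSums(vapply(seq_along(mu), function(j) {
    amp[j] * exp(-(t_mid - mu[j])^2 / (2 * sigma[j %% length(sigma) + 1]^2))
  }, numeric(n_bins)))
  tibble::tibble(bin = seq_len(n_bins), t_mid = t_mid, freq = freq)
}

# Hand-made landmark candidate row for filter-logic tests.
fake_candidate <- function(left_zero, right_zero, max_value, r2 = c(0.99, 0.99),
                           max_up_velocity = max_value / 45) {
  tibble::tibble(left_zero = left_zero,
                 max_frame = (left_zero + right_zero) %/% 2,
                 right_zero = right_zero, max_value = max_value,
                 r2_up = r2[1], r2_down = r2[2],
                 max_up_velocity = max_up_velocity)
}

# Derive deterministic per-participant seeds in tests.
test_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483587)
}
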