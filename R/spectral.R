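#' Extract non-target sequence epochs and assign blink peaks
#'
#' One epoch per target-free five-tone sequence, spanning `[onset, onset +
#' window_ms)` from the sequence onset; blink peaks fall into the epoch whose
#' half-open window contains them. Blinks in target sequences, or later than
#' `window_ms` after a sequence onset, are excluded from the epoch set.
#'
#' @param catalog A `blink_catalog` (peak times in `max_ms`, global time
#'   base shared with the protocol) or a numeric vector of peak times (ms).
#' @param protocol A [generate_protocol()] result.
#' @param window_ms Epoch length in ms (default 3500; must not exceed the
#'   sequence duration, asserted).
#' @return A list of class `epoch_set`: `epochs` (tibble `epoch`,
#'   `sequence_index`, `onset_ms`), `latencies` (tibble `epoch`,
#'   `latency_ms` relative to epoch start), `window_ms`, `n_blinks`.
#' @export
extract_epochs <- function(catalog, protocol, window_ms = 3500) {
  soa <- attr(protocol, "soa_ms") %||% 750
  stopifnot(window_ms <= 5 * soa)  # epochs must not overlap
  seqs <- protocol_sequences(protocol)
  keep <- dplyr::filter(seqs, !.data$has_target)
  keep <- dplyr::mutate(keep, epoch = dplyr::row_number())
  times <- if (is.numeric(catalog)) catalog else catalog$max_ms
  idx <- findInterval(times, keep$onset_ms)
  ok <- idx >= 1L
  lat <- times[ok] - keep$onset_ms[idx[ok]]
  in_win <- lat >= 0 & lat < window_ms
  structure(list(
    epochs = dplyr::select(keep, "epoch", "sequence_index", "onset_ms"),
    latencies = tibble::tibble(epoch = idx[ok][in_win],
                               latency_ms = lat[in_win]),
    window_ms = window_ms,
    n_blinks = sum(in_win)), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$epochs), " epochs of ", x$window_ms, " ms, ",
      x$n_blinks, " blink peaks\n", sep = "")
  invisible(x)
}

#' Concatenate epochs into a blink point-process vector
#'
#' Epochs are concatenated in order; each blink peak becomes a unit impulse
#' at its sample position, all other samples are zero. By default each
#' 3500-ms epoch is zero-padded to the full 3750-ms sequence period before
#' concatenation so that the tone phase stays coherent across epochs: the
#' epoch window (3500 ms) is not an integer number of 750-ms tone cycles,
#' and abutting the windows directly rotates the tone phase by 2/3 cycle
#' per epoch, cancelling the stimulus-rate spectral component that the
#' analysis is after. Set `pad_to_ms = NULL` for plain abutted
#' concatenation.
#'
#' @param epochs An [extract_epochs()] result.
#' @param fs Sampling rate (Hz).
#' @param pad_to_ms Per-epoch length after zero-padding (default 3750, the
#'   five-tone sequence period); must be at least the epoch window.
#' @return Numeric 0/1 vector of length `n_epochs * pad_to_ms * fs / 1000`;
#'   attribute `epoch_samples` gives the per-epoch length.
#' @export
concatenate_epochs <- function(epochs, fs = 500, pad_to_ms = 3750) {
  pad_to_ms <- pad_to_ms %||% epochs$window_ms
  if (pad_to_ms < epochs$window_ms)
    stop("pad_to_ms must be at least the epoch window")
  ep_len <- round(pad_to_ms / 1000 * fs)
  v <- numeric(nrow(epochs$epochs) * ep_len)
  if (nrow(epochs$latencies)) {
    pos <- (epochs$latencies$epoch - 1L) * ep_len +
      round(epochs$latencies$latency_ms / 1000 * fs) + 1L
    pos <- pos[pos >= 1 & pos <= length(v)]
    v[pos] <- 1
  }
  attr(v, "epoch_samples") <- ep_len
  v
}

#' Average FFT power spectrum of a point-process vector
#'
#' Splits the vector into consecutive non-overlapping windows of `n_fft`
#' samples (remainder dropped), computes the per-window amplitude spectrum
#' `|FFT| / N`, squares it to power, and averages across windows. A vector
#' shorter than `n_fft` is zero-padded with a warning; in `mode = "single"`
#' only the first window is used.
#'
#' @param v Point-process vector (see [concatenate_epochs()]).
#' @param n_fft FFT length (default 8192).
#' @param fs Sampling rate (Hz).
#' @param mode `"windowed"` (average all full windows, default) or
#'   `"single"`.
#' @return Tibble of class `blink_spectrum` with `freq_hz` and `power` over
#'   the one-sided grid (resolution `fs / n_fft`); attributes `n_windows`,
#'   `fs`, `n_fft`.
#' @export
fft_power <- function(v, n_fft = 8192, fs = 500,
                      mode = c("windowed", "single")) {
  mode <- match.arg(mode)
  if (!length(v)) {
    warning("empty vector: returning a flat zero spectrum")
    v <- numeric(n_fft)
  }
  if (length(v) < n_fft) {
    warning("vector shorter than n_fft: zero-padding")
    v <- c(v, numeric(n_fft - length(v)))
  }
  n_win <- if (mode == "single") 1L else as.integer(length(v) %/% n_fft)
  half <- n_fft %/% 2 + 1L
  acc <- numeric(half)
  for (w in seq_len(n_win)) {
    seg <- v[((w - 1L) * n_fft + 1L):(w * n_fft)]
    amp <- abs(fft(seg))[seq_len(half)] / n_fft
    acc <- acc + amp^2
  }
  out <- tibble::tibble(freq_hz = (seq_len(half) - 1) * fs / n_fft,
                        power = acc / n_win)
  class(out) <- c("blink_spectrum", class(out))
  attr(out, "n_windows") <- n_win
  attr(out, "fs") <- fs
  attr(out, "n_fft") <- n_fft
  out
}

#' Peak and reference power at a probe frequency
#'
#' The probe bin is the grid bin nearest to `freq` (ties toward the lower
#' frequency). The reference power is the median power over the `n_ref`
#' neighboring bins on each side, excluding the probe bin and its immediate
#' neighbors, giving a local noise floor against which entrainment peaks are
#' judged.
#'
#' @param spectrum A [fft_power()] result.
#' @param freq Probe frequency (Hz).
#' @param n_ref Neighborhood half-width in bins (default 10).
#' @return One-row tibble: `freq_hz` (probe), `bin_hz` (actual bin
#'   frequency), `peak`, `reference`.
#' @export
spectrum_peak <- function(spectrum, freq, n_ref = 10) {
  d <- abs(spectrum$freq_hz - freq)
  k <- which(d == min(d))[1L]  # ties toward lower frequency
  nb <- setdiff(max(1L, k - n_ref):min(nrow(spectrum), k + n_ref),
                (k - 1L):(k + 1L))
  tibble::tibble(freq_hz = freq, bin_hz = spectrum$freq_hz[k],
                 peak = spectrum$power[k],
                 reference = median(spectrum$power[nb]))
}

#' Dominant entrainment frequency of a spectrum
#'
#' The sampled blink point process is harmonic-rich up to the Nyquist
#' frequency, so a global spectral maximum is not informative about
#' entrainment; the search is restricted to the band of stimulus-driven
#' rhythms (default up to 5 Hz, covering the sequence rate, the stimulus
#' rate and its first harmonic), excluding DC.
#'
#' @param spectrum A [fft_power()] result.
#' @param fmax Upper band edge in Hz (default 5).
#' @return Frequency (Hz) of the maximal-power bin in `(0, fmax]`.
#' @export
dominant_frequency <- function(spectrum, fmax = 5) {
  band <- which(spectrum$freq_hz > 0 & spectrum$freq_hz <= fmax)
  spectrum$freq_hz[band[which.max(spectrum$power[band])]]
}

#' Group-level entrainment statistics at probe frequencies
#'
#' Per group and probe frequency, tests per-participant peak power against
#' the per-participant local reference power with a Wilcoxon signed-rank
#' test; between groups, compares peak powers with a one-sided Wilcoxon
#' rank-sum test (alternative: group A exceeds group B). Effect sizes follow
#' the convention `r = Z / n` for the paired test and `r = Z / (n1 + n2)`
#' for the independent test; `conventional_r = TRUE` switches to
#' `Z / sqrt(n)`.
#'
#' @param spectra_a,spectra_b Lists of [fft_power()] results (one per
#'   participant).
#' @param freqs Probe frequencies (Hz).
#' @param conventional_r Use `Z / sqrt(n)` effect sizes instead.
#' @return Tibble: `freq_hz`, `test` (`"A vs reference"`, `"B vs
#'   reference"`, `"A vs B"`), `statistic`, `z`, `p`, `r`, `n`.
#' @export
entrainment_stats <- function(spectra_a, spectra_b,
                              freqs = c(0.267, 1.34, 2.67),
                              conventional_r = FALSE) {
  if (length(spectra_a) < 2 || length(spectra_b) < 2)
    stop("need >= 2 participants per group")
  peaks <- function(spectra, f) {
    purrr::map_dfr(spectra, spectrum_peak, freq = f)
  }
  rows <- purrr::map_dfr(freqs, function(f) {
    pa <- peaks(spectra_a, f); pb <- peaks(spectra_b, f)
    one <- function(label, x, y) {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                alternative = "greater"))
      d <- x - y
      v <- sum(rank(abs(d[d != 0]))[d[d != 0] > 0])
      z <- signed_rank_z(v, sum(d != 0))
      n <- length(x)
      tibble::tibble(freq_hz = f, test = label, statistic = unname(wt$statistic),
                     z = z, p = wt$p.value,
                     r = if (conventional_r) z / sqrt(n) else z / n, n = n)
    }
    wt2 <- suppressWarnings(stats::wilcox.test(pa$peak, pb$peak,
                                               alternative = "greater"))
    z2 <- rank_sum_z(unname(wt2$statistic), nrow(pa), nrow(pb))
    ntot <- nrow(pa) + nrow(pb)
    dplyr::bind_rows(
      one("A vs reference", pa$peak, pa$reference),
      one("B vs reference", pb$peak, pb$reference),
      tibble::tibble(freq_hz = f, test = "A vs B",
                     statistic = unname(wt2$statistic), z = z2,
                     p = wt2$p.value,
                     r = if (conventional_r) z2 / sqrt(ntot) else z2 / ntot,
                     n = ntot))
  })
  rows
}
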