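#' Bin blink latencies and smooth the normalized histogram
#'
#' Blink peak latencies within the sequence window are binned into half-open
#' 20-ms bins, normalized by the participant's total blink count (so the raw
#' frequencies sum to 1), and smoothed with a moving median of 5 bins
#' (windows shrink at the edges rather than padding beyond the sequence).
#' The un-smoothed normalized frequencies are the "pristine" values used by
#' the per-interval and slope analyses.
#'
#' @param latencies An `epoch_set` or a numeric vector of latencies (ms)
#'   within `[0, window_ms)`.
#' @param bin_ms Bin width in ms (default 20).
#' @param window_ms Sequence window (default 3500; 175 bins).
#' @param smooth `"median"` (default) or `"mean"`.
#' @param smooth_width Smoothing window in bins (default 5).
#' @return Tibble of class `binned_distribution`: `bin` (1-based), `t_lo`,
#'   `t_mid` (ms), `count`, `freq_raw`, `freq_smooth`. Attribute
#'   `n_blinks`; all-zero distributions are flagged via attribute `empty`.
#' @export
bin_and_smooth <- function(latencies, bin_ms = 20, window_ms = 3500,
                           smooth = c("median", "mean"), smooth_width = 5) {
  smooth <- match.arg(smooth)
  if (inherits(latencies, "epoch_set")) latencies <- latencies$latencies$latency_ms
  if (any(latencies < 0 | latencies >= window_ms))
    stop("latency outside [0, window_ms): upstream epoching bug")
  n_bins <- as.integer(window_ms / bin_ms)
  counts <- tabulate(floor(latencies / bin_ms) + 1L, nbins = n_bins)
  n_total <- length(latencies)
  freq <- if (n_total) counts / n_total else numeric(n_bins)
  sm <- smooth_curve(freq, smooth_width, smooth)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        t_lo = (seq_len(n_bins) - 1) * bin_ms,
                        t_mid = (seq_len(n_bins) - 0.5) * bin_ms,
                        count = counts, freq_raw = freq, freq_smooth = sm)
  class(out) <- c("binned_distribution", class(out))
  attr(out, "n_blinks") <- n_total
  attr(out, "empty") <- n_total == 0L
  attr(out, "bin_ms") <- bin_ms
  out
}

# Moving median/mean with shrinking windows at the edges.
smooth_curve <- function(x, width = 5, type = c("median", "mean")) {
  type <- match.arg(type)
  half <- width %/% 2
  fun <- if (type == "median") median else mean
  vapply(seq_along(x), function(i) {
    fun(x[max(1L, i - half):min(length(x), i + half)])
  }, numeric(1))
}

#' Pointwise median distribution across participants
#'
#' @param distributions List of [bin_and_smooth()] results, or a numeric
#'   matrix (participants x bins).
#' @param value Which column to take the median of when distributions are
#'   tibbles (default `freq_smooth`).
#' @return Tibble `bin`, `t_mid`, `freq` (pointwise median; midpoint-average
#'   convention for even participant counts).
#' @export
group_median_distribution <- function(distributions, value = "freq_smooth") {
  if (is.matrix(distributions)) {
    m <- distributions
    bin_ms <- 20
    bins <- seq_len(ncol(m))
  } else {
    stopifnot(length(distributions) >= 1)
    m <- do.call(rbind, lapply(distributions, function(d) d[[value]]))
    bin_ms <- attr(distributions[[1]], "bin_ms") %||% 20
    bins <- distributions[[1]]$bin
  }
  tibble::tibble(bin = bins, t_mid = (bins - 0.5) * bin_ms,
                 freq = col_medians(m))
}

#' Fit a five-Gaussian mixture curve to a median blink distribution
#'
#' Models the smoothed median blink-frequency curve as a sum of five
#' Gaussians, one per tone interval, minimized in least squares by
#' Nelder-Mead direct search. Initial means are the tone-interval midpoints,
#' the initial sigma is 20 ms, and initial amplitudes are the curve values
#' at the initial means. The optimizer is restarted from its own optimum
#' until the objective stops improving (relative tolerance 1e-12, at most
#' `max_restarts` restarts), which lets noiseless synthetic curves be
#' recovered essentially exactly.
#'
#' @param curve A [group_median_distribution()] tibble (or any tibble with
#'   `t_mid` and `freq`), length 175 for the default binning.
#' @param init_means Initial component means (ms).
#' @param init_sigma Initial component SD (ms).
#' @param max_iter Nelder-Mead iteration cap per restart.
#' @param max_restarts Maximum number of restarts.
#' @return A list of class `gauss5_fit`: `components` (tibble `mean`,
#'   `sigma`, `amplitude`, ordered by mean), `iterations` (total function
#'   evaluations), `mean_residual` (mean absolute deviation between model
#'   and curve), `converged`, `fitted` (tibble `t_mid`, `freq`, `fit`).
#' @export
fit_five_gaussians <- function(curve,
                               init_means = c(375, 1125, 1875, 2625, 3375),
                               init_sigma = 20, max_iter = 20000,
                               max_restarts = 24) {
  t <- curve$t_mid
  y <- curve$freq
  k <- length(init_means)
  if (all(y == 0)) {
    comps <- tibble::tibble(mean = init_means, sigma = rep(init_sigma, k),
                            amplitude = rep(0, k))
    return(structure(list(components = comps, iterations = 0L,
                          mean_residual = 0, converged = TRUE,
                          fitted = tibble::tibble(t_mid = t, freq = y, fit = 0)),
                     class = "gauss5_fit"))
  }
  model <- function(par) {
    mu <- par[1:k]; sig <- exp(par[(k + 1):(2 * k)]); amp <- par[(2 * k + 1):(3 * k)]
    rowSums(vapply(seq_len(k), function(j) {
      amp[j] * exp(-(t - mu[j])^2 / (2 * sig[j]^2))
    }, numeric(length(t))))
  }
  obj <- function(par) sum((model(par) - y)^2)
  init_amp <- pmax(y[vapply(init_means, function(m) which.min(abs(t - m)), 1L)],
                   max(y) * 1e-3)
  par <- c(init_means, rep(log(init_sigma), k), init_amp)
  total_evals <- 0L
  prev <- Inf
  converged <- FALSE
  for (r in seq_len(max_restarts)) {
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-15))
    total_evals <- total_evals + fit$counts[["function"]]
    par <- fit$par
    if (fit$value < 1e-20 ||
        (is.finite(prev) &&
         (prev - fit$value) <= 1e-10 * (abs(prev) + 1e-30))) {
      converged <- TRUE
      break
    }
    prev <- fit$value
  }
  mu <- par[1:k]; sig <- exp(par[(k + 1):(2 * k)]); amp <- par[(2 * k + 1):(3 * k)]
  ord <- order(mu)
  comps <- tibble::tibble(mean = mu[ord], sigma = sig[ord], amplitude = amp[ord])
  fitted_vals <- model(par)
  structure(list(components = comps, iterations = total_evals,
                 mean_residual = mean(abs(fitted_vals - y)),
                 converged = converged,
                 fitted = tibble::tibble(t_mid = t, freq = y, fit = fitted_vals)),
            class = "gauss5_fit")
}

#' @export
print.gauss5_fit <- function(x, ...) {
  cat("<gauss5_fit> mean residual ", format(x$mean_residual, digits = 4),
      ", ", x$iterations, " function evaluations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Chi-square distance between two frequency curves
#'
#' `sum((x_i - y_i)^2 / (x_i + y_i)) / 2`, with bins where `x_i + y_i = 0`
#' contributing 0. Symmetric, non-negative, zero iff the curves are equal.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return The distance (scalar).
#' @export
chi2_distance <- function(x, y) {
  if (length(x) != length(y)) stop("curves must have equal length")
  if (any(x < 0) || any(y < 0)) stop("curves must be non-negative")
  s <- x + y
  ok <- s > 0
  sum((x[ok] - y[ok])^2 / s[ok]) / 2
}

#' Permutation test of the chi-square distance between group median curves
#'
#' The observed statistic is the chi-square distance between the two groups'
#' pointwise-median curves. The null distribution is built by randomly
#' permuting participant group labels and recomputing the distance;
#' `p = (1 + #(null >= observed)) / (n_boot + 1)`.
#'
#' @param group_a,group_b Lists of [bin_and_smooth()] tibbles or numeric
#'   matrices (participants x bins).
#' @param n_boot Number of label randomizations (default 1000).
#' @param seed Integer seed.
#' @param value Column used when inputs are tibbles (default `freq_smooth`).
#' @return A list of class `dist_test`: `distance`, `p`, `n_boot`, `null`
#'   (the null distances).
#' @export
bootstrap_distance_test <- function(group_a, group_b, n_boot = 1000,
                                    seed = 1L, value = "freq_smooth") {
  as_mat <- function(g) {
    if (is.matrix(g)) g else do.call(rbind, lapply(g, function(d) d[[value]]))
  }
  a <- as_mat(group_a); b <- as_mat(group_b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 participants per group")
  set.seed(seed)
  pool <- rbind(a, b)
  na <- nrow(a); ntot <- nrow(pool)
  obs <- chi2_distance(col_medians(a), col_medians(b))
  null <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(ntot, na)
    chi2_distance(col_medians(pool[idx, , drop = FALSE]),
                  col_medians(pool[-idx, , drop = FALSE]))
  }, numeric(1))
  structure(list(distance = obs, p = (1 + sum(null >= obs)) / (n_boot + 1),
                 n_boot = n_boot, null = null),
            class = "dist_test")
}

#' @export
print.dist_test <- function(x, ...) {
  cat("<dist_test> chi-square distance ", format(x$distance, digits = 4),
      ", p = ", format(x$p, digits = 3), " (", x$n_boot,
      " randomizations)\n", sep = "")
  invisible(x)
}

#' Per-interval group comparison at the fitted Gaussian peaks
#'
#' For each tone interval, reads every participant's pristine (normalized,
#' un-smoothed) blink frequency at the bin containing the reference group's
#' fitted Gaussian peak in that interval, compares groups with a Wilcoxon
#' rank-sum test, and adjusts the five p-values with Benjamini-Hochberg FDR.
#'
#' @param group_a,group_b Lists of [bin_and_smooth()] tibbles or matrices
#'   (participants x bins) of pristine frequencies.
#' @param fit_a The reference group's [fit_five_gaussians()] result.
#' @param bin_ms Bin width (ms).
#' @param soa_ms Tone interval length (ms).
#' @return Tibble: `interval` (1-5), `peak_ms`, `bin`, `p`, `p_fdr`.
#'   Intervals whose peak falls outside the window are skipped with a
#'   warning.
#' @export
per_interval_peak_tests <- function(group_a, group_b, fit_a, bin_ms = 20,
                                    soa_ms = 750) {
  as_mat <- function(g) {
    if (is.matrix(g)) g else do.call(rbind, lapply(g, function(d) d$freq_raw))
  }
  a <- as_mat(group_a); b <- as_mat(group_b)
  n_bins <- ncol(a)
  window_ms <- n_bins * bin_ms
  peaks <- fit_a$components$mean
  rows <- purrr::map_dfr(seq_along(peaks), function(j) {
    pk <- peaks[j]
    if (pk < 0 || pk >= window_ms) {
      warning("fitted peak outside the sequence window; interval skipped")
      return(tibble::tibble())
    }
    bin <- floor(pk / bin_ms) + 1L
    interval <- floor(pk / soa_ms) + 1L
    p <- suppressWarnings(stats::wilcox.test(a[, bin], b[, bin]))$p.value
    tibble::tibble(interval = interval, peak_ms = pk, bin = bin, p = p)
  })
  rows$p_fdr <- stats::p.adjust(rows$p, method = "BH")
  rows
}
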