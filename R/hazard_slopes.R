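#' Peri-stimulus blink-frequency matrix across potential target positions
#'
#' For each potential target position (tone onsets at 750, 1500, 2250 ms
#' within the sequence window), counts blink peaks in half-open 20-ms bins
#' covering -300 to +300 ms around the onset (one bin edge coincides with
#' the onset; 15 pre- and 15 post-stimulus bins) and normalizes by the
#' participant's total blink count — the same pristine normalization as the
#' latency histograms.
#'
#' @param epochs An `epoch_set` (see [extract_epochs()]) or a numeric vector
#'   of within-sequence latencies (ms).
#' @param onsets_ms Potential target onsets within the sequence (default
#'   `c(750, 1500, 2250)` for positions 2-4).
#' @param half_window_ms Peri-stimulus half-window (default 300).
#' @param bin_ms Bin width (default 20).
#' @param n_total Total blink count for normalization; defaults to the
#'   number of latencies supplied.
#' @return Tibble of class `peristim`: `position` (2, 3, 4), `bin` (1-based
#'   across the window), `rel_lo_ms` (bin left edge relative to onset),
#'   `freq`.
#' @export
build_peristim <- function(epochs, onsets_ms = c(750, 1500, 2250),
                           half_window_ms = 300, bin_ms = 20,
                           n_total = NULL) {
  lat <- if (inherits(epochs, "epoch_set")) epochs$latencies$latency_ms else epochs
  window_ms <- if (inherits(epochs, "epoch_set")) epochs$window_ms else 3500
  stopifnot(min(onsets_ms) - half_window_ms >= 0,
            max(onsets_ms) + half_window_ms <= window_ms)
  n_total <- n_total %||% length(lat)
  n_bins <- as.integer(2 * half_window_ms / bin_ms)
  rows <- purrr::map_dfr(seq_along(onsets_ms), function(i) {
    rel <- lat - onsets_ms[i]
    inw <- rel >= -half_window_ms & rel < half_window_ms
    counts <- tabulate(floor((rel[inw] + half_window_ms) / bin_ms) + 1L,
                       nbins = n_bins)
    tibble::tibble(position = i + 1L, bin = seq_len(n_bins),
                   rel_lo_ms = -half_window_ms + (seq_len(n_bins) - 1) * bin_ms,
                   freq = if (n_total > 0) counts / n_total else counts * 0)
  })
  class(rows) <- c("peristim", class(rows))
  rows
}

#' Robust slope of blink frequency across target positions
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685, scale = 1.48 x median absolute residual) of the
#' frequencies at positions 2, 3, 4 on centered position codes (-1, 0, 1).
#' The slope unit is change in frequency per position step; negative slopes
#' indicate deepening suppression with increasing target probability. With
#' zero residuals (an exact line) the robust fit equals ordinary least
#' squares. If the IRLS does not converge the OLS slope is returned with a
#' `converged = FALSE` attribute.
#'
#' @param y Frequencies at the ordered positions.
#' @param x Position codes (default centered `(-1, 0, 1)`).
#' @param tuning Bisquare tuning constant (default 4.685).
#' @param max_iter Iteration cap.
#' @return Slope (scalar) with attribute `converged`.
#' @export
robust_slope <- function(y, x = seq_along(y) - (length(y) + 1) / 2,
                         tuning = 4.685, max_iter = 50) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (all(y == y[1])) return(structure(0, converged = TRUE))
  wls <- function(w) {
    xm <- sum(w * x) / sum(w)
    ym <- sum(w * y) / sum(w)
    sxx <- sum(w * (x - xm)^2)
    b <- if (sxx > 0) sum(w * (x - xm) * (y - ym)) / sxx else 0
    list(slope = b, intercept = ym - b * xm)
  }
  fit <- wls(rep(1, length(y)))
  ols_slope <- fit$slope
  slope <- ols_slope
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    resid <- y - (fit$intercept + fit$slope * x)
    s <- 1.48 * median(abs(resid))
    if (s < 1e-12) { converged <- TRUE; break }
    u <- resid / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2) { slope <- ols_slope; break }
    new_fit <- wls(w)
    if (abs(new_fit$slope - fit$slope) < 1e-10 * (1 + abs(fit$slope))) {
      fit <- new_fit; converged <- TRUE; break
    }
    fit <- new_fit
  }
  slope <- if (converged) fit$slope else ols_slope
  structure(slope, converged = converged)
}

#' Per-bin robust slopes for one participant
#'
#' @param peristim A [build_peristim()] tibble.
#' @return Tibble `bin`, `rel_lo_ms`, `slope`.
#' @export
slope_profile <- function(peristim) {
  wide <- tidyr::pivot_wider(peristim, id_cols = c("bin", "rel_lo_ms"),
                             names_from = "position", values_from = "freq")
  pos_cols <- setdiff(names(wide), c("bin", "rel_lo_ms"))
  sl <- vapply(seq_len(nrow(wide)), function(i) {
    as.numeric(robust_slope(as.numeric(wide[i, pos_cols])))
  }, numeric(1))
  tibble::tibble(bin = wide$bin, rel_lo_ms = wide$rel_lo_ms, slope = sl)
}

# Per-bin one-sample t statistics of a participants x bins matrix, possibly
# sign-flipped per participant. css = colSums(s^2) is flip-invariant.
col_t <- function(s, signs = NULL, css = colSums(s^2)) {
  n <- nrow(s)
  m <- if (is.null(signs)) colMeans(s) else as.numeric(signs %*% s) / n
  v <- (css - n * m^2) / (n - 1)
  m / sqrt(pmax(v, 1e-300) / n)
}

# Contiguous supra-threshold clusters and their summed-t mass for the
# requested tail. Returns a data.frame (possibly empty).
find_clusters <- function(t_vals, t_crit, tail = c("less", "greater")) {
  tail <- match.arg(tail)
  hit <- if (tail == "less") t_vals < t_crit else t_vals > t_crit
  if (!any(hit)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ks <- which(r$values)
  data.frame(start = starts[ks], end = ends[ks],
             mass = vapply(ks, function(k) {
               sum(t_vals[starts[k]:ends[k]])
             }, numeric(1)))
}

#' One-sample sign-flip cluster permutation test on slope profiles
#'
#' Tests whether per-bin robust slopes differ from zero across participants.
#' Bins whose one-sample t statistic exceeds the one-sided critical value at
#' `cluster_alpha` form contiguous candidate clusters whose mass is the sum
#' of their t values. The null distribution of the extreme cluster mass is
#' built by randomly flipping the sign of each participant's whole slope
#' profile; when `2^n <= n_perm` all sign patterns are enumerated and the
#' p-values are exact. With `method = "tmax"` the extreme single-bin t
#' statistic is used instead of cluster mass.
#'
#' @param slopes Numeric matrix, participants x bins.
#' @param alternative `"less"` (suppression; default) or `"greater"`.
#' @param cluster_alpha Cluster-forming tail probability (default 0.05).
#' @param n_perm Number of permutations (default 1000; warning below 100).
#' @param seed Integer seed (ignored for exhaustive enumeration).
#' @param method `"mass"` (default) or `"tmax"`.
#' @param rel_lo_ms Optional bin left edges (ms) used for reporting.
#' @return A list of class `cluster_test`: `bins` (tibble `bin`,
#'   `rel_lo_ms`, `t`), `clusters` (tibble `start`, `end`, `start_ms`,
#'   `end_ms`, `mass`, `p`), `t_crit`, `exhaustive`, `n_perm`, `null`
#'   (extreme null masses).
#' @export
cluster_permutation_test <- function(slopes, alternative = c("less", "greater"),
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = 1L, method = c("mass", "tmax"),
                                     rel_lo_ms = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(is.matrix(slopes), nrow(slopes) >= 2)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  n <- nrow(slopes)
  css <- colSums(slopes^2)
  t_crit <- qt(cluster_alpha, df = n - 1)
  if (alternative == "greater") t_crit <- -t_crit
  t_obs <- col_t(slopes, css = css)
  obs <- find_clusters(t_obs, t_crit, alternative)

  extreme <- function(t_vals) {
    if (method == "tmax") {
      if (alternative == "less") min(t_vals) else max(t_vals)
    } else {
      cl <- find_clusters(t_vals, t_crit, alternative)
      if (!nrow(cl)) 0 else if (alternative == "less") min(cl$mass) else max(cl$mass)
    }
  }

  # tie tolerance: the observed statistic recomputed along a different
  # floating-point path (e.g. the identity sign pattern) must still count
  tie_eps <- function(mass) 1e-9 * (1 + abs(mass))
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- vapply(seq_len(nrow(signs_mat)), function(i) {
      extreme(col_t(slopes, signs_mat[i, ], css))
    }, numeric(1))
    denom <- nrow(signs_mat)
    p_of <- function(mass) {
      k <- if (alternative == "less") sum(null <= mass + tie_eps(mass))
           else sum(null >= mass - tie_eps(mass))
      k / denom
    }
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      extreme(col_t(slopes, sample(c(-1, 1), n, replace = TRUE), css))
    }, numeric(1))
    p_of <- function(mass) {
      k <- if (alternative == "less") sum(null <= mass + tie_eps(mass))
           else sum(null >= mass - tie_eps(mass))
      (1 + k) / (n_perm + 1)
    }
  }

  obs_stat <- if (method == "tmax") {
    if (nrow(obs)) vapply(seq_len(nrow(obs)), function(k) {
      seg <- t_obs[obs$start[k]:obs$end[k]]
      if (alternative == "less") min(seg) else max(seg)
    }, numeric(1)) else numeric(0)
  } else obs$mass

  rel <- rel_lo_ms %||% seq_len(ncol(slopes))
  clusters <- tibble::tibble(
    start = obs$start, end = obs$end,
    start_ms = rel[obs$start], end_ms = rel[obs$end],
    mass = obs$mass,
    p = if (nrow(obs)) vapply(obs_stat, p_of, numeric(1)) else numeric(0))
  structure(list(
    bins = tibble::tibble(bin = seq_len(ncol(slopes)), rel_lo_ms = rel, t = t_obs),
    clusters = clusters, t_crit = t_crit, exhaustive = exhaustive,
    n_perm = if (exhaustive) 2^n else n_perm, null = null,
    alternative = alternative, method = method),
    class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", nrow(x$clusters), " cluster(s), ",
      if (x$exhaustive) "exhaustive " else "", x$n_perm,
      " sign-flip permutations, threshold t = ",
      format(x$t_crit, digits = 4), "\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Slope matrix for a cohort of epoch sets
#'
#' Convenience wrapper: builds the peri-stimulus matrix and per-bin robust
#' slope profile for each participant and stacks them.
#'
#' @param epoch_sets List of `epoch_set` objects (one per participant).
#' @param ... Passed to [build_peristim()].
#' @return List: `slopes` (participants x bins matrix), `rel_lo_ms`.
#' @export
cohort_slopes <- function(epoch_sets, ...) {
  profs <- purrr::map(epoch_sets, function(ep) slope_profile(build_peristim(ep, ...)))
  list(slopes = do.call(rbind, lapply(profs, `[[`, "slope")),
       rel_lo_ms = profs[[1]]$rel_lo_ms)
}
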