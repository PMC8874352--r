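# Candidate velocity events on a horizontal EOG trace: peaks of the
# derivative magnitude above an adaptive robust threshold, with features
# (peak velocity, amplitude, duration) per event. The trace is low-passed
# (30 Hz) before differentiation; white measurement noise would otherwise
# dominate the velocity signal.
saccade_candidates <- function(x, fs, threshold_k = 4, min_sep_ms = 80) {
  lp <- signal::butter(4, min(30 / (fs / 2), 0.99), type = "low")
  x <- as.numeric(signal::filtfilt(lp, x))
  v <- c(0, diff(x)) * fs  # units per second
  av <- abs(v)
  thr <- median(av) + threshold_k * 1.48 * median(abs(av - median(av)))
  above <- av > thr
  if (!any(above)) {
    return(tibble::tibble(onset_ms = numeric(), peak_ms = numeric(),
                          duration_ms = numeric(), peak_velocity = numeric(),
                          amplitude = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by < min_sep_ms (one saccade can cross threshold twice)
  min_sep <- round(min_sep_ms / 1000 * fs)
  keep <- list(); cs <- runs[1, 1]; ce <- runs[1, 2]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - ce < min_sep) ce <- runs[i, 2]
      else { keep[[length(keep) + 1L]] <- c(cs, ce); cs <- runs[i, 1]; ce <- runs[i, 2] }
    }
  }
  keep[[length(keep) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, keep)
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    s <- m[i, 1]; e <- m[i, 2]
    pk <- s + which.max(av[s:e]) - 1L
    # duration from half-peak crossings of the velocity profile around the peak
    half <- av[pk] / 2
    a <- pk; while (a > 1 && av[a - 1] > half) a <- a - 1L
    b <- pk; while (b < length(av) && av[b + 1] > half) b <- b + 1L
    tibble::tibble(onset_ms = (a - 1) / fs * 1000,
                   peak_ms = (pk - 1) / fs * 1000,
                   duration_ms = (b - a + 1) / fs * 1000,
                   peak_velocity = av[pk],
                   amplitude = abs(x[min(length(x), b + 1)] - x[max(1, a - 1)]))
  })
}

#' Train a two-class Gaussian feature model for saccade detection
#'
#' Extracts candidate velocity events from an unsupervised training window
#' of the horizontal EOG trace and fits a two-component Gaussian mixture
#' (saccade vs. other) to their log peak velocity, log amplitude and log
#' duration by expectation-maximization. The saccade class is the component
#' with the larger mean peak velocity. A fit whose component mean velocities
#' differ by less than a factor e (1 log unit) is flagged degenerate
#' (single-class data).
#'
#' @param x Horizontal (bipolar) EOG trace.
#' @param fs Sampling rate (Hz).
#' @param train_window_s Training window length in seconds, in `[50, 200]`.
#' @param seed Integer seed (the EM initialization is deterministic; the
#'   seed is stored for bookkeeping).
#' @return A list of class `saccade_model`: `mixture` (the fitted mixture),
#'   `saccade_class`, `degenerate`, `features` (training events),
#'   `threshold_k`, `fs`.
#' @export
train_feature_model <- function(x, fs, train_window_s = 100, seed = 1L) {
  stopifnot(train_window_s >= 50, train_window_s <= 200)
  n_train <- round(train_window_s * fs)
  if (length(x) < n_train) stop("trace shorter than the training window")
  set.seed(seed)
  ev <- saccade_candidates(x[seq_len(n_train)], fs)
  if (nrow(ev) < 10)
    stop("fewer than 10 candidate events in the training window")
  feats <- cbind(log_vel = log(ev$peak_velocity),
                 log_amp = log(pmax(ev$amplitude, 1e-9)),
                 log_dur = log(ev$duration_ms))
  mix <- mclust::Mclust(feats, G = 2, verbose = FALSE)
  mu_vel <- mix$parameters$mean["log_vel", ]
  sacc_class <- which.max(mu_vel)
  # single-class data: components whose mean peak velocities differ by less
  # than a factor e cannot be saccades vs. background
  degenerate <- abs(diff(mu_vel)) < 1
  structure(list(mixture = mix, saccade_class = sacc_class,
                 degenerate = degenerate,
                 features = dplyr::mutate(ev, class = mix$classification),
                 fs = fs, seed = seed),
            class = "saccade_model")
}

#' @export
print.saccade_model <- function(x, ...) {
  cat("<saccade_model> ", nrow(x$features), " training events, saccade class ",
      x$saccade_class, if (x$degenerate) " (degenerate fit)", "\n", sep = "")
  invisible(x)
}

#' Score candidate events with saccade posterior probabilities
#'
#' Detects candidate velocity events over the full trace and assigns each
#' the posterior probability of the saccade class under the trained mixture.
#' Events overlapping detected blink intervals are excluded by default
#' (peri-blink saccadic movements are handled by the blink detector, not a
#' third mixture class).
#'
#' @param x Horizontal EOG trace.
#' @param model A [train_feature_model()] result.
#' @param blink_intervals Optional tibble with `start_ms`, `end_ms` of blink
#'   intervals to exclude.
#' @param exclude_blinks Exclude events overlapping blink intervals
#'   (default `TRUE`).
#' @return Tibble of saccade events: `onset_ms`, `duration_ms`,
#'   `probability` (posterior of the saccade class; the two class posteriors
#'   sum to 1 per event).
#' @export
score_events <- function(x, model, blink_intervals = NULL,
                         exclude_blinks = TRUE) {
  ev <- saccade_candidates(x, model$fs)
  if (!nrow(ev)) {
    return(tibble::tibble(onset_ms = numeric(), duration_ms = numeric(),
                          probability = numeric()))
  }
  feats <- cbind(log_vel = log(ev$peak_velocity),
                 log_amp = log(pmax(ev$amplitude, 1e-9)),
                 log_dur = log(ev$duration_ms))
  post <- mclust::predict.Mclust(model$mixture, feats)$z
  prob <- post[, model$saccade_class]
  out <- tibble::tibble(onset_ms = ev$onset_ms, duration_ms = ev$duration_ms,
                        probability = prob)
  if (exclude_blinks && !is.null(blink_intervals) && nrow(blink_intervals)) {
    ov <- vapply(seq_len(nrow(out)), function(i) {
      any(out$onset_ms[i] < blink_intervals$end_ms &
            out$onset_ms[i] + out$duration_ms[i] > blink_intervals$start_ms)
    }, logical(1))
    out <- out[!ov, ]
  }
  out
}

#' Compare saccade-probability (or duration) variance between groups
#'
#' Computes, per participant, the variance of event saccade probabilities
#' (or durations) across that participant's events, and compares the two
#' groups of per-participant variances with a Wilcoxon rank-sum test,
#' reporting `Z` and the effect size `r = Z / (n1 + n2)` (or `Z / sqrt(n)`
#' with `conventional_r`).
#'
#' @param group_a,group_b Lists of [score_events()] tibbles, one per
#'   participant.
#' @param what `"probability"` (default) or `"duration_ms"`.
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @param conventional_r Use `Z / sqrt(n)` effect size.
#' @return One-row tibble: `what`, `mean_a`, `mean_b`, `statistic`, `z`,
#'   `p`, `r`, `degenerate` (`TRUE` when every participant's variance is 0).
#' @export
variance_compare <- function(group_a, group_b, what = "probability",
                             alternative = "two.sided",
                             conventional_r = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 participants per group")
  pvar <- function(g) vapply(g, function(ev) {
    if (nrow(ev) < 2) 0 else stats::var(ev[[what]])
  }, numeric(1))
  va <- pvar(group_a); vb <- pvar(group_b)
  degenerate <- all(va == 0) && all(vb == 0)
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = alternative))
  z <- rank_sum_z(unname(wt$statistic), length(va), length(vb))
  n <- length(va) + length(vb)
  tibble::tibble(what = what, mean_a = mean(va), mean_b = mean(vb),
                 statistic = unname(wt$statistic), z = z, p = wt$p.value,
                 r = if (conventional_r) z / sqrt(n) else z / n,
                 degenerate = degenerate)
}
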