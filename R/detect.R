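#' Band-limit and standardize a trace for blink detection
#'
#' Zero-phase band-pass at 1-20 Hz (4th-order Butterworth applied
#' forward-backward), then standardization to zero mean and unit SD. The
#' filter realization is a package choice (the stereotype detector only
#' fixes the passband); it is exposed through `order`.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz), >= 100.
#' @param band Passband in Hz.
#' @param order Total filter order (must be even; order/2 passed to the
#'   band-pass design).
#' @return Standardized band-limited numeric vector.
#' @export
preprocess_trace <- function(x, fs, band = c(1, 20), order = 4) {
  stopifnot(fs >= 100, order %% 2 == 0)
  if (length(x) < 3 * fs)
    stop("trace shorter than 3 filter lengths (need >= 3 s of signal)")
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  as.numeric((y - mean(y)) / sd(y))
}

#' Find candidate blink intervals in a standardized trace
#'
#' Maximal runs where the trace exceeds its mean by 1.5 SD; runs separated
#' by less than `min_separation_ms` are merged, then runs shorter than
#' `min_interval_ms` are dropped.
#'
#' @param z Standardized trace (see [preprocess_trace()]).
#' @param fs Sampling rate (Hz).
#' @param threshold_sd Threshold in SD units above the mean (default 1.5).
#' @param min_interval_ms Minimum run length (ms).
#' @param min_separation_ms Minimum separation between runs (ms).
#' @return Tibble with `start`, `end` (1-based sample indices, inclusive).
#' @export
find_candidates <- function(z, fs, threshold_sd = 1.5,
                            min_interval_ms = 50, min_separation_ms = 50) {
  thr <- mean(z) + threshold_sd * sd(z)
  above <- z > thr
  if (!any(above)) return(tibble::tibble(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < min_separation_ms
  min_sep <- round(min_separation_ms / 1000 * fs)
  if (nrow(runs) > 1L) {
    keep_start <- runs$start[1L]
    merged <- list()
    cur_end <- runs$end[1L]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - cur_end - 1L < min_sep) {
        cur_end <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
        keep_start <- runs$start[i]
        cur_end <- runs$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
    m <- do.call(rbind, merged)
    runs <- tibble::tibble(start = m[, 1], end = m[, 2])
  }
  min_len <- round(min_interval_ms / 1000 * fs)
  dplyr::filter(runs, .data$end - .data$start + 1L >= min_len)
}

# Least-squares line fit over the inner 80% (by amplitude span) of a stroke.
# Returns slope, intercept (vs sample index within the stroke), and R^2
# against the actual trajectory over the fitted span.
stroke_fit <- function(values) {
  if (length(values) < 3L) return(list(slope = NA_real_, r2 = 0))
  lo <- min(values); hi <- max(values)
  lo_cut <- lo + 0.1 * (hi - lo)
  hi_cut <- lo + 0.9 * (hi - lo)
  keep <- which(values >= lo_cut & values <= hi_cut)
  if (length(keep) < 3L) keep <- seq_along(values)
  x <- keep; y <- values[keep]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(list(slope = 0, r2 = 0))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  fitted <- mean(y) + slope * (x - mean(x))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else max(0, 1 - sum((y - fitted)^2) / sst)
  list(slope = slope, r2 = r2)
}

#' Fit blink landmarks and stroke lines for one candidate interval
#'
#' Locates the interval maximum and the zero crossings immediately left and
#' right of it (searched up to `max_search_s` from the interval edges), then
#' fits least-squares lines to the inner 80% (by amplitude span) of the
#' up-stroke and the down-stroke. The stroke R-squared values measure how
#' stereotypical the putative blink is.
#'
#' @param z Standardized trace.
#' @param start,end Candidate interval (sample indices).
#' @param fs Sampling rate (Hz).
#' @param max_search_s Zero-crossing search bound in seconds (default 1).
#' @return One-row tibble (`left_zero`, `max_frame`, `right_zero`,
#'   `max_value`, `r2_up`, `r2_down`, `max_up_velocity`), or `NULL` when a
#'   zero crossing is missing within the search bound (candidate rejected).
#' @export
fit_landmarks <- function(z, start, end, fs = 500, max_search_s = 1) {
  stopifnot(start >= 1, end <= length(z), start <= end)
  seg <- z[start:end]
  max_frame <- start + which.max(seg) - 1L
  max_value <- z[max_frame]
  bound <- round(max_search_s * fs)

  lz <- NA_integer_
  lo <- max(1L, max_frame - bound)
  for (i in max_frame:lo) if (z[i] <= 0) { lz <- i; break }
  if (is.na(lz)) return(NULL)  # degenerate baseline: no left zero crossing
  rz <- NA_integer_
  hi <- min(length(z), max_frame + bound)
  for (i in max_frame:hi) if (z[i] <= 0) { rz <- i; break }
  if (is.na(rz)) return(NULL)  # no right zero crossing within the bound

  up <- z[lz:max_frame]
  down <- z[max_frame:rz]
  fu <- stroke_fit(up)
  fd <- stroke_fit(down)
  vel <- if (length(up) > 1L) max(diff(up)) else NA_real_
  tibble::tibble(left_zero = lz, max_frame = max_frame, right_zero = rz,
                 max_value = max_value, r2_up = fu$r2, r2_down = fd$r2,
                 max_up_velocity = vel)
}

#' Blink-amplitude ratio (BAR) and stereotypy filter
#'
#' BAR divides the mean signal amplitude between a blink's zero crossings by
#' the mean of the positive portion of the surrounding signal (from the
#' previous blink's right zero crossing to the current left zero crossing,
#' and from the current right zero crossing to the next blink's right zero
#' crossing, or the end of the signal for the last blink). Candidates with
#' BAR outside `bar_range` are excluded; an empty positive surround yields
#' `BAR = Inf` and exclusion.
#'
#' @param candidates Tibble of landmark rows (time-ordered).
#' @param z Standardized trace.
#' @param bar_range Accepted BAR range (default `c(3, 20)`).
#' @return The retained candidates with a `bar` column.
#' @export
compute_bar <- function(candidates, z, bar_range = c(3, 20)) {
  n <- nrow(candidates)
  if (!n) return(dplyr::mutate(candidates, bar = numeric(0)))
  bar <- numeric(n)
  for (i in seq_len(n)) {
    inblink <- mean(z[candidates$left_zero[i]:candidates$right_zero[i]])
    pre_from <- if (i > 1L) candidates$right_zero[i - 1L] else 1L
    post_to <- if (i < n) candidates$right_zero[i + 1L] else length(z)
    surround <- c(z[pre_from:candidates$left_zero[i]],
                  z[candidates$right_zero[i]:post_to])
    pos <- surround[surround > 0]
    bar[i] <- if (length(pos)) inblink / mean(pos) else Inf
  }
  out <- dplyr::mutate(candidates, bar = bar)
  dplyr::filter(out, .data$bar >= bar_range[1], .data$bar <= bar_range[2])
}

# pAVR: peak amplitude divided by peak up-stroke velocity, expressed per
# 10 ms of rise time. Curved blink rises (~90 ms) score ~9; sharp saccadic
# rises score well below the cutoff of 3.
pavr_value <- function(max_value, max_up_velocity, fs) {
  vel_per_ms <- max_up_velocity * fs / 1000
  (max_value / vel_per_ms) / 10
}

#' Tier blinks and apply stereotypy and amplitude filters
#'
#' Assigns quality tiers from the stroke fits (good: both R^2 > 0.90;
#' better: > 0.95; best: > 0.98), removes saccadic events by the positive
#' amplitude-by-velocity ratio (pAVR < 3), and removes amplitude outliers:
#' candidates farther than 5 robust SD (best tier) or 2 robust SD (other
#' tiers) from the best-blink median amplitude, where the robust SD is 1.48
#' times the median absolute deviation from that median. When no best-tier
#' blink exists the good-tier median is used with a warning.
#'
#' @param candidates Tibble from [compute_bar()].
#' @param fs Sampling rate (Hz).
#' @param min_pavr pAVR cutoff (default 3).
#' @param tier_r2 Named thresholds for the three tiers.
#' @return Used blinks: the surviving candidates with `pavr` and `tier`
#'   columns.
#' @export
apply_quality_filters <- function(candidates, fs = 500, min_pavr = 3,
                                  tier_r2 = c(good = 0.90, better = 0.95,
                                              best = 0.98)) {
  if (!nrow(candidates)) {
    return(dplyr::mutate(candidates, pavr = numeric(0), tier = character(0)))
  }
  r2min <- pmin(candidates$r2_up, candidates$r2_down)
  tier <- dplyr::case_when(
    r2min > tier_r2[["best"]] ~ "best",
    r2min > tier_r2[["better"]] ~ "better",
    r2min > tier_r2[["good"]] ~ "good",
    TRUE ~ "none")
  out <- dplyr::mutate(candidates,
                       pavr = pavr_value(.data$max_value,
                                         .data$max_up_velocity, fs),
                       tier = tier)
  out <- dplyr::filter(out, .data$tier != "none", .data$pavr >= min_pavr)
  if (!nrow(out)) return(out)

  best_amp <- out$max_value[out$tier == "best"]
  if (length(best_amp)) {
    ref <- median(best_amp)
  } else {
    warning("no best-tier blinks; amplitude filter uses good-tier median")
    ref <- median(out$max_value)
  }
  rsd <- 1.48 * median(abs(out$max_value - ref))
  if (rsd > 0) {
    lim <- ifelse(out$tier == "best", 5, 2)
    out <- dplyr::filter(out, abs(.data$max_value - ref) <= lim * rsd)
  }
  out
}

#' Detect used blinks on one channel
#'
#' Full stereotype-detection chain: band-limit and standardize, find
#' supra-threshold candidate intervals, fit landmarks and stroke lines,
#' apply the BAR, pAVR and amplitude filters.
#'
#' @param x Raw channel trace.
#' @param fs Sampling rate (Hz).
#' @param ... Passed to the stage functions.
#' @return Tibble of used blinks with landmark sample indices, `max_ms`
#'   (peak time in ms), stroke R^2, `bar`, `pavr`, `tier`.
#' @export
detect_blinks <- function(x, fs = 500, ...) {
  z <- preprocess_trace(x, fs)
  ivl <- find_candidates(z, fs)
  cands <- purrr::map(seq_len(nrow(ivl)), function(i) {
    fit_landmarks(z, ivl$start[i], ivl$end[i], fs)
  })
  cands <- dplyr::bind_rows(purrr::compact(cands))
  if (!nrow(cands)) {
    return(tibble::tibble(left_zero = integer(), max_frame = integer(),
                          right_zero = integer(), max_value = numeric(),
                          r2_up = numeric(), r2_down = numeric(),
                          max_up_velocity = numeric(), bar = numeric(),
                          pavr = numeric(), tier = character(),
                          max_ms = numeric()))
  }
  cands <- dplyr::distinct(cands, .data$max_frame, .keep_all = TRUE)
  cands <- dplyr::arrange(cands, .data$max_frame)
  used <- apply_quality_filters(compute_bar(cands, z), fs, ...)
  dplyr::mutate(used, max_ms = (.data$max_frame - 1) / fs * 1000)
}

#' Select the best channel and build a blink catalog
#'
#' Runs the detector on each candidate channel and keeps the channel that
#' yields the most good-or-better blinks (ties broken by the priority order
#' of `channels`). Catalogs with fewer than `min_blinks` used blinks are
#' flagged unstable.
#'
#' @param recording An `eog_recording` (or a tibble of channel columns).
#' @param channels Candidate channel names, in tie-break priority order.
#' @param fs Sampling rate; taken from the recording when available.
#' @param min_blinks Stability threshold (default 20).
#' @param participant Optional participant id stored on the catalog.
#' @return A tibble of class `blink_catalog` of used blinks, with attributes
#'   `channel`, `participant`, `n_used`, `unstable`, and `ibi_ms`
#'   (inter-blink peak intervals).
#' @export
select_best_signal <- function(recording,
                               channels = c("upperV", "lowerV", "Fp1", "Fp2",
                                            "Fz", "F3", "F4"),
                               fs = NULL, min_blinks = 20,
                               participant = NA_character_) {
  sig <- if (inherits(recording, "eog_recording")) recording$signal else recording
  fs <- fs %||% (if (inherits(recording, "eog_recording")) recording$fs else 500)
  channels <- intersect(channels, names(sig))
  if (!length(channels)) stop("no candidate channel present in the recording")
  runs <- purrr::map(channels, function(ch) detect_blinks(sig[[ch]], fs))
  n_good <- vapply(runs, function(r) sum(r$tier %in% c("good", "better", "best")), 1L)
  pick <- which.max(n_good)  # first max wins: channels are in priority order
  cat_tbl <- runs[[pick]]
  class(cat_tbl) <- c("blink_catalog", class(cat_tbl))
  attr(cat_tbl, "channel") <- channels[pick]
  attr(cat_tbl, "participant") <- participant
  attr(cat_tbl, "n_used") <- nrow(cat_tbl)
  attr(cat_tbl, "unstable") <- nrow(cat_tbl) < min_blinks
  attr(cat_tbl, "ibi_ms") <- if (nrow(cat_tbl) > 1) diff(cat_tbl$max_ms) else numeric(0)
  cat_tbl
}

#' Build a blink catalog directly from known peak times
#'
#' Used when ground-truth event logs (or an external detector's output)
#' stand in for signal-level detection, e.g. in event-level simulations.
#'
#' @param time_ms Blink peak times in ms.
#' @param participant Participant id.
#' @param min_blinks Stability threshold.
#' @return A `blink_catalog` tibble with `max_ms`.
#' @export
catalog_from_times <- function(time_ms, participant = NA_character_,
                               min_blinks = 20) {
  time_ms <- sort(time_ms)
  out <- tibble::tibble(max_ms = time_ms)
  class(out) <- c("blink_catalog", class(out))
  attr(out, "channel") <- "ground_truth"
  attr(out, "participant") <- participant
  attr(out, "n_used") <- nrow(out)
  attr(out, "unstable") <- nrow(out) < min_blinks
  attr(out, "ibi_ms") <- if (nrow(out) > 1) diff(time_ms) else numeric(0)
  out
}

#' Inter-blink intervals of a catalog
#' @param catalog A `blink_catalog`.
#' @return Numeric vector of intervals between successive blink peaks (ms).
#' @export
blink_ibis <- function(catalog) {
  attr(catalog, "ibi_ms") %||%
    (if (nrow(catalog) > 1) diff(sort(catalog$max_ms)) else numeric(0))
}
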