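#' Stereotyped blink waveform description
#'
#' Blinks close the eye fast (< 0.1 s) and reopen more slowly (~0.2 s), for a
#' total excursion of ~0.3 s. The template is a linear up-stroke followed by a
#' truncated-and-rescaled exponential down-stroke (time constant equal to the
#' stroke duration, so the decay is gently convex but near-linear over its
#' inner 80%), smoothed with a short raised-cosine kernel so the peak and feet
#' are rounded as in real recordings.
#'
#' @param up_ms Up-stroke (closing) duration in ms; must be < 100.
#' @param down_ms Down-stroke (reopening) duration in ms.
#' @param amplitude Peak amplitude in channel-relative units.
#' @param smooth_ms Raised-cosine smoothing kernel width in ms.
#' @return A list of class `blink_shape`.
#' @export
blink_shape <- function(up_ms = 90, down_ms = 200, amplitude = 1,
                        smooth_ms = 16) {
  stopifnot(up_ms > 0, up_ms < 100, down_ms > 0, amplitude > 0)
  structure(list(up_ms = up_ms, down_ms = down_ms, amplitude = amplitude,
                 smooth_ms = smooth_ms), class = "blink_shape")
}

#' Render a blink template at a sampling rate
#'
#' @param shape A [blink_shape()].
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the waveform (peak value = `amplitude`), with
#'   attribute `peak_sample` giving the 1-based index of the maximum.
#' @export
blink_template <- function(shape, fs = 500) {
  n_up <- max(2L, round(shape$up_ms / 1000 * fs))
  n_down <- max(2L, round(shape$down_ms / 1000 * fs))
  up <- seq(0, 1, length.out = n_up + 1L)[-1L]
  tt <- seq(0, 1, length.out = n_down + 1L)[-1L]
  tau <- 1  # decay time constant = stroke duration (near-linear inner 80%)
  down <- (exp(-tt / tau) - exp(-1 / tau)) / (1 - exp(-1 / tau))
  w <- c(rep(0, 8), up, down, rep(0, 8))
  n_k <- max(3L, 2L * (round(shape$smooth_ms / 1000 * fs) %/% 2L) + 1L)
  k <- 0.5 * (1 - cos(2 * pi * seq_len(n_k) / (n_k + 1)))
  k <- k / sum(k)
  sm <- stats::filter(w, k, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm) / max(sm) * shape$amplitude
  attr(sm, "peak_sample") <- which.max(sm)
  sm
}

#' Blink timing model
#'
#' Baseline blinking is a renewal process with inter-blink intervals uniform
#' on `base_interval_s` (spontaneous blinking every 3-5 s). Two modulations
#' structure the timing relative to an isochronous tone stream:
#' `kappa` concentrates blinks at a preferred phase of the 750-ms tone cycle
#' (raised-cosine multiplicative gain, `(1 - kappa) + kappa (1 +
#' cos(theta)) / 2`, so off-peak phases keep `1 - kappa` of the baseline
#' intensity), and `beta <= 0` log-linearly
#' suppresses blink intensity inside the pre-stimulus windows of potential
#' target positions 2, 3, 4 (factor `exp(beta * (position - 2))`), emulating
#' hazard-rate oculomotor inhibition.
#'
#' @param base_interval_s Length-2 range of baseline inter-blink intervals
#'   in seconds (default `c(3, 5)`).
#' @param kappa Entrainment strength in `[0, 1]`; 0 = no phase preference.
#' @param beta Per-position log-decrement (<= 0) of pre-stimulus blink
#'   intensity across positions 2 -> 3 -> 4.
#' @param prestim_window_ms Pre-stimulus suppression window length (ms).
#' @param phase_peak Preferred phase of the tone cycle in `[0, 1)`.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `timing_model`.
#' @export
timing_model <- function(base_interval_s = c(3, 5), kappa = 0, beta = 0,
                         prestim_window_ms = 300, phase_peak = 0.5,
                         seed = NULL) {
  stopifnot(length(base_interval_s) == 2, base_interval_s[1] > 0,
            base_interval_s[2] >= base_interval_s[1],
            kappa >= 0, kappa <= 1, beta <= 0, prestim_window_ms > 0)
  structure(list(base_interval_s = base_interval_s, kappa = kappa,
                 beta = beta, prestim_window_ms = prestim_window_ms,
                 phase_peak = phase_peak, seed = seed),
            class = "timing_model")
}

# Multiplicative modulation gain in (0, 1] at time t (ms) under a protocol.
# Exposed internally for thinning; vectorized over t.
timing_gain <- function(t, model, soa_ms, prestim_tbl) {
  phase <- (t %% soa_ms) / soa_ms
  # raised-cosine mixture: gain in [1 - kappa, 1], linear in kappa, so
  # entrainment never fully silences off-peak phases at moderate kappa
  g <- (1 - model$kappa) +
    model$kappa * (1 + cos(2 * pi * (phase - model$phase_peak))) / 2
  if (model$beta < 0 && nrow(prestim_tbl)) {
    idx <- findInterval(t, prestim_tbl$lo)
    hit <- idx >= 1L & t < prestim_tbl$hi[pmax(idx, 1L)]
    g[hit] <- g[hit] * exp(model$beta * (prestim_tbl$position[idx[hit]] - 2))
  }
  if (any(!is.finite(g))) stop("non-finite intensity gain")
  g
}

# Pre-stimulus windows [onset - w, onset) of positions 2-4 for all sequences.
prestim_windows <- function(protocol, window_ms) {
  tones <- dplyr::filter(protocol, .data$position %in% 2:4)
  tibble::tibble(lo = tones$onset_ms - window_ms, hi = tones$onset_ms,
                 position = tones$position)
}

#' Sample blink peak times under a timing model
#'
#' Renewal proposals (intervals uniform on `base_interval_s`) thinned by the
#' phase/suppression gain: a proposed blink at time `t` is accepted with
#' probability `gain(t) <= 1`; rejected proposals are redrawn from the same
#' origin (Lewis-Shedler-style thinning of a bounded intensity). With
#' `kappa = 0` and `beta = 0` every proposal is accepted and the process is
#' the pure renewal process.
#'
#' @param model A [timing_model()].
#' @param protocol A [generate_protocol()] result; defines the tone cycle,
#'   the pre-stimulus windows, and the recording duration.
#' @return Tibble with `time_ms` (blink peak times) and `phase` (position in
#'   the tone cycle, `[0, 1)`).
#' @export
sample_blink_times <- function(model, protocol) {
  if (!nrow(protocol)) stop("protocol is empty")
  soa <- attr(protocol, "soa_ms") %||% 750
  dur_ms <- max(protocol$onset_ms) + soa
  if (!is.null(model$seed)) set.seed(model$seed)
  pres <- prestim_windows(protocol, model$prestim_window_ms)
  lo <- model$base_interval_s[1] * 1000
  hi <- model$base_interval_s[2] * 1000
  times <- numeric(ceiling(dur_ms / lo) + 16L)
  n <- 0L
  t <- 0
  max_prop <- 2000 * ceiling(dur_ms / lo + 1)
  prop <- 0L
  repeat {
    tc <- t + runif(1, lo, hi)
    prop <- prop + 1L
    if (tc >= dur_ms || prop > max_prop) break
    if (runif(1) <= timing_gain(tc, model, soa, pres)) {
      t <- tc
      n <- n + 1L
      times[n] <- tc
    }
  }
  tibble::tibble(time_ms = times[seq_len(n)],
                 phase = (times[seq_len(n)] %% soa) / soa)
}

#' Render a continuous multichannel recording from ground-truth events
#'
#' Adds the stereotyped blink waveform at each blink peak time with
#' channel-appropriate polarity and gain (opposite signs above/below the eye,
#' attenuated on frontal electrodes, small crosstalk on lateral channels),
#' renders saccades as step displacements with exponential settling on the
#' lateral channels, and superimposes additive Gaussian noise.
#'
#' @param blinks Tibble with `time_ms` (peak times) and optionally
#'   `amplitude`; or a numeric vector of peak times.
#' @param saccades Optional tibble with `onset_ms`, `duration_ms`,
#'   `amplitude` (sign = direction).
#' @param shape A [blink_shape()].
#' @param noise_sd Additive white Gaussian noise SD (channel-relative units).
#' @param fs Sampling rate (Hz).
#' @param duration_s Recording duration in seconds.
#' @param seed Integer seed for the noise, or `NULL`.
#' @return A list of class `eog_recording`: `signal` (tibble: `time_s` plus
#'   one column per channel), `fs`, and `ground_truth` (list of `blinks` and
#'   `saccades` tibbles; one log entry per rendered waveform).
#' @export
render_recording <- function(blinks, saccades = NULL, shape = blink_shape(),
                             noise_sd = 0.10, fs = 500, duration_s,
                             seed = NULL) {
  if (is.numeric(blinks)) blinks <- tibble::tibble(time_ms = blinks)
  if (!"amplitude" %in% names(blinks))
    blinks$amplitude <- rep(shape$amplitude, nrow(blinks))
  n <- round(duration_s * fs)
  if (nrow(blinks) && any(blinks$time_ms < 0 | blinks$time_ms >= duration_s * 1000))
    stop("blink times outside recording duration")
  if (nrow(blinks) > 1 && any(diff(sort(blinks$time_ms)) < 422))
    warning("blinks closer than 422 ms (below the physiological IBI range)")
  if (!is.null(seed)) set.seed(seed)

  gains <- c(upperV = 1, lowerV = -0.8, Fp1 = 0.6, Fp2 = 0.6, Fz = 0.35,
             F3 = 0.3, F4 = 0.3, leftLateral = 0.05, rightLateral = 0.05)
  tpl <- blink_template(shape, fs)
  pk <- attr(tpl, "peak_sample")

  base <- numeric(n)
  for (i in seq_len(nrow(blinks))) {
    ctr <- round(blinks$time_ms[i] / 1000 * fs) + 1L
    idx <- (ctr - pk + 1L):(ctr - pk + length(tpl))
    ok <- idx >= 1L & idx <= n
    base[idx[ok]] <- base[idx[ok]] +
      tpl[ok] * (blinks$amplitude[i] / shape$amplitude)
  }

  sacc_trace <- numeric(n)
  if (!is.null(saccades) && nrow(saccades)) {
    if (!"amplitude" %in% names(saccades)) saccades$amplitude <- 0.5
    for (i in seq_len(nrow(saccades))) {
      on <- round(saccades$onset_ms[i] / 1000 * fs) + 1L
      len <- max(2L, round(saccades$duration_ms[i] / 1000 * fs))
      hold <- round(0.2 * fs)  # fixation displacement persists briefly
      idx <- on:min(n, on + len + hold)
      prof <- c(seq(0, 1, length.out = len),
                exp(-(seq_len(length(idx) - len)) / (0.05 * fs)))
      sacc_trace[idx] <- sacc_trace[idx] + saccades$amplitude[i] * prof[seq_along(idx)]
    }
  }

  sig <- lapply(names(gains), function(ch) {
    x <- base * gains[[ch]]
    if (ch == "leftLateral") x <- x + sacc_trace
    if (ch == "rightLateral") x <- x - sacc_trace
    x + rnorm(n, 0, noise_sd)
  })
  names(sig) <- names(gains)
  signal_tbl <- tibble::as_tibble(c(list(time_s = (seq_len(n) - 1) / fs), sig))
  structure(list(signal = signal_tbl, fs = fs,
                 ground_truth = list(blinks = blinks,
                                     saccades = saccades %||%
                                       tibble::tibble(onset_ms = numeric(),
                                                      duration_ms = numeric(),
                                                      amplitude = numeric()))),
            class = "eog_recording")
}

#' @export
print.eog_recording <- function(x, ...) {
  cat("<eog_recording> ", nrow(x$signal), " samples @ ", x$fs, " Hz, ",
      ncol(x$signal) - 1L, " channels, ",
      nrow(x$ground_truth$blinks), " ground-truth blinks\n", sep = "")
  invisible(x)
}

#' Group presets for synthetic cohorts
#'
#' The control-like preset follows baseline physiology (blink every 3-5 s)
#' with clear entrainment; the patient-like preset blinks less often and
#' entrains more weakly, with more variable saccade behavior. Both presets
#' carry the same pre-stimulus suppression by default, mirroring a
#' hazard-rate effect present in both groups. Patient-like waveform changes
#' are not clinically calibrated; the presets are configurable conditions
#' for the simulation, not clinical claims.
#'
#' @param group `"hc"` or `"pd"`.
#' @return A named list of [timing_model()] arguments plus `saccade_rate_hz`
#'   and `saccade_rate_cv` used by [generate_cohort()].
#' @export
group_preset <- function(group = c("hc", "pd")) {
  group <- match.arg(group)
  if (group == "hc") {
    list(base_interval_s = c(3, 5), kappa = 0.6, beta = -0.8,
         saccade_rate_hz = 0.1, saccade_rate_cv = 0.2)
  } else {
    list(base_interval_s = c(3.5, 6.5), kappa = 0.3, beta = -0.8,
         saccade_rate_hz = 0.1, saccade_rate_cv = 0.6)
  }
}

#' Generate a two-group cohort of ground-truth blink event logs
#'
#' Draws `n_per_group` participants per group with independent,
#' reproducibly derived child seeds, samples each participant's blink peak
#' times under the group's timing model, and (optionally) renders the
#' continuous recordings. Participants are age- and pair-matched across
#' groups.
#'
#' @param n_per_group Participants per group (default 15).
#' @param protocol A [generate_protocol()] result.
#' @param seed Master seed; the whole cohort is deterministic given it.
#' @param overrides Named list `list(hc = list(...), pd = list(...))` of
#'   [group_preset()] overrides.
#' @param render If `TRUE`, also renders an `eog_recording` per participant
#'   (list-column `recording`); memory-heavy, default `FALSE`.
#' @param noise_sd,shape Rendering options, see [render_recording()].
#' @return Tibble with one row per participant: `id`, `group`, `pair`,
#'   `age`, `n_blinks`, `blinks` (list-column of tibbles), and `recording`
#'   if requested.
#' @export
generate_cohort <- function(n_per_group = 15, protocol, seed = 1L,
                            overrides = list(), render = FALSE,
                            noise_sd = 0.10, shape = blink_shape()) {
  stopifnot(n_per_group >= 1)
  set.seed(seed)
  ages <- round(runif(n_per_group, 50, 78))
  rows <- list()
  for (g in c("hc", "pd")) {
    preset <- utils::modifyList(group_preset(g), overrides[[g]] %||% list())
    for (i in seq_len(n_per_group)) {
      sd_i <- child_seed(seed, i + if (g == "pd") n_per_group else 0L)
      tm <- timing_model(base_interval_s = preset$base_interval_s,
                         kappa = preset$kappa, beta = preset$beta,
                         seed = sd_i)
      bl <- sample_blink_times(tm, protocol)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("%s%02d", g, i), group = g, pair = i, age = ages[i],
        n_blinks = nrow(bl), blinks = list(bl))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (render) {
    dur_s <- (max(protocol$onset_ms) + (attr(protocol, "soa_ms") %||% 750)) / 1000
    out$recording <- purrr::map2(out$blinks, seq_len(nrow(out)), function(b, j) {
      render_recording(b, shape = shape, noise_sd = noise_sd,
                       duration_s = dur_s, seed = child_seed(seed, 10000 + j))
    })
  }
  out
}

#' Write / read a recording as delimited text
#'
#' Compact TSV interchange format: a `time_s` column plus one column per
#' channel.
#'
#' @param recording An `eog_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eog_recording` (without ground truth).
#' @export
write_recording <- function(recording, path) {
  utils::write.table(as.data.frame(recording$signal), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(signal = df, fs = round(fs),
                 ground_truth = list(blinks = tibble::tibble(time_ms = numeric()),
                                     saccades = tibble::tibble())),
            class = "eog_recording")
}
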