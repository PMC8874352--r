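#' Exclude blink-count outliers, with matched-pair removal
#'
#' Formalizes outlier screening on blink counts: a participant whose count
#' lies more than `k_iqr` interquartile ranges above their group's upper
#' quartile is excluded, together with their gender/age-matched partner in
#' the other group when `paired = TRUE`.
#'
#' @param records Tibble with at least `id`, `group`, `blink_count`, and
#'   `pair` (pair id) when paired removal is requested.
#' @param k_iqr IQR multiplier (default 3).
#' @param paired Remove the matched partner too (default `TRUE`).
#' @return `records` with logical `excluded` and character `exclusion_reason`
#'   columns.
#' @export
outlier_exclusion <- function(records, k_iqr = 3, paired = TRUE) {
  if (paired && !"pair" %in% names(records))
    stop("paired removal requested but no 'pair' column present")
  rec <- dplyr::group_by(records, .data$group)
  rec <- dplyr::mutate(rec,
    .upper = stats::quantile(.data$blink_count, 0.75) +
      k_iqr * stats::IQR(.data$blink_count))
  rec <- dplyr::ungroup(rec)
  out_flag <- rec$blink_count > rec$.upper
  reason <- ifelse(out_flag, "blink-count outlier", NA_character_)
  if (paired && any(out_flag)) {
    partner <- records$pair %in% records$pair[out_flag] & !out_flag
    reason[partner] <- "matched partner of excluded outlier"
    out_flag <- out_flag | partner
  }
  dplyr::mutate(dplyr::select(rec, -".upper"),
                excluded = out_flag, exclusion_reason = reason)
}

#' Cohort-level blink comparisons
#'
#' One-sided Wilcoxon rank-sum tests of total blink counts (group A assumed
#' higher) and of median inter-blink intervals (group A assumed shorter);
#' bisquare robust regression of group B counts on group A counts, pair by
#' pair; Spearman correlation of pair-mean counts with age; and a
#' Kolmogorov-Smirnov normality screen of the counts motivating the
#' non-parametric tests.
#'
#' @param records Tibble with `id`, `group` (two levels; the first sorted
#'   level is "group A"), `pair`, `age`, `blink_count`, `median_ibi_ms`.
#' @param conventional_r Use `Z / sqrt(n)` effect sizes instead of the
#'   rank-sum `Z / (n1 + n2)`.
#' @return A list of class `cohort_report`: `rank_tests` (tibble),
#'   `pair_regression` (tibble or `NULL` when pairing is absent),
#'   `age_correlation`, `normality`.
#' @export
cohort_tests <- function(records, conventional_r = FALSE) {
  groups <- sort(unique(records$group))
  if (length(groups) != 2) stop("records must contain exactly two groups")
  a <- dplyr::filter(records, .data$group == groups[1])
  b <- dplyr::filter(records, .data$group == groups[2])
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 participants per group")

  rank_test <- function(what, xa, xb, alternative) {
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = alternative))
    z <- rank_sum_z(unname(wt$statistic), length(xa), length(xb))
    n <- length(xa) + length(xb)
    tibble::tibble(what = what, alternative = alternative,
                   median_a = median(xa), median_b = median(xb),
                   statistic = unname(wt$statistic), z = z, p = wt$p.value,
                   r = if (conventional_r) z / sqrt(n) else z / n)
  }
  rank_tests <- dplyr::bind_rows(
    rank_test("blink_count", a$blink_count, b$blink_count, "greater"),
    rank_test("median_ibi_ms", a$median_ibi_ms, b$median_ibi_ms, "less"))

  pair_regression <- NULL
  if ("pair" %in% names(records) &&
      all(sort(a$pair) == sort(b$pair))) {
    a_ord <- dplyr::arrange(a, .data$pair)
    b_ord <- dplyr::arrange(b, .data$pair)
    fit <- MASS::rlm(b_ord$blink_count ~ a_ord$blink_count,
                     psi = MASS::psi.bisquare, maxit = 100)
    cf <- summary(fit)$coefficients
    tval <- cf[2, "t value"]
    df <- nrow(a_ord) - 2
    pair_regression <- tibble::tibble(
      slope = cf[2, "Value"], se = cf[2, "Std. Error"], t = tval, df = df,
      p = 2 * pt(abs(tval), df, lower.tail = FALSE))
  } else {
    warning("pairing absent or unmatched: pair regression skipped")
  }

  pair_means <- dplyr::summarise(
    dplyr::group_by(records, .data$pair),
    mean_count = mean(.data$blink_count), age = .data$age[1],
    .groups = "drop")
  ct <- suppressWarnings(stats::cor.test(pair_means$mean_count,
                                         pair_means$age, method = "spearman"))
  age_correlation <- tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                                    n = nrow(pair_means))

  counts <- records$blink_count
  ks <- suppressWarnings(stats::ks.test(scale(counts), "pnorm"))
  normality <- tibble::tibble(what = "blink_count",
                              statistic = unname(ks$statistic), p = ks$p.value)

  structure(list(rank_tests = rank_tests, pair_regression = pair_regression,
                 age_correlation = age_correlation, normality = normality,
                 groups = groups),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> groups:", paste(x$groups, collapse = " vs "), "\n")
  print(x$rank_tests)
  if (!is.null(x$pair_regression)) {
    cat("\nPaired robust regression (B ~ A):\n"); print(x$pair_regression)
  }
  cat("\nAge correlation (Spearman):\n"); print(x$age_correlation)
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_per_group Participants per group.
#' @param n_sequences,n_target_sequences,soa_ms Protocol design.
#' @param n_boot Distance-test randomizations.
#' @param n_perm Cluster-test permutations.
#' @param overrides Group timing-model overrides (see [generate_cohort()]).
#' @return Named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = tempfile("blinkhazard_"), seed = 1L,
                            n_per_group = 15, n_sequences = 240,
                            n_target_sequences = 60, soa_ms = 750,
                            n_boot = 1000, n_perm = 1000,
                            overrides = list()) {
  list(out_dir = out_dir, seed = seed, n_per_group = n_per_group,
       n_sequences = n_sequences, n_target_sequences = n_target_sequences,
       soa_ms = soa_ms, n_boot = n_boot, n_perm = n_perm,
       overrides = overrides)
}

#' Run the full two-cohort analysis pipeline
#'
#' End-to-end, reproducible from a single master seed: generates the
#' protocol and a two-group synthetic cohort (event-level ground-truth
#' catalogs), epochs the non-target sequences, computes per-participant
#' spectra and latency histograms, fits the five-Gaussian description of
#' each group's median distribution, runs the chi-square distance bootstrap,
#' the per-interval peak tests, the peri-stimulus robust-slope cluster
#' permutation test per group, and the cohort-level comparisons, writing
#' TSV/JSON artifacts and a manifest to `out_dir`.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file with
#'   the same fields.
#' @return Invisibly, a list with the in-memory results (`protocol`,
#'   `cohort`, `records`, `spectra_stats`, `fits`, `distance_test`,
#'   `interval_tests`, `clusters`, `cohort_report`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  protocol <- generate_protocol(cfg$n_sequences, cfg$n_target_sequences,
                                cfg$soa_ms, seed = cfg$seed)
  write_protocol(protocol, file.path(cfg$out_dir, "events.tsv"))

  cohort <- generate_cohort(cfg$n_per_group, protocol, seed = cfg$seed,
                            overrides = cfg$overrides)

  epoch_sets <- purrr::map(cohort$blinks, function(b) {
    extract_epochs(b$time_ms, protocol)
  })
  dists <- purrr::map(epoch_sets, bin_and_smooth)
  spectra <- purrr::map(epoch_sets, function(ep) {
    fft_power(concatenate_epochs(ep))
  })

  records <- dplyr::mutate(
    dplyr::select(cohort, "id", "group", "pair", "age"),
    blink_count = purrr::map_int(cohort$blinks, nrow),
    median_ibi_ms = purrr::map_dbl(cohort$blinks, function(b) {
      if (nrow(b) > 1) median(diff(b$time_ms)) else NA_real_
    }),
    n_epoch_blinks = purrr::map_int(epoch_sets, function(e) e$n_blinks))
  records <- outlier_exclusion(records)
  keep <- !records$excluded
  ia <- which(keep & records$group == "hc")
  ib <- which(keep & records$group == "pd")

  blinks_tbl <- dplyr::bind_rows(purrr::map2(cohort$blinks, cohort$id,
    function(b, id) dplyr::mutate(b, id = id)))
  utils::write.table(as.data.frame(blinks_tbl),
                     file.path(cfg$out_dir, "blinks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hist_tbl <- dplyr::bind_rows(purrr::map2(dists, cohort$id, function(d, id) {
    dplyr::mutate(tibble::as_tibble(d), id = id)
  }))
  utils::write.table(as.data.frame(hist_tbl),
                     file.path(cfg$out_dir, "histograms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  spectra_stats <- entrainment_stats(spectra[ia], spectra[ib])

  med_a <- group_median_distribution(dists[ia])
  med_b <- group_median_distribution(dists[ib])
  fit_a <- fit_five_gaussians(med_a)
  fit_b <- fit_five_gaussians(med_b)
  fits_tbl <- dplyr::bind_rows(
    dplyr::mutate(fit_a$components, group = "hc"),
    dplyr::mutate(fit_b$components, group = "pd"))
  utils::write.table(as.data.frame(fits_tbl),
                     file.path(cfg$out_dir, "gaussian_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dist_test <- bootstrap_distance_test(dists[ia], dists[ib],
                                       n_boot = cfg$n_boot,
                                       seed = child_seed(cfg$seed, 1))
  interval_tests <- per_interval_peak_tests(dists[ia], dists[ib], fit_a,
                                            soa_ms = cfg$soa_ms)

  clusters <- purrr::map(list(hc = ia, pd = ib), function(idx) {
    cs <- cohort_slopes(epoch_sets[idx])
    cluster_permutation_test(cs$slopes, n_perm = cfg$n_perm,
                             seed = child_seed(cfg$seed, 2),
                             rel_lo_ms = cs$rel_lo_ms)
  })

  report <- cohort_tests(records[keep, ])

  json_out <- list(
    distance_test = list(distance = dist_test$distance, p = dist_test$p,
                         n_boot = dist_test$n_boot),
    interval_tests = interval_tests,
    clusters = purrr::map(clusters, function(cl) {
      list(t_crit = cl$t_crit, n_perm = cl$n_perm,
           clusters = cl$clusters, bins = cl$bins)
    }),
    entrainment = spectra_stats,
    rank_tests = report$rank_tests,
    pair_regression = report$pair_regression,
    age_correlation = report$age_correlation,
    normality = report$normality,
    exclusions = dplyr::filter(records, .data$excluded))
  jsonlite::write_json(json_out, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "blinkhazard",
    version = as.character(utils::packageVersion("blinkhazard")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_excluded = sum(records$excluded),
    excluded = records$id[records$excluded],
    exclusion_reasons = records$exclusion_reason[records$excluded],
    file_md5 = as.list(tools::md5sum(
      sort(list.files(cfg$out_dir, pattern = "\\.(tsv|json)$",
                      full.names = TRUE)))))
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(protocol = protocol, cohort = cohort, records = records,
                 spectra_stats = spectra_stats,
                 fits = list(hc = fit_a, pd = fit_b),
                 distance_test = dist_test, interval_tests = interval_tests,
                 clusters = clusters, cohort_report = report,
                 manifest = manifest))
}
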