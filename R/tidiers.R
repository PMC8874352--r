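#' Tidy a five-Gaussian fit
#'
#' @param x A `gauss5_fit`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `mean`, `sigma`,
#'   `amplitude`.
#' @export
tidy.gauss5_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = "mean")
}

#' @rdname tidy.gauss5_fit
#' @return `glance()`: one-row tibble with `iterations`, `mean_residual`,
#'   `converged`.
#' @export
glance.gauss5_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, mean_residual = x$mean_residual,
                 converged = x$converged)
}

#' Tidy a cluster permutation test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return Tibble of clusters (`start`, `end`, `start_ms`, `end_ms`,
#'   `mass`, `p`).
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @rdname tidy.cluster_test
#' @return `glance()`: one-row tibble with `n_clusters`, `min_p`, `t_crit`,
#'   `n_perm`, `exhaustive`, `method`.
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
                 t_crit = x$t_crit, n_perm = x$n_perm,
                 exhaustive = x$exhaustive, method = x$method)
}

#' Tidy a chi-square distance test
#'
#' @param x A `dist_test`.
#' @param ... Unused.
#' @return One-row tibble with `distance`, `p`, `n_boot`.
#' @export
glance.dist_test <- function(x, ...) {
  tibble::tibble(distance = x$distance, p = x$p, n_boot = x$n_boot)
}

#' @rdname glance.dist_test
#' @export
tidy.dist_test <- function(x, ...) glance.dist_test(x)

#' Tidy a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return The stacked rank tests with the regression, age-correlation and
#'   normality rows appended (`what`, `statistic`, `p`, plus test-specific
#'   columns).
#' @export
tidy.cohort_report <- function(x, ...) {
  out <- dplyr::mutate(x$rank_tests, test = "rank_sum")
  if (!is.null(x$pair_regression)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(
      x$pair_regression, what = "pair_regression", test = "robust_regression",
      statistic = .data$t))
  }
  out <- dplyr::bind_rows(
    out,
    dplyr::mutate(x$age_correlation, what = "age_correlation",
                  test = "spearman", statistic = .data$rho),
    dplyr::mutate(x$normality, test = "kolmogorov_smirnov"))
  dplyr::relocate(out, "what", "test")
}
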