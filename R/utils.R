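#' @importFrom rlang .data %||%
#' @importFrom stats median mad sd fft qt pt qnorm rnorm runif
#' @importFrom generics tidy glance
#' @importFrom mclust Mclust mclustBIC predict.Mclust
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Column medians of a numeric matrix; midpoint-average convention for even n.
col_medians <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(as.numeric(m[1L, ]))
  sorted <- matrix(m[order(col(m), m)], nrow = n)
  if (n %% 2L == 1L) {
    sorted[(n + 1L) %/% 2L, ]
  } else {
    (sorted[n %/% 2L, ] + sorted[n %/% 2L + 1L, ]) / 2
  }
}

# Normal-approximation Z for a Wilcoxon signed-rank statistic V on n pairs.
signed_rank_z <- function(v, n) {
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  (v - mu) / sigma
}

# Normal-approximation Z for a Mann-Whitney W (R's wilcox.test statistic).
rank_sum_z <- function(w, n1, n2) {
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  (w - mu) / sigma
}

# Derive a bounded child seed from a master seed and an index.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 9973) %% 2147483587)
}
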