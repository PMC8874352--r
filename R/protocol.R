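#' Generate a five-tone target-detection protocol
#'
#' Builds the ordered tone stream of an isochronous auditory target-detection
#' experiment: continuously repeating five-tone sequences of four standards
#' (440 Hz) followed by a sequence-final non-target deviant (494 Hz), with a
#' rare target (349 Hz) replacing the standard at position 2, 3 or 4 in a
#' subset of sequences. Target-containing sequences are separated by at least
#' two target-free sequences, and target positions are balanced across 2/3/4.
#'
#' With the defaults (240 sequences, 60 targets) the stream contains 900
#' standards (75% of tones), 240 deviants (20%) and 60 targets (5%), i.e. 20
#' targets per position.
#'
#' @param n_sequences Number of five-tone sequences (default 240).
#' @param n_target_sequences Number of sequences containing a target
#'   (default 60). Must satisfy `3 * n_target_sequences - 2 <= n_sequences`
#'   for the spacing constraint to be feasible.
#' @param soa_ms Stimulus onset asynchrony between successive tones in ms
#'   (default 750).
#' @param seed Integer seed; the protocol is deterministic given the seed.
#' @return A tibble of class `blink_protocol` with one row per tone:
#'   `onset_ms`, `pitch_hz`, `role` (standard/deviant/target),
#'   `sequence_index` (0-based), `position` (1-5), `block` (1-3, contiguous
#'   thirds of the sequence list). Attributes: `soa_ms`, `n_sequences`,
#'   `n_target_sequences`, `seed`.
#' @examples
#' p <- generate_protocol(240, 60, 750, seed = 1)
#' table(p$role)
#' @export
generate_protocol <- function(n_sequences = 240, n_target_sequences = 60,
                              soa_ms = 750, seed = 1L) {
  stopifnot(n_sequences >= 1, n_target_sequences >= 0,
            n_target_sequences <= n_sequences, soa_ms > 0)
  n <- as.integer(n_sequences)
  k <- as.integer(n_target_sequences)
  if (k > 0 && 3L * k - 2L > n) {
    stop("spacing constraint infeasible: need n_sequences >= 3 * n_target_sequences - 2 (",
         3L * k - 2L, " > ", n, ")")
  }
  set.seed(seed)

  # Uniform draw over target placements with >= 2 clean sequences between
  # consecutive target sequences: positions p_i (1-based) with p_{i+1} >= p_i + 3
  # biject onto strictly increasing r_i in 1..(n - 2k + 2) via p_i = r_i + 2(i-1).
  if (k > 0) {
    r <- sort(sample.int(n - 2L * k + 2L, k))
    target_seqs <- r + 2L * (seq_len(k) - 1L)
  } else {
    target_seqs <- integer(0)
  }

  # Balanced assignment of target positions 2/3/4.
  if (k > 0) {
    base <- k %/% 3L
    rem <- k %% 3L
    pos_pool <- rep(2:4, times = base)
    if (rem > 0) {
      warning("n_target_sequences not divisible by 3; using maximal positional balance")
      pos_pool <- c(pos_pool, sample(2:4, rem))
    }
    target_pos <- sample(pos_pool, k)
  } else {
    target_pos <- integer(0)
  }

  seq_idx <- rep(0:(n - 1L), each = 5L)
  position <- rep(1:5, times = n)
  role <- rep("standard", 5L * n)
  role[position == 5L] <- "deviant"
  if (k > 0) {
    tgt_rows <- (target_seqs - 1L) * 5L + target_pos
    role[tgt_rows] <- "target"
  }
  pitch <- c(standard = 440, deviant = 494, target = 349)[role]

  # Blocks are contiguous thirds of the sequence list.
  block_of_seq <- as.integer(cut(0:(n - 1L),
                                 breaks = round(seq(0, n, length.out = 4)) - 0.5,
                                 labels = FALSE))

  out <- tibble::tibble(
    onset_ms = (seq_along(role) - 1) * soa_ms,
    pitch_hz = unname(pitch),
    role = role,
    sequence_index = seq_idx,
    position = position,
    block = block_of_seq[seq_idx + 1L]
  )
  class(out) <- c("blink_protocol", class(out))
  attr(out, "soa_ms") <- soa_ms
  attr(out, "n_sequences") <- n
  attr(out, "n_target_sequences") <- k
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Hazard-rate model of target probability over positions
#'
#' Given the probability mass `f` of target occurrence over the potential
#' target positions, computes the cumulative mass `F`, the survival
#' probability `1 - F` evaluated before each position, and the hazard
#' `h = f / (1 - F_before)`: the conditional probability that the target
#' occurs at a position given it has not occurred earlier. For equiprobable
#' placement over three positions, `h = (1/3, 1/2, 1)`.
#'
#' @param f Non-negative probability mass over positions, summing to 1.
#' @param positions Position labels (default `2:4`).
#' @return A tibble of class `hazard_table`: `position`, `f`, `F`
#'   (cumulative), `survival` (before the position), `h`. Hazard is `NA`
#'   where survival is 0 and `f` is 0 (no mass can remain there).
#' @examples
#' hazard(c(1, 1, 1) / 3)
#' @export
hazard <- function(f, positions = seq(2, length.out = length(f))) {
  if (any(f < 0)) stop("f must be non-negative")
  if (abs(sum(f) - 1) > 1e-8) stop("f must sum to 1")
  if (length(positions) != length(f)) stop("positions and f lengths differ")
  Fc <- cumsum(f)
  surv <- c(1, 1 - Fc[-length(Fc)])
  if (any(surv <= 1e-12 & f > 1e-12)) {
    stop("impossible mass: positive f at a position with zero survival")
  }
  h <- ifelse(surv > 1e-12, f / surv, NA_real_)
  out <- tibble::tibble(position = positions, f = f, F = Fc,
                        survival = surv, h = h)
  class(out) <- c("hazard_table", class(out))
  out
}

#' Validate a protocol against its design invariants
#'
#' Checks role counts, per-position target counts, the one-deviant /
#' at-most-one-target per sequence rules, target spacing (>= 2 target-free
#' sequences before each target sequence after the first), onset timing, and
#' global role probabilities. Violations are reported, never raised.
#'
#' @param protocol A `blink_protocol` tibble (or any tibble with the same
#'   columns).
#' @return A list of class `protocol_validation`: `violations` (tibble with
#'   `rule` and `detail`; zero rows for a valid protocol), `role_counts`,
#'   `target_position_counts`, `global_probabilities`.
#' @export
validate_protocol <- function(protocol) {
  p <- protocol
  soa <- attr(p, "soa_ms") %||% {
    d <- diff(sort(unique(p$onset_ms))); if (length(d)) min(d) else NA_real_
  }
  viol <- list()
  add <- function(rule, detail) viol[[length(viol) + 1L]] <<- tibble::tibble(rule = rule, detail = detail)

  per_seq <- dplyr::summarise(dplyr::group_by(p, .data$sequence_index),
                              n_deviant = sum(.data$role == "deviant"),
                              n_target = sum(.data$role == "target"),
                              .groups = "drop")
  bad_dev <- per_seq$sequence_index[per_seq$n_deviant != 1L]
  if (length(bad_dev)) add("one deviant per sequence",
                           paste("sequences:", paste(bad_dev, collapse = ",")))
  multi_t <- per_seq$sequence_index[per_seq$n_target > 1L]
  if (length(multi_t)) add("multiple targets in one sequence",
                           paste("sequences:", paste(multi_t, collapse = ",")))

  if (any(p$role[p$position == 5L] != "deviant"))
    add("position 5 must be deviant", "non-deviant role at position 5")
  if (any(!p$position[p$role == "target"] %in% 2:4))
    add("targets only at positions 2-4", "target outside positions 2-4")

  tseq <- sort(per_seq$sequence_index[per_seq$n_target >= 1L])
  if (length(tseq) > 1L) {
    gaps <- diff(tseq)
    if (any(gaps < 3L))
      add("spacing < 2 target-free sequences",
          paste("between sequences:",
                paste(tseq[which(gaps < 3L)], tseq[which(gaps < 3L) + 1L],
                      sep = "-", collapse = ",")))
  }

  if (!is.na(soa)) {
    expected <- (seq_len(nrow(p)) - 1) * soa
    if (any(abs(p$onset_ms - expected) > 1e-9))
      add("isochronous onsets", "onset_ms != tone index x SOA")
  }

  counts <- table(factor(p$role, levels = c("standard", "deviant", "target")))
  out <- list(
    violations = if (length(viol)) dplyr::bind_rows(viol)
                 else tibble::tibble(rule = character(), detail = character()),
    role_counts = tibble::tibble(role = names(counts), n = as.integer(counts)),
    target_position_counts = tibble::tibble(
      position = 2:4,
      n = vapply(2:4, function(q) sum(p$role == "target" & p$position == q), 1L)),
    global_probabilities = tibble::tibble(role = names(counts),
                                          probability = as.numeric(counts) / nrow(p))
  )
  class(out) <- "protocol_validation"
  out
}

#' @export
print.protocol_validation <- function(x, ...) {
  cat("Protocol validation:", nrow(x$violations), "violation(s)\n")
  if (nrow(x$violations)) print(x$violations)
  cat("\nRole counts:\n"); print(x$role_counts)
  cat("\nGlobal probabilities:\n"); print(x$global_probabilities)
  invisible(x)
}

#' Sequence onsets of a protocol
#'
#' @param protocol A `blink_protocol`.
#' @param targets_only If `TRUE`, restrict to target-containing sequences.
#' @return Tibble `sequence_index`, `onset_ms` (onset of the first tone),
#'   `has_target`.
#' @export
protocol_sequences <- function(protocol, targets_only = FALSE) {
  out <- dplyr::summarise(dplyr::group_by(protocol, .data$sequence_index),
                          onset_ms = min(.data$onset_ms),
                          has_target = any(.data$role == "target"),
                          .groups = "drop")
  if (targets_only) out <- dplyr::filter(out, .data$has_target)
  out
}

#' Write / read a protocol event table
#'
#' Tab-separated event table with columns `onset_ms`, `pitch_hz`, `role`,
#' `sequence_index`, `position`, `block`.
#'
#' @param protocol A `blink_protocol`.
#' @param path Output path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a `blink_protocol` tibble.
#' @export
write_protocol <- function(protocol, path) {
  utils::write.table(as.data.frame(protocol), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("blink_protocol", class(out))
  d <- diff(sort(unique(out$onset_ms)))
  attr(out, "soa_ms") <- if (length(d)) min(d) else NA_real_
  attr(out, "n_sequences") <- length(unique(out$sequence_index))
  attr(out, "n_target_sequences") <- sum(out$role == "target")
  out
}
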