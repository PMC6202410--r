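#' Frequency of a pair observable in a sequence
#'
#' Counts the composite observable \eqn{Y = (X_A, X_B; \ell)} by flattening
#' it to a single gapped pattern (see [pair_to_pattern()]) and counting with
#' [count_pattern()]. Exposed separately so the bulk scanner
#' ([scan_pairs()]) and the per-pattern path share one contract.
#'
#' @param seq A cleaned A/C/G/T sequence.
#' @param y A [pair_observable()].
#' @param convention Middle-gap convention, see [pair_to_pattern()].
#' @return A one-row tibble as from [count_pattern()].
#' @export
pair_frequency <- function(seq, y, convention = c("formula", "table1")) {
  convention <- match.arg(convention)
  count_pattern(seq, pair_to_pattern(y, convention))
}

#' Normalized cross-correlation z of a pair observable
#'
#' The joint frequency of \eqn{Y = (X_A, X_B; \ell)} normalized by the
#' expectation under independence:
#' \deqn{z_{[X_A,X_B]}(\ell) = \frac{P(X_A, X_B; \ell)}{P(X_A) P(X_B)}.}
#' \eqn{z = 1} means no correlation between the two patterns at that
#' separation; deviations from 1 are signatures of structure. Marginal
#' frequencies are computed over the whole sequence with their own window
#' counts.
#'
#' @inheritParams pair_frequency
#' @return A one-row tibble with columns `X_A`, `X_B`, `ell`, `convention`,
#'   `count`, `windows`, `P_joint`, `P_A`, `P_B`, `z`. `z` is `NA` when a
#'   marginal frequency is 0 or the composite has no windows.
#' @examples
#' z_score("GGACCGGCCACAGGAA", pair_observable("GG", "CC", 2))
#' @export
z_score <- function(seq, y, convention = c("formula", "table1")) {
  stopifnot(inherits(y, "pair_observable"))
  convention <- match.arg(convention)
  joint <- pair_frequency(seq, y, convention)
  pa <- count_pattern(seq, y$first)
  pb <- count_pattern(seq, y$second)
  denom <- pa$frequency * pb$frequency
  z <- if (is.na(joint$frequency) || is.na(denom) || denom == 0) NA_real_ else
    joint$frequency / denom
  tibble::tibble(
    X_A = format(y$first), X_B = format(y$second), ell = y$sep,
    convention = convention,
    count = joint$count, windows = joint$windows,
    P_joint = joint$frequency, P_A = pa$frequency, P_B = pb$frequency,
    z = z
  )
}

#' Dyadic scale grid
#'
#' Scales \eqn{\ell = 2^i} for the given exponents, the standard grid for
#' scanning separations from single bases to megabases.
#'
#' @param exponents Nonnegative integers, strictly increasing (default 0:24).
#' @return Numeric vector of scales.
#' @export
scale_grid <- function(exponents = 0:24) {
  stopifnot(all(exponents >= 0), !is.unsorted(exponents, strictly = TRUE))
  2^exponents
}

#' Scan all ordered dinucleotide pairs over a grid of scales
#'
#' For every ordered pair of dinucleotides \eqn{(X_A, X_B)} (256 pairs) and
#' every scale \eqn{\ell} in the grid, computes the joint count of
#' \eqn{Y = (X_A, X_B; \ell)}, the marginal dinucleotide frequencies, and the
#' normalized cross-correlation \eqn{z} (see [z_score()]). For each scale all
#' 256 joint counts come from a single pass over the sequence (a joint
#' histogram of position-wise dinucleotide codes), so scanning is linear in
#' sequence length per scale.
#'
#' Scales whose composite observable has fewer than `min_windows` windows in
#' the sequence are dropped with a message: \eqn{z} estimates from a handful
#' of windows are statistically meaningless.
#'
#' @param seq A cleaned A/C/G/T sequence.
#' @param scales Numeric vector of separation scales (default [scale_grid()]).
#' @param convention Middle-gap convention, see [pair_to_pattern()].
#' @param min_windows Minimum number of composite windows for a scale to be
#'   reported (default 1000).
#' @param label Optional sequence label carried into the output.
#' @return A tibble with columns `seq_label`, `X_A`, `X_B`, `ell`,
#'   `convention`, `count`, `windows`, `P_joint`, `P_A`, `P_B`, `z`
#'   (256 rows per retained scale).
#' @examples
#' g <- generate_genome(domain_model_config(macro_length = 2e4, seed = 1))
#' tab <- scan_pairs(g$sequence, scales = 2^(0:6))
#' @export
scan_pairs <- function(seq, scales = scale_grid(),
                       convention = c("formula", "table1"),
                       min_windows = 1000L, label = "seq") {
  convention <- match.arg(convention)
  if (length(scales) == 0L) stop("empty scale grid", call. = FALSE)
  stopifnot(all(scales >= 1))
  codes <- seq_to_codes(seq)
  n <- length(codes)
  if (n < 4L) stop("sequence too short to scan dinucleotide pairs", call. = FALSE)

  # dinucleotide code at each start position (1..n-1)
  di <- (codes[-n] - 1L) * 4L + codes[-1L]
  marg_counts <- tabulate(di, nbins = 16L)
  p_marg <- marg_counts / (n - 1)

  # middle gap between the two dinucleotides
  mid <- if (convention == "formula") scales else scales + 1
  lens <- mid + 3              # composite pattern size
  windows <- n - lens + 1
  keep <- windows >= min_windows
  if (!any(keep)) {
    stop("no scale has at least ", min_windows, " windows in this sequence",
         call. = FALSE)
  }
  if (any(!keep)) {
    message("dropping ", sum(!keep), " scale(s) with fewer than ", min_windows,
            " windows: ell = ", paste(scales[!keep], collapse = ", "))
  }

  purrr::map_dfr(which(keep), function(k) {
    np <- as.integer(windows[k])
    offset <- as.integer(mid[k] + 1)   # start of X_B relative to start of X_A
    a <- di[seq_len(np)]
    b <- di[seq_len(np) + offset]
    joint <- tabulate((a - 1L) * 16L + b, nbins = 256L)
    pj <- joint / np
    ia <- rep(seq_len(16L), each = 16L)
    ib <- rep(seq_len(16L), times = 16L)
    denom <- p_marg[ia] * p_marg[ib]
    tibble::tibble(
      seq_label = label,
      X_A = DINUCLEOTIDES[ia], X_B = DINUCLEOTIDES[ib],
      ell = scales[k], convention = convention,
      count = joint, windows = np,
      P_joint = pj, P_A = p_marg[ia], P_B = p_marg[ib],
      z = ifelse(denom > 0, pj / denom, NA_real_)
    )
  })
}
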