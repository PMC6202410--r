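# Closure structure of the 256 ordered dinucleotide pairs, cached per symmetry.
# The separation is carried opaquely (the algebra never alters it), so one
# closure table serves every scale.
.closure_cache <- new.env(parent = emptyenv())

#' @keywords internal
#' @noRd
dinuc_index <- function(x_a, x_b) {
  (match(x_a, DINUCLEOTIDES) - 1L) * 16L + match(x_b, DINUCLEOTIDES)
}

#' Closure membership for all 256 ordered dinucleotide pairs
#'
#' For each reference pair \eqn{(X_A, X_B)} (indexed
#' `(code(X_A)-1)*16 + code(X_B)` in the A,C,G,T dinucleotide order), the
#' indices of the members of its closure set under the given symmetry.
#' Closures of dinucleotide pairs never leave the set of dinucleotide pairs
#' (it is closed under reverse-complement and swap), which is asserted here.
#'
#' @param symmetry Symmetry name or generator words ([symmetry_generators()]).
#' @return A list of 256 integer vectors.
#' @export
dinuc_pair_closures <- function(symmetry) {
  key <- paste(symmetry_generators(symmetry), collapse = "+")
  if (!is.null(.closure_cache[[key]])) return(.closure_cache[[key]])
  out <- vector("list", 256L)
  for (ia in seq_len(16L)) {
    for (ib in seq_len(16L)) {
      y <- pair_observable(DINUCLEOTIDES[ia], DINUCLEOTIDES[ib], sep = 1L)
      cl <- closure(symmetry, y)
      mem <- vapply(cl, function(p) {
        a <- paste(p$first$symbols, collapse = "")
        b <- paste(p$second$symbols, collapse = "")
        stopifnot(a %in% DINUCLEOTIDES, b %in% DINUCLEOTIDES)
        dinuc_index(a, b)
      }, integer(1))
      out[[(ia - 1L) * 16L + ib]] <- mem
    }
  }
  .closure_cache[[key]] <- out
  out
}

#' Spread of z values at one scale
#'
#' The population (divide-by-n) standard deviation of the 256 z values at a
#' given scale, the normalization \eqn{\sigma(\ell)} used by the symmetry
#' distance. Undefined (`NA`) z values are excluded with a message.
#'
#' @param scan_tbl A scan table from [scan_pairs()] (one sequence).
#' @param ell A scale present in the table.
#' @return The standard deviation (a nonnegative scalar).
#' @export
sigma_at_scale <- function(scan_tbl, ell) {
  z <- scan_tbl$z[scan_tbl$ell == ell]
  if (length(z) == 0L) stop("scale ", ell, " not present in the scan table", call. = FALSE)
  n_na <- sum(is.na(z))
  if (n_na > 0L) {
    message(n_na, " undefined z value(s) excluded at ell = ", ell)
    z <- z[!is.na(z)]
  }
  if (length(z) < 2L) stop("need at least 2 defined z values at ell = ", ell, call. = FALSE)
  sqrt(mean((z - mean(z))^2))
}

#' Symmetry distance of one reference pair at one scale
#'
#' The mean, over the closure set \eqn{\mathcal S_S(Y_{ref})} of the reference
#' pair (which includes \eqn{Y_{ref}} itself, contributing 0), of the squared
#' difference between each member's z and the reference z, normalized by the
#' variance of z over all pairs:
#' \deqn{d_\ell(Y_{ref}; S) = \frac{1}{|\mathcal S_S|}
#'   \sum_{Y \in \mathcal S_S(Y_{ref})}
#'   \frac{[z_{[Y]}(\ell) - z_{[Y_{ref}]}(\ell)]^2}{\sigma^2(\ell)}.}
#'
#' @param y_ref A [pair_observable()] with dinucleotide components.
#' @param symmetry Symmetry name or generator words.
#' @param scan_tbl A scan table from [scan_pairs()] (one sequence).
#' @param ell Scale at which to evaluate (defaults to `y_ref$sep`).
#' @return A nonnegative scalar.
#' @export
symmetry_distance <- function(y_ref, symmetry, scan_tbl, ell = y_ref$sep) {
  stopifnot(inherits(y_ref, "pair_observable"))
  sig <- sigma_at_scale(scan_tbl, ell)
  if (sig == 0) stop("sigma is 0 at ell = ", ell, "; distance undefined", call. = FALSE)
  sub <- scan_tbl[scan_tbl$ell == ell, ]
  z <- rep(NA_real_, 256L)
  z[dinuc_index(sub$X_A, sub$X_B)] <- sub$z
  cl <- closure(symmetry, y_ref)
  idx <- vapply(cl, function(p) {
    dinuc_index(paste(p$first$symbols, collapse = ""),
                paste(p$second$symbols, collapse = ""))
  }, integer(1))
  if (anyNA(z[idx])) {
    missing <- vapply(cl[is.na(z[idx])], format, character(1))
    stop("z undefined for closure member(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref_idx <- dinuc_index(paste(y_ref$first$symbols, collapse = ""),
                         paste(y_ref$second$symbols, collapse = ""))
  mean((z[idx] - z[ref_idx])^2) / sig^2
}

#' Symmetry index curves I_S(l)
#'
#' The strength of each symmetry at each scale, averaged over the reference
#' set \eqn{\mathcal A} of all 256 ordered dinucleotide pairs:
#' \deqn{I_S(\ell) = \frac{1}{2|\mathcal A|}
#'   \sum_{Y_{ref} \in \mathcal A} d_\ell(Y_{ref}; S).}
#' \eqn{I_S(\ell) = 0} indicates full validity of the symmetry at that scale
#' (z identical within every closure set); large values indicate that z
#' varies within closures as much as across all pairs. Reference pairs whose
#' closure contains an undefined z are excluded (with a message) and
#' \eqn{|\mathcal A|} reduced accordingly.
#'
#' @param scan_tbl A scan table from [scan_pairs()]; may contain several
#'   sequences (`seq_label`) — curves are computed per sequence.
#' @param symmetries Character vector of symmetry names (default all four).
#' @param refs Integer indices (in 1..256, dinucleotide-pair code order) of
#'   the reference pairs to average over; default all 256. Restricting the
#'   reference set is useful e.g. for null calibrations over pairs with
#'   non-degenerate closures.
#' @return A tibble with columns `seq_label`, `symmetry`, `ell`, `I`,
#'   `sigma`, `n_ref`. `I` is `NA` where `sigma` is 0. `sigma` is always the
#'   spread over all defined z values, regardless of `refs`.
#' @examples
#' g <- generate_genome(domain_model_config(macro_length = 5e4, seed = 7))
#' curves <- index_curves(scan_pairs(g$sequence, scales = 2^(0:8)))
#' @export
index_curves <- function(scan_tbl, symmetries = c("S1", "S2", "S3", "S4"),
                         refs = seq_len(256L)) {
  stopifnot(all(refs %in% seq_len(256L)))
  # flattened closure membership per symmetry for vectorized evaluation
  prep <- lapply(symmetries, function(s) {
    cl <- dinuc_pair_closures(s)
    list(ref = rep(seq_len(256L), lengths(cl)),
         member = unlist(cl, use.names = FALSE),
         m = lengths(cl))
  })
  names(prep) <- symmetries
  # the full group S3 spans every closure, so it decides ref usability
  full_group <- dinuc_pair_closures("S3")
  fg_ref <- rep(seq_len(256L), lengths(full_group))
  fg_member <- unlist(full_group, use.names = FALSE)
  in_refs <- seq_len(256L) %in% refs

  # one z vector of length 256 per (seq_label, ell) group, as matrix columns
  grp <- dplyr::distinct(scan_tbl[, c("seq_label", "ell")])
  grp <- dplyr::arrange(grp, .data$seq_label, .data$ell)
  col <- match(paste(scan_tbl$seq_label, scan_tbl$ell),
               paste(grp$seq_label, grp$ell))
  ng <- nrow(grp)
  Z <- matrix(NA_real_, 256L, ng)
  Z[cbind(dinuc_index(scan_tbl$X_A, scan_tbl$X_B), col)] <- scan_tbl$z

  # a ref is usable only if z is defined on its whole symmetry orbit
  ok_ref <- matrix(in_refs, 256L, ng)
  if (anyNA(Z)) {
    na_orbit <- rowsum(is.na(Z)[fg_member, , drop = FALSE] + 0, fg_ref)
    ok_ref <- ok_ref & na_orbit == 0
    n_na <- colSums(na_orbit > 0 & in_refs)
    for (k in which(n_na > 0L)) {
      message(n_na[k], " reference pair(s) with undefined z excluded at ell = ",
              grp$ell[k])
    }
  }
  n_ok <- colSums(ok_ref)

  n_def <- colSums(!is.na(Z))
  zbar <- colMeans(Z, na.rm = TRUE)
  sig <- sqrt(colMeans(sweep(Z, 2L, zbar)^2, na.rm = TRUE))
  sig[n_def < 2L] <- NA_real_

  out <- purrr::map_dfr(symmetries, function(s) {
    p <- prep[[s]]
    diffsq <- (Z[p$member, , drop = FALSE] - Z[p$ref, , drop = FALSE])^2
    diffsq[is.na(diffsq)] <- 0        # excluded refs never contribute
    d_by_ref <- rowsum(diffsq, p$ref) / p$m
    i_val <- colSums(d_by_ref * ok_ref) / (2 * n_ok * sig^2)
    i_val[is.na(sig) | sig == 0 | n_ok == 0L] <- NA_real_
    tibble::tibble(seq_label = grp$seq_label, symmetry = s, ell = grp$ell,
                   I = i_val, sigma = sig, n_ref = n_ok)
  })
  dplyr::arrange(out, .data$seq_label, .data$symmetry, .data$ell)
}

#' Detect the characteristic scales L_D, L_S, L_M
#'
#' Reads the three characteristic scales off the symmetry-index curves using
#' a fixed presence threshold (a symmetry is "present" at a scale when
#' \eqn{0 \le I_S \le} `threshold`):
#' \describe{
#'   \item{L_D (domain scale)}{smallest grid scale at which S2 is present —
#'     pairs of curves merge into groups of four.}
#'   \item{L_S (cluster scale)}{smallest grid scale at which S3 is present —
#'     all curves coincide.}
#'   \item{L_M (macrostructure scale)}{smallest grid scale at which S1 has
#'     ceased to be present while S4 is present — Chargaff symmetry breaks
#'     across macrostructure boundaries.}
#' }
#' Estimates carry the grid resolution (one dyadic step) as their error; an
#' undetectable scale is reported absent with a reason, not an error.
#'
#' @param curves A tibble from [index_curves()].
#' @param threshold Presence cutoff for I_S (default 0.025).
#' @return A tibble with columns `seq_label`, `scale` (`"L_D"`, `"L_S"`,
#'   `"L_M"`), `value` (`NA` when absent), `present`, `reason`.
#' @export
detect_scales <- function(curves, threshold = 0.025) {
  stopifnot(threshold >= 0)
  first_scale <- function(sub, cond) {
    ells <- sort(unique(sub$ell))
    hit <- ells[vapply(ells, function(l) isTRUE(cond(sub, l)), logical(1))]
    if (length(hit) == 0L) NA_real_ else min(hit)
  }
  i_of <- function(sub, s, l) {
    v <- sub$I[sub$symmetry == s & sub$ell == l]
    if (length(v) == 0L) NA_real_ else v[[1L]]
  }
  curves |>
    dplyr::group_by(.data$seq_label) |>
    dplyr::group_modify(function(sub, grp) {
      ld <- first_scale(sub, function(sb, l) i_of(sb, "S2", l) <= threshold)
      ls <- first_scale(sub, function(sb, l) i_of(sb, "S3", l) <= threshold)
      lm <- first_scale(sub, function(sb, l) {
        i_of(sb, "S1", l) > threshold && i_of(sb, "S4", l) <= threshold
      })
      tibble::tibble(
        scale = c("L_D", "L_S", "L_M"),
        value = c(ld, ls, lm),
        present = !is.na(c(ld, ls, lm)),
        reason = dplyr::case_when(
          !is.na(c(ld, ls, lm)) ~ "detected",
          TRUE ~ c("S2 never present on the grid",
                   "S3 never present on the grid",
                   "no scale with S1 absent and S4 present")
        )
      )
    }) |>
    dplyr::ungroup()
}

#' Normalized heatmap intensities of the symmetry index
#'
#' Per sequence, rescales the symmetry-index values to a 0-1 intensity for
#' heatmap display: with \eqn{I_{min}} the minimum index in the sequence,
#' values at or below \eqn{1.05 I_{min}} map to full intensity 1, values at
#' or above \eqn{6.5 I_{min}} map to 0, linear in between. When
#' \eqn{I_{min} = 0} the limit rule applies (intensity 1 exactly where
#' \eqn{I = 0}, else 0) and a message is emitted.
#'
#' @param curves A tibble from [index_curves()] (one or more sequences).
#' @return The input with columns `I_min` and `intensity` added.
#' @export
heatmap_table <- function(curves) {
  curves |>
    dplyr::group_by(.data$seq_label) |>
    dplyr::group_modify(function(sub, grp) {
      imin <- min(sub$I, na.rm = TRUE)
      if (imin == 0) {
        message("I_min is 0 for ", grp$seq_label,
                "; intensity is 1 exactly where I = 0")
        sub$intensity <- as.numeric(sub$I == 0)
      } else {
        sub$intensity <- pmin(pmax((6.5 * imin - sub$I) / (6.5 * imin - 1.05 * imin), 0), 1)
      }
      sub$I_min <- imin
      sub
    }) |>
    dplyr::ungroup()
}
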