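#' Plot cross-correlation curves z(l) for symmetry-related pairs
#'
#' Line plot of \eqn{z(\ell)} against scale (log-log style axes) for a
#' reference dinucleotide pair and all members of its closure under a
#' symmetry (default the full group S3, i.e. all 8 symmetry-related
#' curves). Curves that lie on top of each other indicate a symmetry valid
#' at that scale.
#'
#' @param scan_tbl A scan table from [scan_pairs()].
#' @param x_a,x_b Reference dinucleotides (default CC, TC).
#' @param symmetry Symmetry whose closure selects the curves (default "S3").
#' @return A ggplot object.
#' @export
plot_z_curves <- function(scan_tbl, x_a = "CC", x_b = "TC", symmetry = "S3") {
  cl <- closure(symmetry, pair_observable(x_a, x_b, sep = 1L))
  keys <- vapply(cl, function(p) {
    paste0(paste(p$first$symbols, collapse = ""), ",",
           paste(p$second$symbols, collapse = ""))
  }, character(1))
  sub <- scan_tbl |>
    dplyr::mutate(pair = paste0(.data$X_A, ",", .data$X_B)) |>
    dplyr::filter(.data$pair %in% keys)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$ell, y = .data$z,
                                    colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "separation scale ℓ (bp)",
                  y = "z(ℓ)", colour = "(X_A, X_B)") +
    ggplot2::theme_minimal()
}

#' Plot the symmetry-index curves I_S(l)
#'
#' One line per symmetry on a log-x axis, with the presence threshold drawn
#' as a horizontal rule: the smaller the index, the stronger the symmetry at
#' that scale.
#'
#' @param curves A tibble from [index_curves()].
#' @param threshold Presence cutoff to draw (default 0.025).
#' @return A ggplot object.
#' @export
plot_index_curves <- function(curves, threshold = 0.025) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$ell, y = .data$I,
                                       colour = .data$symmetry)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(S1 = "#2166ac", S2 = "#1b7837",
                                            S3 = "#b2182b", S4 = "black")) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "separation scale ℓ (bp)", y = "I_S(ℓ)",
                  colour = "symmetry") +
    ggplot2::facet_wrap(ggplot2::vars(.data$seq_label)) +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized symmetry intensities across sequences
#'
#' Tile plot of the [heatmap_table()] intensities: per sequence and
#' symmetry, intensity 1 (full colour) marks scales where the index is
#' within 5% of the sequence minimum and 0 (white) marks indices at least
#' 6.5 times the minimum.
#'
#' @param hm A tibble from [heatmap_table()].
#' @return A ggplot object.
#' @export
plot_symmetry_heatmap <- function(hm) {
  ggplot2::ggplot(hm, ggplot2::aes(x = factor(.data$ell), y = .data$seq_label,
                                   fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$symmetry), ncol = 1) +
    ggplot2::labs(x = "separation scale ℓ (bp)", y = NULL,
                  fill = "intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Autoplot method for symmetry profiles
#'
#' Draws the symmetry-index curves of the profile via [plot_index_curves()].
#'
#' @param object A [symmetry_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symmetry_profile <- function(object, ...) {
  plot_index_curves(object$curves, threshold = object$threshold)
}
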