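#' Full symmetry profile of one sequence
#'
#' The core in-memory pipeline: scan all 256 ordered dinucleotide pairs over
#' the scale grid ([scan_pairs()]), compute the four symmetry-index curves
#' ([index_curves()]), and read off the characteristic scales
#' ([detect_scales()]).
#'
#' @param seq A cleaned A/C/G/T sequence.
#' @param scales Scale grid (default [scale_grid()]; scales that do not fit
#'   are dropped).
#' @param convention Middle-gap convention, see [pair_to_pattern()].
#' @param threshold Symmetry presence cutoff (default 0.025).
#' @param min_windows Minimum composite windows per scale (default 1000).
#' @param label Sequence label.
#' @return An object of class `symmetry_profile`: a list with `scan`
#'   (correlation table), `curves` (index curves), `scales` (detected
#'   characteristic scales), `threshold`, `convention`, `label`, `n`
#'   (sequence length). Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' g <- generate_genome(domain_model_config(macro_length = 5e4, seed = 1))
#' p <- symmetry_profile(g$sequence, scales = 2^(0:9))
#' glance(p)
#' @export
symmetry_profile <- function(seq, scales = scale_grid(),
                             convention = c("formula", "table1"),
                             threshold = 0.025, min_windows = 1000L,
                             label = "seq") {
  convention <- match.arg(convention)
  scan <- scan_pairs(seq, scales = scales, convention = convention,
                     min_windows = min_windows, label = label)
  curves <- index_curves(scan)
  structure(list(
    scan = scan,
    curves = curves,
    scales = detect_scales(curves, threshold = threshold),
    threshold = threshold,
    convention = convention,
    label = label,
    n = nchar(seq)
  ), class = "symmetry_profile")
}

#' @export
print.symmetry_profile <- function(x, ...) {
  cat("<symmetry_profile> ", x$label, " (", format(x$n, big.mark = ","),
      " bp, ", length(unique(x$curves$ell)), " scales, convention ",
      x$convention, ")\n", sep = "")
  sc <- x$scales
  for (i in seq_len(nrow(sc))) {
    cat("  ", sc$scale[i], ": ",
        if (sc$present[i]) format(sc$value[i], big.mark = ",") else
          paste0("absent (", sc$reason[i], ")"), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy and one-line summaries of a symmetry profile
#'
#' `tidy()` returns the symmetry-index curves (one row per symmetry and
#' scale); `glance()` returns a one-row summary with the sequence length and
#' the detected characteristic scales.
#'
#' @param x A [symmetry_profile()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.symmetry_profile <- function(x, ...) {
  x$curves
}

#' @rdname tidy.symmetry_profile
#' @export
glance.symmetry_profile <- function(x, ...) {
  sc <- x$scales
  tibble::tibble(
    seq_label = x$label,
    n = x$n,
    n_scales = length(unique(x$curves$ell)),
    convention = x$convention,
    threshold = x$threshold,
    L_D = sc$value[sc$scale == "L_D"][1],
    L_S = sc$value[sc$scale == "L_S"][1],
    L_M = sc$value[sc$scale == "L_M"][1]
  )
}

#' @keywords internal
#' @noRd
write_profile_outputs <- function(profile, output_dir, prefix) {
  paths <- list(
    correlations = file.path(output_dir, paste0(prefix, "_correlations.tsv")),
    index_curves = file.path(output_dir, paste0(prefix, "_index_curves.tsv")),
    scales = file.path(output_dir, paste0(prefix, "_scales.json")),
    heatmap = file.path(output_dir, paste0(prefix, "_heatmap.tsv"))
  )
  readr::write_tsv(profile$scan, paths$correlations)
  readr::write_tsv(profile$curves, paths$index_curves)
  jsonlite::write_json(profile$scales, paths$scales, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_tsv(heatmap_table(profile$curves), paths$heatmap)
  paths
}

#' Run the end-to-end analysis with file outputs
#'
#' Orchestrates a full run — simulate (or load a FASTA), clean, scan, index,
#' detect scales — and writes the correlation table, index curves, detected
#' scales, heatmap table and a manifest (inputs, seed, convention, package
#' version) sufficient to re-run bit-identically.
#'
#' @param input Either a FASTA file path or a [domain_model_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @param scales,convention,threshold,min_windows Passed to
#'   [symmetry_profile()].
#' @param record_policy FASTA record policy, see [read_fasta()] (only used
#'   for FASTA input).
#' @return Invisibly, a list of `symmetry_profile` objects (one per
#'   sequence) with attribute `manifest` (also written as
#'   `manifest.json`).
#' @export
run_analysis <- function(input, output_dir,
                         scales = scale_grid(),
                         convention = c("formula", "table1"),
                         threshold = 0.025, min_windows = 1000L,
                         record_policy = "per-record") {
  convention <- match.arg(convention)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(input, "domain_model_config")) {
    g <- generate_genome(input)
    seqs <- tibble::tibble(label = "simulated", sequence = g$sequence)
    input_desc <- list(type = "simulation",
                       seed = input$seed,
                       macro_length = input$macro_length,
                       n_processes = length(input$processes),
                       chunk_range = input$chunk_range,
                       revcomp_prob = input$revcomp_prob)
    jsonlite::write_json(g$ground_truth$scales,
                         file.path(output_dir, "ground_truth_scales.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stopifnot(is.character(input), length(input) == 1L)
    raw <- read_fasta(input, record_policy = record_policy)
    cleaned <- clean_sequence(raw$sequence)
    seqs <- tibble::tibble(label = raw$label[cleaned$input],
                           sequence = cleaned$sequence)
    input_desc <- list(type = "fasta", path = input,
                       record_policy = record_policy,
                       removed_fraction = cleaned$removed_fraction)
  }
  profiles <- purrr::pmap(seqs, function(label, sequence) {
    p <- symmetry_profile(sequence, scales = scales, convention = convention,
                          threshold = threshold, min_windows = min_windows,
                          label = label)
    write_profile_outputs(p, output_dir, prefix = label)
    p
  })
  manifest <- list(
    package = "symscales",
    version = as.character(utils::packageVersion("symscales")),
    input = input_desc,
    convention = convention,
    threshold = threshold,
    min_windows = min_windows,
    scales = scales,
    sequences = seqs$label,
    complete = TRUE
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(profiles, "manifest") <- manifest
  invisible(profiles)
}

#' Analyze several inputs and aggregate their heatmap intensities
#'
#' Runs [run_analysis()] on each input; per-input failures are logged and
#' the run continues. The per-sequence index curves are combined into one
#' normalized heatmap intensity table ([heatmap_table()]) across all
#' analyzed sequences.
#'
#' @param inputs List (or vector) of inputs as accepted by [run_analysis()].
#' @param output_dir Output directory; each input writes into a numbered
#'   subdirectory, and the aggregated heatmap is written at the top level.
#' @param ... Passed to [run_analysis()].
#' @return Invisibly, a list with `profiles` (flat list over sequences) and
#'   `heatmap` (the aggregated intensity tibble).
#' @export
run_multi <- function(inputs, output_dir, ...) {
  if (length(inputs) == 0L) stop("empty input list", call. = FALSE)
  if (is.character(inputs)) inputs <- as.list(inputs)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list()
  for (i in seq_along(inputs)) {
    sub <- file.path(output_dir, sprintf("input%02d", i))
    res <- tryCatch(run_analysis(inputs[[i]], sub, ...), error = function(e) {
      message("input ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) profiles <- c(profiles, res)
  }
  if (length(profiles) == 0L) stop("all inputs failed", call. = FALSE)
  curves <- purrr::map_dfr(seq_along(profiles), function(i) {
    dplyr::mutate(profiles[[i]]$curves,
                  seq_label = paste0(.data$seq_label, "#", i))
  })
  hm <- heatmap_table(curves)
  readr::write_tsv(hm, file.path(output_dir, "heatmap_all.tsv"))
  invisible(list(profiles = profiles, heatmap = hm))
}
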