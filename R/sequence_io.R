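#' Read nucleotide sequences from a FASTA file
#'
#' Reads a plain (optionally gzipped) FASTA file and returns the raw,
#' uppercased sequences. No cleaning is performed: non-ACGT letters (assembly
#' gaps `N`, IUPAC ambiguity codes, ...) are retained so that
#' [clean_sequence()] can report how much material is removed.
#'
#' Soft-masked (lowercase) bases are uppercased here, before any filtering, so
#' that masked a/c/g/t are treated as ordinary bases.
#'
#' @param path Path to a FASTA file.
#' @param record_policy How to handle multi-record files: `"per-record"`
#'   (default) returns one row per record, `"first"` keeps only the first
#'   record, `"concatenate"` joins all records in file order into a single
#'   sequence.
#' @return A tibble with columns `label` (FASTA header up to the first
#'   whitespace), `sequence` (uppercase character scalar) and `length`.
#' @seealso [clean_sequence()], [write_fasta()]
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "GGACCGGCC", "ACAGGAA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, record_policy = c("per-record", "first", "concatenate")) {
  record_policy <- match.arg(record_policy)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  # BStringSet, not DNAStringSet: raw records may carry arbitrary letters
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  labels <- unname(sub("\\s.*$", "", names(recs)))
  seqs <- unname(toupper(as.character(recs)))
  if (record_policy == "first") {
    labels <- labels[1L]
    seqs <- seqs[1L]
  } else if (record_policy == "concatenate") {
    labels <- labels[1L]
    seqs <- paste(seqs, collapse = "")
  }
  tibble::tibble(label = labels, sequence = seqs, length = nchar(seqs))
}

#' Remove non-ACGT letters from raw sequences
#'
#' Deletes (splices out) every character that is not one of `A`, `C`, `G`,
#' `T`, preserving the relative order of the retained bases, and reports the
#' removed fraction. This mirrors the standard preprocessing of reference
#' assemblies, where gap runs and ambiguity codes make up a small fraction of
#' the genome (about 1.7% of the human assembly) and are dropped before
#' counting.
#'
#' Optionally, `split_at_n` splits the sequence at runs of at least
#' `split_at_n` non-ACGT characters instead of splicing across them, returning
#' one row per segment; short runs below the threshold are still spliced.
#'
#' @param x Character vector of raw sequences (any case; uppercased first).
#' @param split_at_n `NULL` (default, splice everything) or a positive
#'   integer: split into segments at runs of `>= split_at_n` non-ACGT
#'   characters.
#' @return A tibble with one row per input (or per segment when splitting)
#'   and columns `input` (index of the input element), `segment`, `sequence`,
#'   `length`, `n_removed`, `removed_fraction`. For an empty input the
#'   removed fraction is 0 by convention.
#' @examples
#' clean_sequence("ACGNNT")
#' clean_sequence("acgtNNNNacgt", split_at_n = 3)
#' @export
clean_sequence <- function(x, split_at_n = NULL) {
  stopifnot(is.character(x))
  if (!is.null(split_at_n)) {
    stopifnot(length(split_at_n) == 1L, split_at_n >= 1)
  }
  purrr::imap_dfr(x, function(raw, idx) {
    raw <- toupper(raw)
    n_raw <- nchar(raw)
    if (is.null(split_at_n)) {
      pieces <- gsub("[^ACGT]", "", raw)
    } else {
      run <- sprintf("[^ACGT]{%d,}", as.integer(split_at_n))
      pieces <- gsub("[^ACGT]", "", strsplit(raw, run)[[1]])
      if (length(pieces) == 0L) pieces <- ""
      pieces <- pieces[pieces != "" | length(pieces) == 1L]
    }
    kept <- sum(nchar(pieces))
    tibble::tibble(
      input = idx,
      segment = seq_along(pieces),
      sequence = pieces,
      length = nchar(pieces),
      n_removed = n_raw - kept,
      removed_fraction = if (n_raw == 0L) 0 else (n_raw - kept) / n_raw
    )
  })
}

#' Write sequences to a FASTA file
#'
#' @param seq Character vector of sequences.
#' @param path Output path.
#' @param labels Record labels; defaults to `seq1`, `seq2`, ...
#' @param line_width Sequence line width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seq, path, labels = NULL, line_width = 60L) {
  stopifnot(is.character(seq), line_width >= 1)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seq))
  x <- Biostrings::BStringSet(seq)
  names(x) <- labels
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(line_width))
  invisible(path)
}
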