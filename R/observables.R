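#' @keywords internal
#' @noRd
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  raw <- utf8ToInt(seq)
  codes <- integer(length(raw))
  codes[raw == 65L] <- 1L  # A
  codes[raw == 67L] <- 2L  # C
  codes[raw == 71L] <- 3L  # G
  codes[raw == 84L] <- 4L  # T
  if (any(codes == 0L)) {
    stop("sequence contains letters outside {A,C,G,T}; run clean_sequence() first",
         call. = FALSE)
  }
  codes
}

#' @keywords internal
#' @noRd
codes_to_seq <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[codes])
}

#' Gapped-pattern observables
#'
#' A gapped pattern is an ordered set of bases together with the pairwise
#' distances (gaps) between consecutive bases: symbols
#' \eqn{(\alpha_0, \dots, \alpha_k)} and gaps \eqn{(\tau_1, \dots, \tau_k)},
#' all gaps \eqn{\ge 1}. A contiguous oligonucleotide is the special case with
#' all gaps equal to 1; gaps larger than 1 leave unconstrained positions in
#' between. The span of the pattern (its size) is
#' \eqn{\ell_X = \sum_i \tau_i + 1}.
#'
#' @param symbols Character vector of bases in `{A,C,G,T}`, or a single
#'   string such as `"ACG"` which is split into characters.
#' @param gaps Integer vector of gaps, one fewer than symbols; defaults to
#'   all-1 (contiguous oligonucleotide).
#' @return An object of class `gapped_pattern`.
#' @examples
#' gapped_pattern(c("A", "C", "G"), c(1, 2)) # A, then C 1 after, then G 2 after
#' gapped_pattern("ACT")                     # contiguous trinucleotide
#' @export
gapped_pattern <- function(symbols, gaps = NULL) {
  if (is.character(symbols) && length(symbols) == 1L && nchar(symbols) > 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  symbols <- toupper(as.character(symbols))
  if (length(symbols) < 1L || !all(symbols %in% DNA_BASES)) {
    stop("pattern symbols must be in {A,C,G,T}", call. = FALSE)
  }
  if (is.null(gaps)) gaps <- rep(1L, length(symbols) - 1L)
  gaps <- as.integer(gaps)
  if (length(gaps) != length(symbols) - 1L) {
    stop("need exactly length(symbols) - 1 gaps", call. = FALSE)
  }
  if (length(gaps) > 0L && any(gaps < 1L)) {
    stop("all gaps must be >= 1", call. = FALSE)
  }
  structure(list(symbols = symbols, gaps = gaps), class = "gapped_pattern")
}

#' Parse a gapped-pattern literal
#'
#' The literal syntax interleaves bases with gap values: `"A1C2G"` means
#' symbols A, C, G with gaps 1 and 2. Digits between letters are mandatory
#' gap values; as a shorthand, an all-letter literal such as `"ACT"` denotes
#' the contiguous oligonucleotide (all gaps 1).
#'
#' @param x A pattern literal string.
#' @return A [gapped_pattern()].
#' @examples
#' parse_pattern("A1C2G")
#' parse_pattern("ACT")
#' @export
parse_pattern <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(trimws(x))
  if (grepl("^[ACGT]+$", x)) {
    return(gapped_pattern(x))
  }
  if (!grepl("^[ACGT]([0-9]+[ACGT])*$", x)) {
    stop("malformed pattern literal: ", x, call. = FALSE)
  }
  symbols <- regmatches(x, gregexpr("[ACGT]", x))[[1]]
  gaps <- as.integer(regmatches(x, gregexpr("[0-9]+", x))[[1]])
  gapped_pattern(symbols, gaps)
}

#' @export
format.gapped_pattern <- function(x, ...) {
  if (length(x$symbols) == 1L) return(x$symbols)
  paste0(x$symbols[-length(x$symbols)], x$gaps, collapse = "") |>
    paste0(x$symbols[length(x$symbols)])
}

#' @export
print.gapped_pattern <- function(x, ...) {
  cat("<gapped_pattern> ", format(x), "  (size ", pattern_size(x), ")\n", sep = "")
  invisible(x)
}

#' @export
`==.gapped_pattern` <- function(e1, e2) {
  identical(e1$symbols, e2$symbols) && identical(e1$gaps, e2$gaps)
}

#' Size (span) of a gapped pattern
#'
#' The number of sequence positions a pattern occupies:
#' \eqn{\ell_X = \sum_i \tau_i + 1}. A single base has size 1.
#'
#' @param x A [gapped_pattern()].
#' @return A positive integer.
#' @examples
#' pattern_size(parse_pattern("A1C2G")) # 4
#' @export
pattern_size <- function(x) {
  stopifnot(inherits(x, "gapped_pattern"))
  sum(x$gaps) + 1L
}

#' Count occurrences of a gapped pattern in a sequence
#'
#' Counts the start positions \eqn{i}, over all \eqn{N' = N - \ell_X + 1}
#' windows in which the pattern fits, at which every pattern base matches the
#' sequence: \eqn{s_{i+\ell_j} = \alpha_j} with offsets
#' \eqn{\ell_j = \sum_{r \le j} \tau_r} (and \eqn{\ell_0 = 0}). Overlapping
#' occurrences all count. The frequency is \eqn{P(X) = \mathrm{count}/N'}.
#'
#' @param seq A cleaned A/C/G/T sequence (character scalar) or a
#'   [gapped_pattern()]-ready character vector of length 1.
#' @param pattern A [gapped_pattern()] or a pattern literal accepted by
#'   [parse_pattern()].
#' @return A one-row tibble with columns `pattern`, `size`, `count`,
#'   `windows` and `frequency`. When the pattern does not fit
#'   (\eqn{N < \ell_X}), `windows` is 0 and `frequency` is `NA`, with a
#'   warning.
#' @examples
#' count_pattern("GGACCGGCCACAGGAA", "A1C2G") # 2 of 13 windows
#' @export
count_pattern <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "gapped_pattern"))
  codes <- seq_to_codes(seq)
  res <- count_pattern_codes(codes, pattern)
  lab <- format(pattern)
  lx <- pattern_size(pattern)
  tibble::tibble(
    pattern = lab,
    size = lx,
    count = res$count,
    windows = res$windows,
    frequency = if (res$windows > 0L) res$count / res$windows else NA_real_
  )
}

#' @keywords internal
#' @noRd
count_pattern_codes <- function(codes, pattern) {
  lx <- pattern_size(pattern)
  n <- length(codes)
  if (n < lx) {
    warning("pattern (size ", lx, ") does not fit in sequence (length ", n,
            "); no windows", call. = FALSE)
    return(list(count = 0L, windows = 0L))
  }
  np <- n - lx + 1L
  offsets <- c(0L, cumsum(pattern$gaps))
  want <- match(pattern$symbols, DNA_BASES)
  ok <- rep(TRUE, np)
  for (j in seq_along(offsets)) {
    ok <- ok & codes[offsets[j] + seq_len(np)] == want[j]
  }
  list(count = sum(ok), windows = np)
}

#' Reverse complement of a sequence
#'
#' Reverses the sequence and complements each base (A<->T, C<->G). An
#' involution: applying it twice returns the input.
#'
#' @param seq An A/C/G/T character scalar (empty string allowed).
#' @return The reverse-complemented sequence.
#' @examples
#' revcomp_sequence("CGT") # "ACG"
#' @export
revcomp_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Reverse complement of a gapped pattern
#'
#' The observable symmetric to \eqn{X = ((\alpha_0,\dots,\alpha_k),
#' (\tau_1,\dots,\tau_k))} under strand symmetry is
#' \eqn{\hat X = ((\hat\alpha_k,\dots,\hat\alpha_0),
#' (\tau_k,\dots,\tau_1))}: bases complemented and reversed, gaps reversed.
#' The size is preserved, and the transform is an involution.
#'
#' @param x A [gapped_pattern()].
#' @return The reverse-complement pattern.
#' @examples
#' format(revcomp_pattern(parse_pattern("A1C2G"))) # "C2G1T"
#' @export
revcomp_pattern <- function(x) {
  stopifnot(inherits(x, "gapped_pattern"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gapped_pattern(rev(unname(comp[x$symbols])), rev(x$gaps))
}
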