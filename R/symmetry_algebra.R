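#' Composite pair observables
#'
#' A pair observable \eqn{Y = (X_A, X_B; \ell)} requires pattern \eqn{X_A}
#' and pattern \eqn{X_B} to co-occur at separation scale \eqn{\ell \ge 1}.
#' Scanning \eqn{\ell} over decades probes which strand symmetries hold at
#' which genomic scales.
#'
#' @param first,second [gapped_pattern()]s (or literals / base strings such
#'   as `"CC"`, parsed as contiguous oligonucleotides).
#' @param sep Separation scale \eqn{\ell \ge 1}.
#' @return An object of class `pair_observable`.
#' @examples
#' pair_observable("CC", "TC", sep = 4)
#' @export
pair_observable <- function(first, second, sep) {
  if (is.character(first)) first <- parse_pattern(first)
  if (is.character(second)) second <- parse_pattern(second)
  stopifnot(inherits(first, "gapped_pattern"), inherits(second, "gapped_pattern"))
  sep <- as.integer(sep)
  stopifnot(length(sep) == 1L, sep >= 1L)
  structure(list(first = first, second = second, sep = sep),
            class = "pair_observable")
}

#' @export
format.pair_observable <- function(x, ...) {
  paste0("(", format(x$first), ", ", format(x$second), "; ", x$sep, ")")
}

#' @export
print.pair_observable <- function(x, ...) {
  cat("<pair_observable> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.pair_observable` <- function(e1, e2) {
  e1$first == e2$first && e1$second == e2$second && e1$sep == e2$sep
}

#' Flatten a pair observable into a single gapped pattern
#'
#' Concatenates the two component patterns into one gapped pattern whose
#' middle gap encodes the separation. Two conventions for the middle gap are
#' supported:
#' \describe{
#'   \item{`"formula"`}{middle gap \eqn{= \ell} (the separation written
#'     directly into the gap vector); the default.}
#'   \item{`"table1"`}{middle gap \eqn{= \ell + 1}, i.e. \eqn{\ell} fully
#'     unconstrained positions between the last base of \eqn{X_A} and the
#'     first base of \eqn{X_B} (for dinucleotides at \eqn{\ell = 4} this is
#'     the 8-position layout with 4 arbitrary middle positions).}
#' }
#'
#' @param y A [pair_observable()].
#' @param convention `"formula"` (default) or `"table1"`.
#' @return A [gapped_pattern()].
#' @examples
#' format(pair_to_pattern(pair_observable("AC", "GT", 4)))           # "A1C4G1T"
#' format(pair_to_pattern(pair_observable("AC", "GT", 4), "table1")) # "A1C5G1T"
#' @export
pair_to_pattern <- function(y, convention = c("formula", "table1")) {
  stopifnot(inherits(y, "pair_observable"))
  convention <- match.arg(convention)
  mid <- if (convention == "formula") y$sep else y$sep + 1L
  gapped_pattern(c(y$first$symbols, y$second$symbols),
                 c(y$first$gaps, mid, y$second$gaps))
}

#' Elementary symmetry transformations of a pair observable
#'
#' `transform_R()` reverses the order of the pair:
#' \eqn{(X_A, X_B; \ell) \to (X_B, X_A; \ell)}. `transform_C()` applies the
#' reverse-complement to the first component only:
#' \eqn{(X_A, X_B; \ell) \to (\hat X_A, X_B; \ell)}. Both are involutions;
#' they do not commute. The composition `CRC` maps
#' \eqn{(X_A, X_B; \ell) \to (\hat X_B, \hat X_A; \ell)}, the extended
#' Chargaff transform of the composite.
#'
#' @param y A [pair_observable()].
#' @return The transformed [pair_observable()].
#' @examples
#' format(transform_R(pair_observable("CC", "TC", 4))) # (TC, CC; 4)
#' format(transform_C(pair_observable("CC", "TC", 4))) # (GG, TC; 4)
#' @export
transform_R <- function(y) {
  stopifnot(inherits(y, "pair_observable"))
  pair_observable(y$second, y$first, y$sep)
}

#' @rdname transform_R
#' @export
transform_C <- function(y) {
  stopifnot(inherits(y, "pair_observable"))
  pair_observable(revcomp_pattern(y$first), y$second, y$sep)
}

#' Apply a transformation word to a pair observable
#'
#' A word is a string over the letters `R` and `C`. Letters are applied
#' right-to-left (the rightmost transformation acts first), matching standard
#' operator composition; for the generator words used here the generated
#' closures are order-independent.
#'
#' @param word Nonempty string over `{R, C}` such as `"CRC"`.
#' @param y A [pair_observable()].
#' @return The transformed [pair_observable()].
#' @examples
#' format(apply_word("CRC", pair_observable("CC", "TC", 4))) # (GA, GG; 4)
#' @export
apply_word <- function(word, y) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) >= 1L)
  letters_ <- strsplit(word, "")[[1]]
  if (!all(letters_ %in% c("R", "C"))) {
    stop("transformation word must use only letters R and C: ", word, call. = FALSE)
  }
  for (ch in rev(letters_)) {
    y <- if (ch == "R") transform_R(y) else transform_C(y)
  }
  y
}

# Fixed registry of the four nested symmetries.
SYMMETRY_GENERATORS <- list(
  S1 = "CRC",
  S2 = c("CRC", "R"),
  S3 = c("R", "C"),
  S4 = c("RCR", "C")
)

#' Generator words of the symmetries S1-S4
#'
#' The four symmetries are defined by generator sets over the transformations
#' `R` (swap the pair) and `C` (reverse-complement the first component):
#' S1 = \{CRC\} (extended Chargaff), S2 = \{CRC, R\}, S3 = \{R, C\} (the full
#' group), S4 = \{RCR, C\}. Their closures nest: S1 < S2 < S3 and S4 < S3.
#'
#' @param name One of `"S1"`, `"S2"`, `"S3"`, `"S4"`, or a custom character
#'   vector of words over `{R, C}` which is returned as-is.
#' @return Character vector of generator words.
#' @examples
#' symmetry_generators("S2")
#' @export
symmetry_generators <- function(name) {
  if (length(name) == 1L && name %in% names(SYMMETRY_GENERATORS)) {
    return(SYMMETRY_GENERATORS[[name]])
  }
  ok <- vapply(name, function(w) grepl("^[RC]+$", w), logical(1))
  if (!all(ok)) {
    stop("unknown symmetry; use S1-S4 or a vector of words over {R,C}",
         call. = FALSE)
  }
  name
}

#' @keywords internal
#' @noRd
pair_key <- function(y) format(y)

#' Closure set of a pair observable under a symmetry
#'
#' The smallest set containing `y` and closed under every generator word of
#' the symmetry (breadth-first closure with set semantics, duplicates
#' removed). For dinucleotide pairs the closure has at most 8 elements (the
#' full group generated by R and C); degenerate pairs (e.g. a self
#' reverse-complement component) give smaller closures.
#'
#' @param symmetry A symmetry name (`"S1"`..`"S4"`) or custom generator
#'   words (see [symmetry_generators()]).
#' @param y The reference [pair_observable()].
#' @return A list of [pair_observable()]s; the first element is `y`.
#' @examples
#' length(closure("S2", pair_observable("CC", "TC", 4))) # 4
#' @export
closure <- function(symmetry, y) {
  stopifnot(inherits(y, "pair_observable"))
  gens <- symmetry_generators(symmetry)
  out <- list(y)
  names(out) <- pair_key(y)
  queue <- list(y)
  while (length(queue) > 0L) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (g in gens) {
      cand <- apply_word(g, cur)
      key <- pair_key(cand)
      if (is.null(out[[key]])) {
        out[[key]] <- cand
        queue[[length(queue) + 1L]] <- cand
      }
    }
  }
  unname(out)
}
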