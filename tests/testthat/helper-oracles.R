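# Independent oracles and fixture builders, deliberately naive and distinct
# from the package implementation.

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# reverse complement via chartr, independent of Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# position-by-position scanning count of a gapped pattern (symbols, gaps)
oracle_count <- function(seq, symbols, gaps) {
  n <- nchar(seq)
  offsets <- c(0, cumsum(gaps))
  lx <- offsets[length(offsets)] + 1
  if (n < lx) return(list(count = 0L, windows = 0L))
  np <- as.integer(n - lx + 1)
  count <- 0L
  for (i in seq_len(np)) {
    hit <- TRUE
    for (j in seq_along(symbols)) {
      if (substr(seq, i + offsets[j], i + offsets[j]) != symbols[j]) {
        hit <- FALSE
        break
      }
    }
    if (hit) count <- count + 1L
  }
  list(count = count, windows = np)
}

random_pattern <- function(max_k = 4, max_size = 32) {
  k <- sample(0:max_k, 1)
  symbols <- sample(c("A", "C", "G", "T"), k + 1, replace = TRUE)
  if (k == 0) return(gapped_pattern(symbols, integer(0)))
  repeat {
    gaps <- sample(1:8, k, replace = TRUE)
    if (sum(gaps) + 1 <= max_size) break
  }
  gapped_pattern(symbols, gaps)
}

random_pair <- function(sep = NULL) {
  dn <- function() paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                         collapse = "")
  if (is.null(sep)) sep <- sample(1:64, 1)
  pair_observable(dn(), dn(), sep)
}

# scan table skeleton covering all 256 ordered dinucleotide pairs; several
# stacked replicates are distinguished by their ell values
null_scan_table <- function(z, ell = 1, label = "null") {
  bases <- c("A", "C", "G", "T")
  dn <- as.vector(t(outer(bases, bases, paste0)))
  grid <- expand.grid(ib = 1:16, ia = 1:16)
  reps <- length(z) / 256
  stopifnot(reps == round(reps))
  if (length(ell) == 1) ell <- rep(ell, length(z))
  tibble::tibble(seq_label = label,
                 X_A = rep(dn[grid$ia], reps), X_B = rep(dn[grid$ib], reps),
                 ell = ell, z = z)
}

# matrix power by repeated multiplication
mat_pow <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}
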