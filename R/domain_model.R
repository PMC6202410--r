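# Transition matrices of the two shipped domain processes, row/column order
# A, C, G, T. Both have stationary measures that violate Chargaff's rule
# (mu(A) != mu(T), mu(C) != mu(G)), which is what makes the symmetry
# hierarchy of the simulated genome nontrivial.

#' Shipped domain-process transition matrices
#'
#' The two 4x4 row-stochastic matrices driving the default simulator
#' processes. Rows/columns are ordered A, C, G, T; entry `[a, b]` is the
#' probability that base `b` follows base `a`. Both chains mix within about
#' ten bases (setting the domain scale \eqn{L_D \simeq 10}) and have
#' Chargaff-violating stationary measures.
#'
#' @return A 4x4 numeric matrix with dimnames.
#' @examples
#' rowSums(markov_matrix_I())
#' @export
markov_matrix_I <- function() {
  matrix(c(0.20, 0.10, 0.20, 0.50,
           0.01, 0.84, 0.01, 0.14,
           0.40, 0.10, 0.40, 0.10,
           0.30, 0.15, 0.25, 0.30),
         nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
}

#' @rdname markov_matrix_I
#' @export
markov_matrix_II <- function() {
  matrix(c(0.10, 0.20, 0.10, 0.60,
           0.10, 0.75, 0.10, 0.05,
           0.10, 0.40, 0.10, 0.40,
           0.10, 0.35, 0.45, 0.10),
         nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
}

#' Stationary distribution of a 4-state Markov transition matrix
#'
#' The unique left fixed vector \eqn{\mu} with \eqn{\mu M = \mu},
#' \eqn{\sum \mu = 1}, computed from the left eigenvector of eigenvalue 1.
#' Errors if the chain does not have a unique stationary distribution
#' (reducible or periodic chain).
#'
#' @param M A 4x4 row-stochastic matrix.
#' @return A probability vector named A, C, G, T.
#' @examples
#' stationary_distribution(markov_matrix_I())
#' @export
stationary_distribution <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == 4L, ncol(M) == 4L, all(M >= 0))
  if (any(abs(rowSums(M) - 1) > 1e-12)) {
    stop("matrix rows must sum to 1", call. = FALSE)
  }
  e <- eigen(t(M))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) != 1L) {
    stop("no unique stationary distribution (chain reducible or periodic)",
         call. = FALSE)
  }
  v <- Re(e$vectors[, unit])
  mu <- v / sum(v)
  if (any(mu < -1e-12)) {
    stop("no unique stationary distribution (chain reducible or periodic)",
         call. = FALSE)
  }
  mu <- pmax(mu, 0)
  stats::setNames(mu / sum(mu), DNA_BASES)
}

#' Define a domain process
#'
#' Bundles a transition matrix with its stationary distribution and
#' precomputed cumulative rows for fast simulation.
#'
#' @param M A 4x4 row-stochastic matrix (rows/columns A, C, G, T).
#' @return An object of class `markov_process` with elements `matrix`,
#'   `stationary`, `mixing_decay` (second-largest eigenvalue modulus, the
#'   per-step correlation decay factor whose inverse log sets the domain
#'   correlation scale).
#' @export
markov_process <- function(M) {
  mu <- stationary_distribution(M)
  ev <- sort(Mod(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  structure(list(
    matrix = M,
    stationary = mu,
    mixing_decay = ev[2L],
    cum = t(apply(M, 1L, cumsum)),
    init_cum = cumsum(mu)
  ), class = "markov_process")
}

#' Simulator configuration
#'
#' All parameters of the three-level generative model. The defaults are the
#' reference study conditions: two order-1 Markov processes with the shipped
#' Chargaff-violating matrices, chunks of length uniform on [130, 170]
#' reverse-complemented independently with probability 1/2 (geometric
#' same-orientation runs of mean 2 chunks, hence a cluster scale
#' \eqn{L_S \simeq 2 \times 150 = 300}), and one macrostructure of target
#' length \eqn{10^6} per process.
#'
#' @param processes List of transition matrices or `markov_process` objects
#'   (default the two shipped matrices), one macrostructure each.
#' @param chunk_range Integer range for uniform chunk lengths (default
#'   `c(130, 170)`).
#' @param revcomp_prob Probability that a chunk is reverse-complemented
#'   before concatenation (default 0.5).
#' @param macro_length Target macrostructure length in bases (default 1e6).
#' @param seed Optional integer seed; when non-`NULL`, [generate_genome()]
#'   seeds R's RNG so the genome is bit-reproducible.
#' @return An object of class `domain_model_config`.
#' @export
domain_model_config <- function(processes = list(markov_matrix_I(), markov_matrix_II()),
                                chunk_range = c(130L, 170L),
                                revcomp_prob = 0.5,
                                macro_length = 1e6,
                                seed = NULL) {
  processes <- lapply(processes, function(p) {
    if (inherits(p, "markov_process")) p else markov_process(p)
  })
  stopifnot(length(processes) >= 1L,
            length(chunk_range) == 2L, chunk_range[1] >= 1,
            chunk_range[2] >= chunk_range[1],
            revcomp_prob >= 0, revcomp_prob <= 1,
            macro_length >= 1)
  structure(list(
    processes = processes,
    chunk_range = as.integer(chunk_range),
    revcomp_prob = revcomp_prob,
    macro_length = macro_length,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "domain_model_config")
}

#' @keywords internal
#' @noRd
generate_chunk_codes <- function(process, length) {
  markov_chunk_cpp(process$cum, process$init_cum, as.integer(length))
}

#' Generate one domain chunk
#'
#' A fresh realization of the domain process: the first base is drawn from
#' the stationary distribution, subsequent bases from the transition matrix.
#' Chunks are independent realizations — the Markov state does not continue
#' across chunk boundaries (it could not, since individual chunks get
#' reverse-complemented).
#'
#' @param process A `markov_process` (or a transition matrix).
#' @param length Chunk length (bases, `>= 1`).
#' @return A character scalar sequence.
#' @export
generate_chunk <- function(process, length) {
  if (is.matrix(process)) process <- markov_process(process)
  stopifnot(inherits(process, "markov_process"), length >= 1)
  codes_to_seq(generate_chunk_codes(process, length))
}

#' Generate one macrostructure
#'
#' Concatenates independent chunks of the given process until the target
#' length is reached. Per chunk, in order: (1) its length is drawn uniformly
#' from `chunk_range`, (2) a fair(-by-default) coin decides whether the chunk
#' is reverse-complemented (the mirrored process), (3) its bases are drawn.
#' Generation stops with the first chunk whose addition reaches or exceeds
#' `macro_length`; whole chunks are kept (no truncation), so the final
#' length lies in `[macro_length, macro_length + chunk_range[2])`.
#'
#' @param process A `markov_process` (or transition matrix).
#' @param config A [domain_model_config()] (its `chunk_range`,
#'   `revcomp_prob` and `macro_length` are used; its seed is not applied
#'   here — seed at the genome level or with [set.seed()]).
#' @return A list with `sequence` (character scalar) and `chunk_log`, a
#'   tibble with one row per chunk: `start`, `length`, `revcomp`.
#' @export
generate_macrostructure <- function(process, config = domain_model_config()) {
  if (is.matrix(process)) process <- markov_process(process)
  stopifnot(inherits(process, "markov_process"),
            inherits(config, "domain_model_config"))
  target <- config$macro_length
  est <- ceiling(target / mean(config$chunk_range)) + 64L
  codes_list <- vector("list", est)
  lens <- integer(est)
  flips <- logical(est)
  total <- 0
  k <- 0L
  while (total < target) {
    k <- k + 1L
    len <- sample.int(config$chunk_range[2] - config$chunk_range[1] + 1L, 1L) +
      config$chunk_range[1] - 1L
    flip <- stats::runif(1L) < config$revcomp_prob
    chunk <- generate_chunk_codes(process, len)
    if (flip) chunk <- 5L - rev(chunk)
    if (k > length(codes_list)) {
      codes_list <- c(codes_list, vector("list", 64L))
      lens <- c(lens, integer(64L))
      flips <- c(flips, logical(64L))
    }
    codes_list[[k]] <- chunk
    lens[k] <- len
    flips[k] <- flip
    total <- total + len
  }
  codes <- unlist(codes_list[seq_len(k)], use.names = FALSE)
  list(
    sequence = codes_to_seq(codes),
    chunk_log = tibble::tibble(
      start = cumsum(c(1L, lens[seq_len(k - 1L)])),
      length = lens[seq_len(k)],
      revcomp = flips[seq_len(k)]
    )
  )
}

#' Generate a synthetic genome with a known symmetry hierarchy
#'
#' The full three-level model: one macrostructure per configured process
#' (default two, from the shipped matrices), concatenated in order. Within
#' each macrostructure, mirrored (reverse-complemented) chunks appear with
#' the same abundance as plain ones, so extended Chargaff symmetry holds
#' within — but not across — macrostructures, producing the nested S1-S4
#' hierarchy with ground-truth scales.
#'
#' @param config A [domain_model_config()]; when `config$seed` is set the
#'   RNG is seeded first and genomes are bit-reproducible.
#' @return A list with `sequence` and `ground_truth`, the latter holding
#'   `boundaries` (1-based start of each macrostructure), `chunk_logs` (one
#'   tibble per macrostructure), and `scales`: `L_D` (domain correlation
#'   scale `1/log(1/decay)` from the slowest process, with the raw
#'   second-eigenvalue moduli alongside), `L_S` (twice the mean chunk
#'   length over the mean same-orientation run length at `revcomp_prob`
#'   0.5: `2 * mean(chunk_range)`), `L_M` (the macrostructure length), and
#'   the seed.
#' @examples
#' g <- generate_genome(domain_model_config(macro_length = 1e4, seed = 42))
#' nchar(g$sequence)
#' @export
generate_genome <- function(config = domain_model_config()) {
  stopifnot(inherits(config, "domain_model_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  macros <- lapply(config$processes, generate_macrostructure, config = config)
  seqs <- vapply(macros, `[[`, character(1), "sequence")
  lens <- nchar(seqs)
  decay <- vapply(config$processes, `[[`, numeric(1), "mixing_decay")
  list(
    sequence = paste(seqs, collapse = ""),
    ground_truth = list(
      boundaries = cumsum(c(1, lens[-length(lens)])),
      macro_lengths = lens,
      chunk_logs = lapply(macros, `[[`, "chunk_log"),
      scales = list(
        L_D = 1 / log(1 / max(decay)),
        mixing_decay = decay,
        L_S = 2 * mean(config$chunk_range),
        L_M = config$macro_length
      ),
      seed = config$seed
    )
  )
}
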