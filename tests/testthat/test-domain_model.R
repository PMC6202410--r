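test_that("shipped matrices are row-stochastic with Chargaff-violating stationaries", {
  for (M in list(markov_matrix_I(), markov_matrix_II())) {
    expect_equal(rowSums(M), stats::setNames(rep(1, 4), c("A", "C", "G", "T")))
    expect_true(all(M >= 0))
    mu <- stationary_distribution(M)
    expect_equal(sum(mu), 1)
    expect_equal(as.numeric(mu %*% M), as.numeric(mu), tolerance = 1e-10)
    expect_gt(abs(mu[["A"]] - mu[["T"]]), 0.01)
    expect_gt(abs(mu[["C"]] - mu[["G"]]), 0.01)
  }
  # pin the printed entries of the two processes
  expect_equal(markov_matrix_I()[1, ], c(A = 0.2, C = 0.1, G = 0.2, T = 0.5))
  expect_equal(markov_matrix_I()[2, ], c(A = 0.01, C = 0.84, G = 0.01, T = 0.14))
  expect_equal(markov_matrix_I()[3, ], c(A = 0.4, C = 0.1, G = 0.4, T = 0.1))
  expect_equal(markov_matrix_I()[4, ], c(A = 0.3, C = 0.15, G = 0.25, T = 0.3))
  expect_equal(markov_matrix_II()[1, ], c(A = 0.1, C = 0.2, G = 0.1, T = 0.6))
  expect_equal(markov_matrix_II()[2, ], c(A = 0.1, C = 0.75, G = 0.1, T = 0.05))
  expect_equal(markov_matrix_II()[3, ], c(A = 0.1, C = 0.4, G = 0.1, T = 0.4))
  expect_equal(markov_matrix_II()[4, ], c(A = 0.1, C = 0.35, G = 0.45, T = 0.1))
})

test_that("stationary_distribution handles uniform, degenerate and invalid chains", {
  expect_equal(unname(stationary_distribution(matrix(0.25, 4, 4))), rep(0.25, 4))
  expect_error(stationary_distribution(diag(4)), "unique")
  bad <- matrix(0.3, 4, 4)
  expect_error(stationary_distribution(bad), "sum to 1")
})

test_that("chunk generation follows the stationary law and the transition rows", {
  set.seed(71)
  proc <- markov_process(markov_matrix_I())
  mu <- proc$stationary
  # single-symbol chunks are distributed as mu
  draws <- vapply(1:8000, function(i) generate_chunk(proc, 1), character(1))
  counts <- table(factor(draws, levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(counts, p = mu)$p.value, 0.001)
  # dinucleotide frequencies of a long chunk match mu(a) M[a,b] within 5 SE
  s <- generate_chunk(proc, 1e5)
  tab <- suppressMessages(scan_pairs(s, scales = 1, min_windows = 1L))
  marg <- tab[!duplicated(tab$X_A), c("X_A", "P_A")]
  expected <- as.vector(t(mu * markov_matrix_I()))
  names(expected) <- as.vector(t(outer(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"), paste0)))
  for (d in names(expected)) {
    p_hat <- marg$P_A[marg$X_A == d]
    se <- sqrt(expected[[d]] * (1 - expected[[d]]) / 1e5)
    # autocorrelation inflates the naive binomial SE only mildly here
    expect_lt(abs(p_hat - expected[[d]]), 5 * 2 * se)
  }
})

test_that("a deterministic cycle matrix yields the deterministic cycle", {
  P <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  P["A", "C"] <- 1; P["C", "G"] <- 1; P["G", "T"] <- 1; P["T", "A"] <- 1
  set.seed(73)
  s <- generate_chunk(markov_process(P), 12)
  # every consecutive transition follows the cycle A->C->G->T->A
  steps <- substring(s, 1:11, 2:12)
  expect_true(all(steps %in% c("AC", "CG", "GT", "TA")))
})

test_that("macrostructures keep whole chunks and log lengths and orientations", {
  set.seed(79)
  cfg <- domain_model_config(macro_length = 2e4)
  proc <- markov_process(markov_matrix_I())
  m <- generate_macrostructure(proc, cfg)
  n <- nchar(m$sequence)
  expect_gte(n, 2e4)
  expect_lt(n, 2e4 + 170)
  expect_equal(sum(m$chunk_log$length), n)
  expect_true(all(m$chunk_log$length >= 130 & m$chunk_log$length <= 170))
  expect_equal(m$chunk_log$start,
               cumsum(c(1L, m$chunk_log$length[-nrow(m$chunk_log)])))
})

test_that("chunk lengths are uniform on [130, 170] and orientations are fair", {
  set.seed(83)
  cfg <- domain_model_config(macro_length = 2e6)
  proc <- markov_process(markov_matrix_I())
  log <- generate_macrostructure(proc, cfg)$chunk_log
  expect_gt(nrow(log), 1e4)
  counts <- table(factor(log$length, levels = 130:170))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # mirrored chunks within 3 binomial SE of one half (symmetric abundance)
  frac <- mean(log$revcomp)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(log)))
})

test_that("orientation extremes reproduce the plain and mirrored processes", {
  M <- markov_matrix_I()
  mu <- stationary_distribution(M)
  expected_plain <- as.vector(t(mu * M))
  # mirrored process: dinucleotide ab appears as often as revcomp(ab) under p
  rc_of <- vapply(1:16, function(k) {
    a <- (k - 1) %/% 4 + 1; b <- (k - 1) %% 4 + 1
    (4 - b) * 4L + (5L - a)  # code of comp(b) comp(a)
  }, numeric(1))
  expected_mirror <- expected_plain[rc_of]
  for (case in list(list(p = 0, want = expected_plain),
                    list(p = 1, want = expected_mirror))) {
    set.seed(89)
    cfg <- domain_model_config(macro_length = 2e5, revcomp_prob = case$p)
    m <- generate_macrostructure(markov_process(M), cfg)
    tab <- suppressMessages(scan_pairs(m$sequence, scales = 1, min_windows = 1L))
    marg <- tab$P_A[!duplicated(tab$X_A)]
    expect_lt(max(abs(marg - case$want)), 0.01)
  }
})

test_that("genomes concatenate one macrostructure per process with ground truth", {
  cfg <- domain_model_config(macro_length = 3e4, seed = 97)
  g <- generate_genome(cfg)
  expect_equal(nchar(g$sequence), sum(g$ground_truth$macro_lengths))
  expect_equal(length(g$ground_truth$chunk_logs), 2L)
  expect_equal(g$ground_truth$boundaries[1], 1)
  expect_equal(g$ground_truth$boundaries[2],
               g$ground_truth$macro_lengths[1] + 1)
  expect_true(grepl("^[ACGT]+$", substr(g$sequence, 1, 1000)))
  expect_equal(g$ground_truth$scales$L_S, 300)
  expect_equal(g$ground_truth$scales$L_M, 3e4)
  # domain correlation scale from the slowest-mixing process is of order 10
  expect_gt(g$ground_truth$scales$L_D, 1)
  expect_lt(g$ground_truth$scales$L_D, 50)

  # reproducibility: same seed, same genome; different seed, different genome
  g2 <- generate_genome(cfg)
  expect_identical(g$sequence, g2$sequence)
  g3 <- generate_genome(domain_model_config(macro_length = 3e4, seed = 98))
  expect_false(identical(g$sequence, g3$sequence))
})
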