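test_that("sigma_at_scale is the population standard deviation of z", {
  tb <- tibble::tibble(seq_label = "t", X_A = c("AA", "AC", "AG", "AT"),
                       X_B = "AA", ell = 2, z = c(1, 1, 1, 3))
  expect_equal(sigma_at_scale(tb, 2), sqrt(0.75))
  expect_error(sigma_at_scale(tb, 4), "not present")
  tb$z <- c(2, 2, 2, 2)
  expect_equal(sigma_at_scale(tb, 2), 0)
  tb$z[1:3] <- NA
  expect_error(suppressMessages(sigma_at_scale(tb, 2)), "at least 2")
})

test_that("symmetry_distance reproduces direct arithmetic on a 2-element closure", {
  # closure of S1 at (CC, TC): partner (GA, GG); z_ref = 1.0, z_partner = 1.2,
  # so d = (0 + (0.2/sigma)^2) / 2 with sigma the population SD of all 256
  z <- rep(1, 256)
  tb <- null_scan_table(z, ell = 4)
  ref_i <- which(tb$X_A == "CC" & tb$X_B == "TC")
  par_i <- which(tb$X_A == "GA" & tb$X_B == "GG")
  tb$z[par_i] <- 1.2
  sig <- sigma_at_scale(tb, 4)
  y <- pair_observable("CC", "TC", 4)
  d <- symmetry_distance(y, "S1", tb, 4)
  expect_equal(d, (0 + (0.2 / sig)^2) / 2)
  # closure-constant z gives distance 0
  tb$z[par_i] <- 1
  tb$z[5] <- 2  # keep sigma positive
  expect_equal(symmetry_distance(y, "S1", tb, 4), 0)
})

test_that("symmetry_distance errors name missing closure members", {
  tb <- null_scan_table(stats::rnorm(256), ell = 4)
  tb <- tb[!(tb$X_A == "GA" & tb$X_B == "GG"), ]
  y <- pair_observable("CC", "TC", 4)
  expect_error(suppressMessages(symmetry_distance(y, "S1", tb, 4)),
               "G1A, G1G")
})

test_that("the index is zero iff z is constant within every closure", {
  # z depending only on the S3 orbit: all four indices must vanish
  orbit_rep <- vapply(dinuc_pair_closures("S3"), min, integer(1))
  set.seed(59)
  orbit_z <- stats::rnorm(256)
  tb <- null_scan_table(orbit_z[orbit_rep], ell = 1)
  cur <- index_curves(tb)
  expect_equal(cur$I, rep(0, 4))
  # breaking one orbit lifts the indices above zero
  tb$z[1] <- tb$z[1] + 1
  cur2 <- index_curves(tb)
  expect_true(all(cur2$I > 0))
})

test_that("index curves are nonnegative and flagged when sigma vanishes", {
  tb <- null_scan_table(rep(2, 256), ell = 8)
  cur <- index_curves(tb)
  expect_true(all(is.na(cur$I)))
  expect_equal(cur$sigma, rep(0, 4))
  set.seed(61)
  tb2 <- null_scan_table(stats::rnorm(256), ell = 8)
  cur2 <- index_curves(tb2)
  expect_true(all(cur2$I >= 0))
  expect_equal(cur2$n_ref, rep(256L, 4))
})

test_that("iid z values give indices near the degeneracy-aware null expectation", {
  # exact null: E[I] = mean over refs of (m-1)/m, times |A|/(|A|-1)
  set.seed(67)
  reps <- 300
  tb <- null_scan_table(stats::rnorm(256 * reps),
                        ell = rep(seq_len(reps), each = 256))
  for (s in c("S1", "S3")) {
    m <- lengths(dinuc_pair_closures(s))
    expect_i <- mean((m - 1) / m) * 256 / 255
    cur <- index_curves(tb, symmetries = s)
    se <- stats::sd(cur$I) / sqrt(reps)
    expect_lt(abs(mean(cur$I) - expect_i), 4 * se)
  }
})

test_that("detect_scales implements first-crossing semantics and boundary cases", {
  mk_curves <- function(I_by_sym) {
    purrr::map_dfr(names(I_by_sym), function(s) {
      tibble::tibble(seq_label = "t", symmetry = s,
                     ell = 2^(0:(length(I_by_sym[[s]]) - 1)),
                     I = I_by_sym[[s]], sigma = 1, n_ref = 256L)
    })
  }
  # all curves below threshold everywhere: L_D = L_S = smallest scale, L_M absent
  flat <- mk_curves(list(S1 = rep(0, 4), S2 = rep(0, 4),
                         S3 = rep(0, 4), S4 = rep(0, 4)))
  sc <- detect_scales(flat)
  expect_equal(sc$value[sc$scale == "L_D"], 1)
  expect_equal(sc$value[sc$scale == "L_S"], 1)
  expect_false(sc$present[sc$scale == "L_M"])

  # staged hierarchy: S2 present from 4, S3 from 8, S1 breaks at 16 with S4 present
  staged <- mk_curves(list(
    S1 = c(0.01, 0.01, 0.01, 0.01, 0.30),
    S2 = c(0.50, 0.30, 0.02, 0.01, 0.30),
    S3 = c(0.60, 0.40, 0.30, 0.02, 0.30),
    S4 = c(0.60, 0.40, 0.30, 0.02, 0.01)
  ))
  sc2 <- detect_scales(staged)
  expect_equal(sc2$value, c(4, 8, 16))

  # raising the threshold never increases L_D or L_S
  for (thr in c(0.05, 0.1, 0.5)) {
    sc3 <- detect_scales(staged, threshold = thr)
    expect_lte(sc3$value[sc3$scale == "L_D"], sc2$value[sc2$scale == "L_D"])
    expect_lte(sc3$value[sc3$scale == "L_S"], sc2$value[sc2$scale == "L_S"])
  }
})

test_that("heatmap intensities follow the 1.05/6.5 interpolation rule", {
  imin <- 0.02
  curves <- tibble::tibble(
    seq_label = "t", symmetry = "S1", ell = 2^(0:4),
    I = c(imin, 1.05 * imin, 6.5 * imin, (1.05 + 6.5) / 2 * imin, 10 * imin),
    sigma = 1, n_ref = 256L
  )
  hm <- heatmap_table(curves)
  expect_equal(hm$intensity[2], 1)
  expect_equal(hm$intensity[3], 0)
  expect_equal(hm$intensity[4], 0.5)
  expect_equal(hm$intensity[1], 1)   # clamped above full color
  expect_equal(hm$intensity[5], 0)   # clamped below white
  # zero minimum: full color exactly at I == 0
  curves$I <- c(0, 0.01, 0, 0.5, 1)
  expect_message(hm0 <- heatmap_table(curves), "I_min is 0")
  expect_equal(hm0$intensity, c(1, 0, 1, 0, 0))
})
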