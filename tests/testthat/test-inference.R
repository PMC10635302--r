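test_that("two-sample test: identical groups give observed 0 and p-value 1", {
  bas <- tiny_basis()
  set.seed(81)
  cs <- random_coeffs(4, bas)
  res <- two_sample_test(c(cs, cs), c(cs, cs), sigma = 0.1, eigenvalues = bas,
                         n_transpositions = 500, seed = 5)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
})

test_that("incremental two-sample statistic equals from-scratch recomputation", {
  bas <- tiny_basis()
  for (sizes in list(c(4, 4), c(5, 8), c(20, 20))) {
    set.seed(sum(sizes))
    cs <- random_coeffs(sum(sizes), bas)
    m <- sizes[1]; n <- sizes[2]
    X <- pdheat:::hk_embed(cs, bas$eigenvalues, 0.1)
    set.seed(99)
    chain <- pdheat:::two_sample_chain_cpp(X, m, n, 800L, 500L, TRUE)
    for (t in seq(1, 800, by = 7)) {
      labA <- chain$labels[t, ]
      expect_equal(chain$trace[t], two_sample_stat_direct(X, labA),
                   tolerance = 1e-9)
    }
    # group sizes conserved at every step
    expect_true(all(rowSums(chain$labels) == m))
  }
})

test_that("T-ANOVA: conservation and oracle equivalence at every step", {
  bas <- tiny_basis()
  set.seed(77)
  cs <- random_coeffs(15, bas)
  D <- pairwise_distance_matrix(cs, 0.1, bas)
  labels0 <- rep(1:3, c(4, 5, 6))
  set.seed(42)
  chain <- pdheat:::tanova_chain_cpp(D, as.integer(labels0), 1200L, 500L, TRUE)
  total <- sum(D[upper.tri(D)])
  # TSSB + TSSW is conserved at every transposition
  expect_equal(chain$tssb + chain$tssw, rep(total, 1200), tolerance = 1e-9)
  # incremental sums match direct recomputation from the relabeled matrix
  for (t in seq(1, 1200, by = 11)) {
    lab <- chain$labels[t, ]
    direct <- tss_direct(D, lab)
    expect_equal(chain$tssb[t], unname(direct["tssb"]), tolerance = 1e-9)
    expect_equal(chain$tssw[t], unname(direct["tssw"]), tolerance = 1e-9)
    expect_equal(chain$phi[t], unname(direct["tssb"] / direct["tssw"]),
                 tolerance = 1e-9)
  }
  # group sizes conserved
  for (t in c(1, 500, 777, 1200))
    expect_equal(unname(table(chain$labels[t, ])), c(4, 5, 6),
                 ignore_attr = TRUE)
})

test_that("t_anova wrapper: invalid designs and a basic null run", {
  bas <- tiny_basis()
  set.seed(5)
  cs <- random_coeffs(9, bas)
  expect_error(t_anova(list(cs[1:4]), eigenvalues = bas), "at least 2 groups")
  expect_error(t_anova(list(cs[1:4], cs[5]), eigenvalues = bas),
               "at least 2 subjects")
  res <- t_anova(list(cs[1:3], cs[4:6], cs[7:9]), sigma = 0.1,
                 eigenvalues = bas, n_transpositions = 2000, seed = 3)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$tssb + res$tssw,
               sum(pairwise_distance_matrix(cs, 0.1, bas)[upper.tri(diag(9))]),
               tolerance = 1e-9)
})

test_that("type-I error of both tests is nominal under an exchangeable null", {
  bas <- tiny_basis()
  set.seed(314)
  n_rep <- 400
  p2 <- numeric(n_rep); p3 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cs <- random_coeffs(12, bas)
    p2[r] <- two_sample_test(cs[1:6], cs[7:12], sigma = 0.1,
                             eigenvalues = bas, n_transpositions = 600)$p_value
    p3[r] <- t_anova(list(cs[1:4], cs[5:8], cs[9:12]), sigma = 0.1,
                     eigenvalues = bas, n_transpositions = 600)$p_value
  }
  # rejection rate at 0.05 within ~3 binomial SEs of nominal
  se3 <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(p2 < 0.05) - 0.05), se3 + 1e-9)
  expect_lt(abs(mean(p3 < 0.05) - 0.05), se3 + 1e-9)
  # approximate uniformity (Kolmogorov distance)
  ks2 <- max(abs(sort(p2) - (seq_len(n_rep)) / n_rep))
  ks3 <- max(abs(sort(p3) - (seq_len(n_rep)) / n_rep))
  expect_lt(ks2, 0.08)
  expect_lt(ks3, 0.08)
  expect_gt(mean(p3), 0.4); expect_lt(mean(p3), 0.6)
})

test_that("PERMANOVA baseline: hand computation, vegan cross-check, power", {
  # 4-subject toy matrix, groups {1,2} vs {3,4}
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 4
  D[1, 3] <- D[3, 1] <- 9; D[1, 4] <- D[4, 1] <- 16
  D[2, 3] <- D[3, 2] <- 25; D[2, 4] <- D[4, 2] <- 36
  res <- permanova_baseline(D, c(1, 1, 2, 2), n_permutations = 200, seed = 1)
  sst <- sum(D[upper.tri(D)]) / 4
  ssw <- 1 / 2 + 4 / 2
  expect_equal(res$ssw, ssw, tolerance = 1e-12)
  expect_equal(res$ssb, sst - ssw, tolerance = 1e-12)
  expect_equal(res$pseudo_f, (sst - ssw) / (ssw / 2), tolerance = 1e-12)

  # vegan::adonis2 as independent oracle (it takes distances, we store
  # squared distances)
  set.seed(8)
  X <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(24, 3), 6))
  D2 <- as.matrix(dist(X))^2
  g <- factor(rep(1:2, c(5, 6)))
  mine <- permanova_baseline(D2, g, n_permutations = 500, seed = 2)
  van <- vegan::adonis2(stats::as.dist(sqrt(D2)) ~ g, permutations = 500)
  expect_equal(mine$pseudo_f, van$F[1], tolerance = 1e-8)
  expect_lt(mine$p_value, 0.05)

  # duplicated rows across groups: no separation
  Xd <- rbind(X[1:4, ], X[1:4, ])
  Dd <- as.matrix(dist(Xd))^2
  resd <- permanova_baseline(Dd, rep(1:2, each = 4), n_permutations = 300,
                             seed = 3)
  expect_gt(resd$p_value, 0.3)
})

test_that("stabilization diagnostics behave as advertised", {
  # constant trace stabilizes right after the window fills
  cst <- stabilization_check(rep(1, 300), observed = 0.5, window = 100,
                             tol = 0.01)
  expect_true(cst$stabilized)
  expect_equal(cst$running_p[300], 1)
  # alternating exceedance converges to 1/2 within tol by a bounded count
  alt <- stabilization_check(rep(c(1, 0), 3000), observed = 0.5,
                             window = 500, tol = 0.01)
  expect_true(alt$stabilized)
  expect_equal(alt$running_p[6000], 0.5, tolerance = 1e-3)
  # tol = 0 never stabilizes a stochastic trace
  set.seed(1)
  sto <- stabilization_check(runif(3000), observed = 0.5, window = 500,
                             tol = 0)
  expect_false(sto$stabilized)
  expect_error(stabilization_check(numeric(0), 1), "empty")
})

test_that("p-values are valid and monotone in the observed statistic", {
  bas <- tiny_basis()
  set.seed(2024)
  cs <- random_coeffs(10, bas)
  res <- two_sample_test(cs[1:5], cs[6:10], sigma = 0.1, eigenvalues = bas,
                         n_transpositions = 2000, seed = 7, return_trace = TRUE)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  tr <- res$trace
  obs_grid <- quantile(tr, c(0.1, 0.5, 0.9))
  pv <- vapply(obs_grid, function(o) (1 + sum(tr >= o)) / (1 + length(tr)), 0)
  expect_true(all(diff(pv) <= 0))
})
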