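test_that("distance metrics satisfy their axioms and hand values", {
  expect_equal(chi_square_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(chi_square_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(chi_square_distance(c(0, 0), c(0, 0)), 0)  # 0/0 terms drop
  expect_error(chi_square_distance(1:3, 1:2), "length")

  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), log(2))
  expect_equal(jensen_shannon_distance(c(2, 5), c(2, 5)), 0)
  expect_error(jensen_shannon_distance(c(0, 0), c(1, 1)), "positive sums")

  for (s in 1:20) {
    set.seed(600 + s)
    x <- stats::rlnorm(10, 3, 1); y <- stats::rlnorm(10, 3, 1)
    expect_equal(chi_square_distance(x, y), chi_square_distance(y, x))
    j <- jensen_shannon_distance(x, y)
    expect_equal(j, jensen_shannon_distance(y, x))
    expect_gte(j, 0)
    expect_lte(j, log(2))
    expect_equal(j, jensen_shannon_distance(10 * x, y))  # scale invariance
  }
})

test_that("copy-number sampling respects its modes and seeds", {
  pool <- c(10, 50, 200, 900, 4000)
  emp <- abundance_distribution(pool = pool)
  expect_identical(sample_copynumbers(emp, 8, 3, seed = 4),
                   sample_copynumbers(emp, 8, 3, seed = 4))
  expect_true(all(unlist(sample_copynumbers(emp, 20, 5, seed = 1)) %in% pool))

  perm <- abundance_distribution(pool = pool, mode = "permute")
  draw <- sample_copynumbers(perm, 5, 4, seed = 2)
  for (v in draw) expect_identical(sort(v), sort(pool))
  expect_error(sample_copynumbers(perm, 4, 1), "pool length")

  par <- abundance_distribution(meanlog = 5, sdlog = 0.8, mode = "lognormal")
  big <- sample_copynumbers(par, 10000, 1, seed = 3)[[1]]
  se <- 0.8 / sqrt(10000)
  expect_lt(abs(mean(log(big)) - 5), 3 * se)
})

test_that("balance significance gives minimal p for balanced input and calibrated nulls", {
  net <- chain_net()
  dist <- abundance_distribution(meanlog = 4, sdlog = 0.8, mode = "lognormal")
  rep <- balance_significance(net, c(A = 50, B = 100, C = 50), dist,
                              n_rand = 99, seed = 7)
  expect_equal(rep$csd, 0)
  expect_equal(rep$jsd, 0, tolerance = 1e-10)
  expect_equal(rep$p_csd, 1 / 100)
  expect_equal(rep$p_jsd, 1 / 100)
  expect_equal(rep$failures, 0)

  # drawing the "real" vector from the null itself: p should be valid
  # (super-uniform); check the empirical CDF at a few thresholds
  n_draw <- 24L
  ps <- vapply(seq_len(n_draw), function(i) {
    cr <- sample_copynumbers(dist, 3, 1, seed = 900 + i)[[1]]
    names(cr) <- c("A", "B", "C")
    balance_significance(net, cr, dist, n_rand = 60, seed = i)$p_jsd
  }, 1.0)
  for (q in c(0.25, 0.5)) {
    binom_sd <- sqrt(q * (1 - q) / n_draw)
    expect_lte(mean(ps <= q), q + 3 * binom_sd)
  }
})

test_that("a dominant outlier protein skews the chi-square distance far more than the JS distance", {
  base <- c(A = 300, B = 320, C = 310, D = 280, E = 305)
  bal <- base
  real <- base; real[["A"]] <- 40 * base[["A"]]  # cofilin-like overexpression
  csd_with <- chi_square_distance(real, bal)
  jsd_with <- jensen_shannon_distance(real, bal)
  csd_without <- chi_square_distance(real[-1], bal[-1])
  jsd_without <- jensen_shannon_distance(real[-1], bal[-1])
  expect_gt(csd_with / (csd_without + 1e-12), 1e3)
  expect_lt(jsd_with, log(2))
  expect_gt(jsd_with, jsd_without)  # affected, but bounded
})
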