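test_that("system matrices have the defining structure", {
  net <- frustrated_net()
  sys <- build_system(net, c(A = 60, B = 40, C = 50))
  expect_equal(unname(colSums(sys$A)), rep(2, 3))
  expect_equal(diag(sys$Z), rep(1, 4))
  # H annihilates exactly the per-protein-equal vectors
  v_eq <- c(1, 7, 7, 3)  # B's two interfaces equal
  expect_equal(drop(sys$H %*% v_eq), rep(0, 4))
  v_neq <- c(1, 7, 6, 3)
  expect_gt(sum((sys$H %*% v_neq)^2), 0)
  expect_gte(min(eigen(sys$H, symmetric = TRUE)$values), -1e-12)
  # c0 replicated per interface
  expect_equal(sys$c0_int, c(60, 40, 40, 50))

  # single protein with one self-edge: A is the 1x1 matrix [2]
  self_net <- iin(data.frame(protein = "A", interface = "i1"),
                  rbind(c(1L, 1L)))
  expect_equal(unname(build_system(self_net, c(A = 10))$A), matrix(2, 1, 1))

  expect_error(build_system(net, c(A = 1, B = 1),
                            constrained = c("A", "B", "C")),
               "absent from c0")
})

test_that("the quadratic form is symmetric positive semidefinite on random systems", {
  for (s in 1:8) {
    set.seed(500 + s)
    n <- sample(5:8, 1)
    net <- generate_goh_iin(n, sample(3:min(8, n * (n - 1) / 2), 1),
                            gamma = 0.4, seed = 500 + s)
    c0 <- stats::setNames(stats::rlnorm(length(net$proteins), 4, 1),
                          net$proteins)
    sys <- build_system(net, c0, alpha = stats::runif(1, 0.01, 2))
    Q <- 2 * sys$alpha * t(sys$A) %*% sys$Z %*% sys$A +
      2 * t(sys$A) %*% sys$H %*% sys$A
    expect_equal(Q, t(Q))
    expect_gte(min(eigen(Q, symmetric = TRUE)$values), -1e-8 * max(abs(Q)))
  }
})

test_that("already-balanced inputs are recovered exactly, at any alpha", {
  net <- chain_net()
  for (alpha in c(0.01, 0.5, 1, 2)) {
    res <- balance_network(net, c(A = 50, B = 100, C = 50), alpha = alpha)
    expect_equal(unname(protein_copies(res)), c(50, 100, 50), tolerance = 1e-8)
    expect_lt(res$objective, 1e-10)
  }
  # zero input: trivial zero solution
  res0 <- balance_network(net, c(A = 0, B = 0, C = 0))
  expect_equal(unname(res0$x_min), c(0, 0), tolerance = 1e-12)
  expect_equal(res0$objective, 0)
})

test_that("solver matches a brute-force grid oracle on small systems", {
  nets <- list(
    chain_net(),
    frustrated_net(),
    iin(data.frame(protein = c("A", "B"), interface = c("i1", "i1")),
        rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))))
  c0s <- list(c(A = 30, B = 80, C = 20),
              c(A = 55, B = 35, C = 70),
              c(A = 40, B = 90))
  for (k in seq_along(nets)) {
    sys <- build_system(nets[[k]], c0s[[k]], alpha = 1)
    res <- solve_balance(sys)
    oracle <- brute_balance(sys, x_max = 150, steps = 40, refine = 4)
    scale <- max(oracle$objective, 1)
    expect_lt((res$objective - oracle$objective) / scale, 1e-4)
    # forward consistency is exact by construction
    expect_identical(res$c_balanced_int, drop(sys$A %*% res$x_min))
  }
})

test_that("higher alpha pulls the balanced copies closer to the input", {
  net <- frustrated_net()
  c0 <- c(A = 80, B = 30, C = 60)
  alphas <- c(0.01, 0.1, 1, 10)
  fits <- vapply(alphas, function(a) {
    res <- balance_network(net, c0, alpha = a)
    res$fit_distance / a  # the unweighted distance (Ax - C0)' Z (Ax - C0)
  }, 1.0)
  expect_true(all(diff(fits) <= 1e-8))
  # and interface noise does not decrease with alpha
  noises <- vapply(alphas, function(a)
    mean(interface_noise(balance_network(net, c0, alpha = a))), 1.0)
  expect_true(all(diff(noises) >= -1e-10))
})

test_that("perfect-matching networks balance to equal copies under uniform input", {
  # obligate-complex style wiring: disjoint pairs, one interface each
  net <- iin(data.frame(protein = paste0("S", 1:6), interface = rep("i", 6)),
             rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
  res <- balance_network(net, stats::setNames(rep(70, 6), paste0("S", 1:6)))
  expect_equal(unname(protein_copies(res)), rep(70, 6), tolerance = 1e-8)
})

test_that("protein copies, interface noise, and expression ratios follow their definitions", {
  net <- frustrated_net()
  res <- balance_network(net, c(A = 60, B = 40, C = 50))
  fake <- res
  fake$c_balanced_int <- c(100, 200, 300, 0)
  expect_equal(unname(protein_copies(fake)), c(100, 250, 0))
  noise <- interface_noise(fake)
  expect_equal(noise[["B"]], 2500 / 62500)  # sd^2/mu^2 for (200, 300)
  expect_equal(noise[["A"]], 0)             # single interface
  expect_equal(noise[["C"]], 0)             # zero copies, zero variance

  cb <- c(A = 100, B = 250, C = 0)
  cr <- c(A = 4000, B = 250, C = 10)
  ratio <- expression_ratio(cr, cb)
  expect_equal(ratio[["A"]], 40)
  expect_equal(ratio[["B"]], 1)
  expect_true(is.nan(ratio[["C"]]))
  expect_equal(unname(expression_ratio(2 * cr, cb)[c("A", "B")]),
               2 * unname(ratio[c("A", "B")]))
})
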