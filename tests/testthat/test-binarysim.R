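test_that("motif models wire specific edges and make every other pair a misinteraction", {
  tri <- motif_model("triangle", copies = 50)
  expect_equal(sum(tri$pairs$specific), 3L)
  ns <- tri$pairs[!tri$pairs$specific, ]
  expect_equal(nrow(ns), 3L)               # the three self pairs
  expect_true(all(ns$a == ns$b))

  chain <- motif_model("chain")
  sp <- chain$species
  all_pairs <- rbind(t(combn(sp, 2)), cbind(sp, sp))  # brute enumeration
  expect_equal(nrow(chain$pairs), nrow(all_pairs))
  expect_equal(sum(!chain$pairs$specific), nrow(all_pairs) - 2L)

  deg <- motif_model("hub", kd_ratio = 1)
  expect_equal(length(unique(deg$pairs$kd)), 1L)  # degenerate gap
  expect_error(motif_model("triangle", kd_ratio = 0.5), "kd_ratio")
  expect_error(motif_model("pentagon"), "arg")
})

test_that("one reversible pair reaches the closed-form equilibrium and stationary mean", {
  m <- binding_model(c("A", "B"), c(A = 50, B = 50),
                     data.frame(a = "A", b = "B", kd = 0.1))
  res <- simulate_to_steady_state(m, n_runs = 200, seed = 13)
  kd_copies <- 0.1 * 50
  c_eq <- pair_equilibrium(50, 50, kd_copies)
  expect_lt(abs(res$n_specific - c_eq) / c_eq, 0.02)

  # and against the exact birth-death stationary mean at small copy numbers
  m2 <- binding_model(c("A", "B"), c(A = 6, B = 4),
                      data.frame(a = "A", b = "B", kd = 0.2))
  res2 <- simulate_to_steady_state(m2, n_runs = 400, seed = 14)
  exact <- pair_stationary_mean(6, 4, kon = 1 / (0.2 * 50), koff = 1)
  se <- stats::sd(c(0, 1)) # conservative bound; means are window-averaged
  expect_lt(abs(res2$n_specific - exact), max(0.02 * exact, 3 * 1 / sqrt(400)))

  # equilibrium is independent of the dissociation timescale at fixed KD
  fast <- binding_model(c("A", "B"), c(A = 50, B = 50),
                        data.frame(a = "A", b = "B", kd = 0.1), koff = 10)
  res_fast <- simulate_to_steady_state(fast, n_runs = 200, seed = 13,
                                       window = 1)
  expect_lt(abs(res_fast$n_specific - res$n_specific) / c_eq, 0.03)
})

test_that("balanced triangle forms ~25 of each specific complex with minimal misinteraction", {
  res <- simulate_to_steady_state(motif_model("triangle", copies = 50),
                                  n_runs = 300, seed = 5)
  per_edge <- res$pair_counts$mean_count[res$pair_counts$specific]
  expect_true(all(abs(per_edge - 25) < 2))
  expect_lt(binding_cost(res, "complex"), 0.05)
})

test_that("misinteraction cost follows its two definitions and edge conventions", {
  counts <- list(n_specific = 40, n_nonspecific = 10, n_free = 20)
  expect_equal(binding_cost(counts, "complex"), 10 / 60)
  expect_equal(binding_cost(counts, "protein"), 20 / 100)
  none <- list(n_specific = 40, n_nonspecific = 0, n_free = 20)
  expect_equal(binding_cost(none, "complex"), 0)
  zero <- list(n_specific = 0, n_nonspecific = 0, n_free = 0)
  expect_equal(binding_cost(zero, "complex"), 0)
  inf <- list(n_specific = 0, n_nonspecific = 3, n_free = 0)
  expect_equal(binding_cost(inf, "protein"), Inf)
  nofree <- list(n_specific = 30, n_nonspecific = 6, n_free = 0)
  expect_equal(binding_cost(nofree, "complex"), binding_cost(nofree, "protein"))
})

test_that("misinteraction frequency under balance scales linearly with the KD ratio", {
  # abundances large enough that misinteractions are a perturbation (at tens
  # of copies the discrete free pool makes the response superlinear)
  cost_at <- function(ratio)
    binding_cost(simulate_to_steady_state(
      motif_model("hub", copies = c(H = 900, A = 300, B = 300, C = 300),
                  kd_ratio = ratio),
      n_runs = 60, seed = 31), "complex")
  c100 <- cost_at(100)
  c1000 <- cost_at(1000)
  expect_gt(c100, c1000)
  expect_lt(abs(c100 / c1000 - 10) / 10, 0.5)
})

test_that("the cost surface is lowest at balance and symmetric for symmetric motifs", {
  surf <- motif_surface("triangle", variable = c("B", "C"),
                        grid = c(20, 50, 110), fixed_copies = 50,
                        n_runs = 150, seed = 8)
  cost <- surf$cost
  i_bal <- which(surf$x == 1)
  # the balanced point is in the optimal (near-zero-cost) region; the flat
  # valley makes the argmin location itself noise-dominated
  expect_lte(cost[i_bal, i_bal], min(cost) + 0.01)
  # symmetry under swapping the two variable proteins
  expect_lt(max(abs(cost - t(cost))) / max(cost), 0.35)
  # an overexpressed corner self-binds and pays for it
  expect_gt(cost[3, 1], 5 * cost[i_bal, i_bal] + 0.05)
})

test_that("principal-component sensitivity is zero at the optimum and ranks hub above triangle", {
  # synthetic anisotropic paraboloid: the % change curve is exact
  g <- seq(0.2, 1.8, length.out = 9)
  z <- outer(g, g, function(x, y) 1 + 4 * (x - 1)^2 + 0.5 * (y - 1)^2)
  surf <- structure(list(x = g, y = g, cost = z, motif = "synthetic",
                         variable = c("a", "b"), fixed_copies = 50,
                         mode = "complex"), class = "cost_surface")
  sens <- pc_sensitivity(surf)
  expect_equal(sens$curve$pct_change[sens$curve$distance == 0], 0,
               tolerance = 1e-8)
  expect_true(all(sens$curve$pct_change >= -1e-8))
  # the PC of the low-cost region is the soft (y) axis
  expect_gt(abs(sens$direction[2]), abs(sens$direction[1]))

  grid <- c(5, 15, 35, 65, 110)
  sens <- vapply(list(c("hub", "A", "B"), c("square", "B1", "B2"),
                      c("triangle", "B", "C"), c("flag", "A", "B")),
                 function(sp) pc_sensitivity(motif_surface(
                   sp[1], variable = sp[2:3], grid = grid,
                   n_runs = 60, seed = 40 + nchar(sp[1])))$sensitivity,
                 1.0)
  names(sens) <- c("hub", "square", "triangle", "flag")
  # hub and square react most strongly to imbalance; triangle and flag least
  expect_equal(names(which.max(sens)), "hub")
  expect_gt(mean(sens[c("hub", "square")]), mean(sens[c("triangle", "flag")]))
})

test_that("single-interface balancing modes follow the stoichiometry", {
  net <- iin(data.frame(protein = c("A", "B", "C"), interface = rep("i", 3)),
             rbind(c(1L, 2L), c(2L, 3L)))
  eq <- balance_iin_copies(net, mode = "equal-complex", complexes_per_edge = 50)
  expect_equal(unname(eq), c(50, 100, 50))  # proportional to degree
  bal <- balance_iin_copies(net, c0 = c(A = 50, B = 100, C = 50))
  expect_equal(unname(bal), c(50, 100, 50), tolerance = 1e-8)
  bal2 <- balance_iin_copies(net, c0 = c(A = 80, B = 100, C = 40))
  expect_true(all(bal2 >= 0))
  expect_error(balance_iin_copies(frustrated_net(), c0 = c(A = 1, B = 1, C = 1)),
               "single interface")
})

test_that("balancing copies lowers the misinteraction cost of generated networks", {
  nets <- list(generate_goh_iin(12, 14, gamma = 0, seed = 61),
               generate_goh_iin(16, 14, gamma = 0.6, seed = 62))
  dist <- abundance_distribution(meanlog = log(60), sdlog = 0.8,
                                 mode = "lognormal")
  study <- iin_misinteraction_study(nets, dist, n_runs = 30, n_samples = 2,
                                    seed = 17, copies_per_uM = 50)
  expect_true(all(study$cost_balanced <= study$cost_random))
  expect_true(all(study$sensitivity >= 1))
})
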