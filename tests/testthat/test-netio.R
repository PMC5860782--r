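test_that("network TSV reading validates, collapses duplicates, and keeps self-edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\ti1\tB\ti1", "B\ti2\tC\ti1", "C\ti1\tA\ti1"), f)
  net <- read_iin(f)
  expect_s3_class(net, "iin")
  expect_length(net$proteins, 3L)
  expect_equal(nrow(net$interfaces), 4L)
  expect_equal(nrow(net$edges), 3L)

  # duplicate edge lines collapse to one edge
  writeLines(c("A\ti1\tB\ti1", "B\ti1\tA\ti1"), f)
  expect_equal(nrow(read_iin(f)$edges), 1L)

  # minimal self-interaction network
  writeLines("A\ti1\tA\ti1", f)
  self_net <- read_iin(f)
  expect_equal(nrow(self_net$edges), 1L)
  expect_equal(self_net$edges[1, 1], self_net$edges[1, 2])

  # malformed line reported with its line number
  writeLines(c("A\ti1\tB\ti1", "B\ti1\tC"), f)
  expect_error(read_iin(f), "line 2")
})

test_that("network writing is byte-stable and round-trips", {
  net <- iin(data.frame(protein = c("B", "A", "A"),
                        interface = c("i1", "i2", "i1")),
             rbind(c(1L, 2L), c(3L, 3L), c(1L, 3L)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_iin(net, f1)
  back <- read_iin(f1)
  write_iin(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # self-edge emitted exactly once
  expect_equal(sum(grepl("A\ti1\tA\ti1", readLines(f1))), 1L)
  # edge sets agree after the round trip
  key <- function(n) {
    k <- interface_keys(n)
    sort(paste(pmin(k[n$edges[, 1]], k[n$edges[, 2]]),
               pmax(k[n$edges[, 1]], k[n$edges[, 2]])))
  }
  expect_identical(key(net), key(back))
})

test_that("network constructor enforces its invariants", {
  ifc <- data.frame(protein = "A", interface = "i1")
  expect_error(iin(ifc, matrix(numeric(0), 0, 2)), "at least one edge")
  expect_error(iin(ifc, rbind(c(1L, 2L))), "undeclared")
  expect_error(iin(ifc, rbind(c(1L, 1L), c(1L, 1L))), "duplicate")
})

test_that("static-model generator hits the requested size, is seeded, and gamma fattens the tail", {
  net <- generate_goh_iin(150, 150, gamma = 0, seed = 11)
  expect_equal(nrow(net$edges), 150L)
  deg <- tabulate(net$edges, nbins = 150L)
  expect_equal(sum(deg), 300L)  # degree sum = 2 * edges
  expect_identical(generate_goh_iin(40, 60, gamma = 0.5, seed = 3)$edges,
                   generate_goh_iin(40, 60, gamma = 0.5, seed = 3)$edges)
  expect_error(generate_goh_iin(5, 100), "distinct node pairs")

  # Erdos-Renyi case: mean degree 2, degree variance near binomial
  reps <- 40L
  means <- vars <- maxs0 <- maxs8 <- numeric(reps)
  for (r in seq_len(reps)) {
    d0 <- tabulate(generate_goh_iin(150, 150, 0, seed = 100 + r)$edges, 150L)
    d8 <- tabulate(generate_goh_iin(150, 150, 0.8, seed = 100 + r)$edges, 150L)
    means[r] <- mean(d0); vars[r] <- stats::var(d0)
    maxs0[r] <- max(d0); maxs8[r] <- max(d8)
  }
  expect_equal(mean(means), 2, tolerance = 1e-8)
  # ER oracle: degree ~ Binomial(n-1, p), variance ~ 2 for mean 2
  expect_lt(abs(mean(vars) - 2), 0.35)
  # heavier tail under preferential weights
  expect_gt(mean(maxs8), mean(maxs0) + 1)
})

test_that("motif counts match brute-force subgraph enumeration", {
  tri <- iin(data.frame(protein = paste0("P", 1:3), interface = rep("i", 3)),
             rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  expect_equal(count_motifs(tri)[["triangle"]], 1)
  expect_equal(count_motifs(tri)[["chain"]], 0)

  cyc <- iin(data.frame(protein = paste0("P", 1:4), interface = rep("i", 4)),
             rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L)))
  expect_equal(count_motifs(cyc)[["square"]], 1)
  expect_equal(count_motifs(cyc)[["triangle"]], 0)

  flag <- iin(data.frame(protein = paste0("P", 1:4), interface = rep("i", 4)),
              rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(3L, 4L)))
  expect_equal(count_motifs(flag)[["flag"]], 1)
  expect_equal(count_motifs(flag), brute_motifs(flag))

  for (s in 1:12) {
    set.seed(400 + s)
    n <- sample(5:8, 1)
    e <- sample(4:min(12, n * (n - 1) / 2), 1)
    net <- generate_goh_iin(n, e, gamma = 0.3, seed = 400 + s)
    expect_equal(count_motifs(net), brute_motifs(net),
                 info = sprintf("seed %d", 400 + s))
  }
})

test_that("interface rewiring preserves the parent protein network and interface degrees", {
  net <- iin(data.frame(protein = c("A", "A", "B", "B", "C", "D"),
                        interface = c("i1", "i2", "i1", "i2", "i1", "i1")),
             rbind(c(1L, 3L), c(2L, 5L), c(4L, 6L), c(1L, 6L), c(2L, 4L)))
  out <- rewire(net, "interfaces", iters = 300, seed = 5)
  expect_identical(parent_ppin(out), parent_ppin(net))
  expect_identical(out$interfaces, net$interfaces)
  expect_equal(nrow(out$edges), nrow(net$edges))
  deg <- function(n) tabulate(n$edges, nbins = nrow(n$interfaces))
  expect_identical(deg(out), deg(net))
  expect_identical(rewire(net, "interfaces", iters = 300, seed = 5)$edges,
                   out$edges)
})

test_that("topology optimization lowers its motif objective and preserves edge count", {
  net <- generate_goh_iin(40, 60, gamma = 0, seed = 21)
  objective <- function(n) {
    cnt <- count_motifs(n)
    cnt[["chain"]] + cnt[["triangle"]] - cnt[["square"]] - cnt[["hub"]]
  }
  out <- rewire(net, "topology", iters = 150, seed = 9)
  expect_equal(nrow(out$edges), nrow(net$edges))
  expect_lte(objective(out), objective(net))
  expect_error(rewire(net, "topology", iters = 0), "positive")
  expect_identical(rewire(net, "topology", iters = 50, seed = 2)$edges,
                   rewire(net, "topology", iters = 50, seed = 2)$edges)
})
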