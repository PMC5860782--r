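# Independent oracles used across the suite. These deliberately use naive
# enumeration / dense grids, not the package's own algorithms.

# Brute-force motif counts by subset enumeration (networks up to ~8 nodes).
brute_motifs <- function(net) {
  n <- nrow(net$interfaces)
  A <- matrix(0L, n, n)
  e <- net$edges[net$edges[, 1] != net$edges[, 2], , drop = FALSE]
  A[e] <- 1L
  A[e[, 2:1, drop = FALSE]] <- 1L
  adj <- function(i, j) A[i, j] > 0
  tri <- 0; chain <- 0; sq <- 0; hub <- 0; flag <- 0
  if (n >= 3) {
    for (s in utils::combn(n, 3, simplify = FALSE)) {
      i <- s[1]; j <- s[2]; k <- s[3]
      ne <- adj(i, j) + adj(i, k) + adj(j, k)
      if (ne == 3) tri <- tri + 1
      # chains: count per center vertex with non-adjacent endpoints
      if (adj(i, j) && adj(i, k) && !adj(j, k)) chain <- chain + 1
      if (adj(j, i) && adj(j, k) && !adj(i, k)) chain <- chain + 1
      if (adj(k, i) && adj(k, j) && !adj(i, j)) chain <- chain + 1
      # hubs: 3-star centered at any vertex adjacent to the other three --
      # needs 4 nodes; handled below
    }
  }
  if (n >= 4) {
    for (s in utils::combn(n, 4, simplify = FALSE)) {
      # 4-cycles within the subset (each cycle counted once)
      perms <- list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4))
      for (p in perms) {
        v <- s[p]
        if (adj(v[1], v[2]) && adj(v[2], v[3]) &&
            adj(v[3], v[4]) && adj(v[4], v[1])) sq <- sq + 1
      }
      # flags: (triangle, pendant edge) configurations inside the subset
      for (center in 1:4) {
        t3 <- s[-center]
        if (adj(t3[1], t3[2]) && adj(t3[1], t3[3]) && adj(t3[2], t3[3])) {
          for (v in t3) if (adj(v, s[center])) flag <- flag + 1
        }
      }
    }
    for (v in 1:n) {
      d <- sum(A[v, ])
      if (d >= 3) hub <- hub + choose(d, 3)
    }
  } else if (n >= 1) {
    for (v in 1:n) {
      d <- sum(A[v, ])
      if (d >= 3) hub <- hub + choose(d, 3)
    }
  }
  c(chain = chain, triangle = tri, square = sq, hub = hub, flag = flag)
}

# Dense-grid search of the balance objective over x >= 0 (<= 3 edges).
brute_balance <- function(sys, x_max = NULL, steps = 60L, refine = 3L) {
  A <- sys$A
  obj <- function(x) {
    cx <- drop(A %*% x)
    r <- cx - sys$c0_int
    sys$alpha * sum(diag(sys$Z) * r^2) + drop(crossprod(cx, sys$H %*% cx))
  }
  m <- ncol(A)
  if (is.null(x_max)) x_max <- max(sys$c0_int, 1) * 1.5
  lo <- rep(0, m); hi <- rep(x_max, m)
  best <- NULL; best_val <- Inf
  for (pass in seq_len(refine)) {
    grids <- lapply(seq_len(m), function(k) seq(lo[k], hi[k], length.out = steps))
    pts <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(pts, 1, obj)
    i <- which.min(vals)
    if (vals[i] < best_val) { best_val <- vals[i]; best <- pts[i, ] }
    span <- (hi - lo) / (steps - 1)
    lo <- pmax(0, best - 2 * span)
    hi <- best + 2 * span
  }
  list(x = best, objective = best_val)
}

# Deterministic mass-action equilibrium for one reversible pair A + B <=> C
# (quadratic root) in copy units.
pair_equilibrium <- function(a0, b0, kd_copies) {
  # c solves (a0 - c)(b0 - c) = kd * c
  roots <- polyroot(c(a0 * b0, -(a0 + b0 + kd_copies), 1))
  c_eq <- Re(roots[abs(Im(roots)) < 1e-8])
  c_eq[c_eq >= 0 & c_eq <= min(a0, b0) + 1e-9][1]
}

# Exact stationary mean of the bounded birth-death chain for one pair:
# state c in 0..min(a0,b0), up-rate kon*(a0-c)*(b0-c), down-rate koff*c.
pair_stationary_mean <- function(a0, b0, kon, koff) {
  cmax <- min(a0, b0)
  w <- numeric(cmax + 1)
  w[1] <- 0  # log-weights
  for (c in seq_len(cmax))
    w[c + 1] <- w[c] + log(kon * (a0 - c + 1) * (b0 - c + 1)) - log(koff * c)
  p <- exp(w - max(w))
  p <- p / sum(p)
  sum((0:cmax) * p)
}

# Small frustrated test network: B has two interfaces, plus a closing edge,
# so no nontrivial solution satisfies all constraints exactly.
frustrated_net <- function() {
  iin(data.frame(protein = c("A", "B", "B", "C"),
                 interface = c("i1", "i1", "i2", "i1")),
      rbind(c(1L, 2L), c(3L, 4L), c(1L, 4L)))
}

chain_net <- function() {
  iin(data.frame(protein = c("A", "B", "C"),
                 interface = c("i1", "i1", "i1")),
      rbind(c(1L, 2L), c(2L, 3L)))
}
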