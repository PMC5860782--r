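#' Count specificity-related motifs in an interface network
#'
#' Counts the five subgraph motifs known to shape binding specificity in
#' interface-interaction networks: chains, triangles, squares, hubs, and
#' flags. Counting conventions (fixed, and matched by the brute-force
#' enumeration used in the test suite):
#'
#' * `chain`: path `i-k-j` of length 2 whose endpoints `i`, `j` are not
#'   adjacent (i.e. the path does not close a triangle); each unordered
#'   endpoint pair/center combination counts once.
#' * `triangle`: 3-clique, counted once per vertex triple.
#' * `square`: 4-cycle (not necessarily induced), counted once per cycle.
#' * `hub`: 3-star centered at a node, i.e. `choose(degree, 3)` summed over
#'   nodes of degree >= 3.
#' * `flag`: a triangle plus a pendant edge from one of its vertices to a
#'   node outside the triangle; counted once per (triangle, pendant edge)
#'   configuration.
#'
#' Self-edges are ignored for motif counting.
#'
#' @param net an [iin] network
#' @return named numeric vector with elements `chain`, `triangle`, `square`,
#'   `hub`, `flag`
#' @examples
#' tri <- generate_goh_iin(10, 15, seed = 42)
#' count_motifs(tri)
#' @export
count_motifs <- function(net) {
  stopifnot(is.iin(net))
  n <- n_interfaces(net)
  A <- matrix(0L, n, n)
  e <- net$edges[net$edges[, 1L] != net$edges[, 2L], , drop = FALSE]
  if (nrow(e)) {
    A[e] <- 1L
    A[e[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  deg <- rowSums(A)
  A2 <- A %*% A
  upper <- upper.tri(A2)
  triangles <- sum(diag(A2 %*% A)) / 6
  chains <- sum(A2[upper] * (1L - A[upper]))
  # each 4-cycle contributes two endpoint pairs with two shared 2-paths
  squares <- sum(choose(A2[upper], 2)) / 2
  hubs <- sum(choose(deg, 3))
  # flags: for each triangle vertex, pendant edges to outside the triangle
  flags <- 0
  if (triangles > 0) {
    nb <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1L]; j <- e[r, 2L]
      common <- intersect(nb[[i]], nb[[j]])
      common <- common[common > j]  # i < j < k ordering avoids duplicates
      for (k in common) {
        if (k <= i) next
        tri <- c(i, j, k)
        flags <- flags + sum(deg[tri] - 2)
        # subtract pendant edges landing back inside the triangle: deg counts
        # the two triangle edges at each vertex; remaining neighbors outside
        # the triple are genuine pendants, neighbors inside are impossible
        # beyond the two triangle partners (simple graph), so no correction.
      }
    }
  }
  c(chain = chains, triangle = triangles, square = squares,
    hub = hubs, flag = flags)
}

#' Rewire an interface network
#'
#' Two modes:
#'
#' * `"interfaces"` generates a random child IIN for the same parent protein
#'   network: the protein-protein edge set and each protein's interface
#'   count are preserved while the assignment of interactions to interfaces
#'   is shuffled (randomizing which interactions are competitive vs
#'   noncompetitive). Each accepted move picks one protein and swaps the
#'   interface attachment of two of its incident edges, preserving every
#'   interface's degree; moves creating duplicate edges are rejected.
#' * `"topology"` runs a greedy Monte Carlo local topology optimization:
#'   random single-edge replacements are accepted when they strictly
#'   decrease the objective
#'   `w[1]*chains + w[2]*triangles - w[3]*squares - w[4]*hubs`,
#'   so chain/triangle motifs are traded for square/hub motifs. Edge count
#'   is preserved, and if the input graph is connected, connectivity is too.
#'
#' @param net an [iin] network
#' @param mode `"interfaces"` or `"topology"`
#' @param iters number of proposed moves (> 0)
#' @param seed optional integer for reproducible rewiring
#' @param weights length-4 positive weights for the topology objective
#' @return a rewired [iin] network
#' @export
rewire <- function(net, mode = c("interfaces", "topology"), iters = 1000L,
                   seed = NULL, weights = c(1, 1, 1, 1)) {
  stopifnot(is.iin(net))
  mode <- match.arg(mode)
  if (iters <= 0L) stop("iters must be positive")
  with_seed(seed, {
    if (mode == "interfaces") rewire_interfaces_(net, iters)
    else rewire_topology_(net, iters, weights)
  })
}

rewire_interfaces_ <- function(net, iters) {
  edges <- net$edges
  prot <- net$interfaces$protein
  by_prot <- split(seq_len(nrow(net$interfaces)), prot)
  multi <- names(by_prot)[vapply(by_prot, length, 1L) >= 2L]
  if (length(multi) == 0L) return(net)  # one interface per protein: nothing to do
  ekey <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  for (it in seq_len(iters)) {
    p <- multi[sample.int(length(multi), 1L)]
    ifs <- by_prot[[p]]
    # endpoints of edges incident to protein p, as (edge row, column) slots
    hit <- which(matrix(prot[edges] == p, nrow(edges), 2L), arr.ind = TRUE)
    if (nrow(hit) < 2L) next
    pick <- sample.int(nrow(hit), 2L)
    s1 <- hit[pick[1L], ]; s2 <- hit[pick[2L], ]
    i1 <- edges[s1[1L], s1[2L]]; i2 <- edges[s2[1L], s2[2L]]
    if (i1 == i2) next
    cand <- edges
    cand[s1[1L], s1[2L]] <- i2
    cand[s2[1L], s2[2L]] <- i1
    keys <- ekey(cand)
    if (anyDuplicated(keys)) next
    edges <- cand
  }
  iin(net$interfaces, edges)
}

rewire_topology_ <- function(net, iters, weights) {
  stopifnot(length(weights) == 4L, all(weights > 0))
  obj <- function(cnt)
    weights[1L] * cnt[["chain"]] + weights[2L] * cnt[["triangle"]] -
      weights[3L] * cnt[["square"]] - weights[4L] * cnt[["hub"]]
  cur <- net
  was_connected <- igraph::is_connected(as_igraph_(net))
  cur_obj <- obj(count_motifs(cur))
  n <- n_interfaces(net)
  for (it in seq_len(iters)) {
    edges <- cur$edges
    r <- sample.int(nrow(edges), 1L)
    a <- sample.int(n, 1L); b <- sample.int(n, 1L)
    if (a == b) next
    cand <- edges
    cand[r, ] <- c(min(a, b), max(a, b))
    if (anyDuplicated(paste(cand[, 1L], cand[, 2L]))) next
    cand_net <- iin(cur$interfaces, cand)
    if (was_connected && !igraph::is_connected(as_igraph_(cand_net))) next
    cand_obj <- obj(count_motifs(cand_net))
    if (cand_obj < cur_obj) {
      cur <- cand_net
      cur_obj <- cand_obj
    }
  }
  cur
}

as_igraph_ <- function(net) {
  igraph::graph_from_edgelist(net$edges, directed = FALSE)
}
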