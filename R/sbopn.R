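#' Build the stoichiometric balance system for a network
#'
#' Constructs the matrices of the balance optimization problem
#' \deqn{\min_x\; \alpha (Ax - C_0)^T Z (Ax - C_0) + (Ax)^T H (Ax), \quad x \ge 0}
#' for an interface-resolved network:
#'
#' * `A` (interfaces x edges): `A[i, j] = 1` if interface `i` participates in
#'   pairwise interaction `j`, `2` for a self-interaction, else 0. Every
#'   column sums to 2 (each pairwise complex consumes two interface copies).
#' * `H`: block matrix with one complete-graph Laplacian block per protein
#'   (diagonal `k_p - 1`, off-diagonal `-1` among the `k_p` interfaces of
#'   protein `p`), permuted to interface order. `H v = 0` exactly when `v`
#'   assigns equal values to all interfaces of each protein, and
#'   `v' H v >= 0` always, so the second term penalizes unequal interface
#'   copies within a protein.
#' * `Z`: 0/1 diagonal selector of constrained interfaces (all interfaces of
#'   every constrained protein). The identity when all proteins are
#'   constrained.
#' * `c0_int`: the protein-level input copies `c0` replicated to each
#'   interface row.
#'
#' `x` is the vector of desired pairwise complexes, one entry per edge;
#' `alpha` weighs fidelity to the observed copies `c0` against equality of
#' interface copies within proteins.
#'
#' @param net an [iin] network
#' @param c0 named nonnegative numeric vector of input protein copy numbers
#'   (molecules/cell), named by protein id; must cover every constrained
#'   protein
#' @param constrained character vector of constrained protein ids
#'   (default: all proteins appearing in `names(c0)`)
#' @param alpha positive scalar weight for the copy-number fidelity term
#' @return an object of class `stoich_system` with elements `A`, `H`, `Z`,
#'   `c0_int`, `alpha`, `net`
#' @examples
#' net <- read_iin(system.file("extdata", "toy_balanced.tsv",
#'                             package = "stoichbal"))
#' sys <- build_system(net, c(A = 50, B = 100, C = 50))
#' colSums(sys$A)  # every pairwise complex consumes two interface copies
#' @export
build_system <- function(net, c0, constrained = names(c0), alpha = 1) {
  stopifnot(is.iin(net), alpha > 0)
  if (is.null(names(c0)) || any(!nzchar(names(c0))))
    stop("c0 must be named by protein id")
  if (any(c0 < 0)) stop("copy numbers must be nonnegative")
  missing_c0 <- setdiff(constrained, names(c0))
  if (length(missing_c0))
    stop("constrained protein(s) absent from c0: ",
         paste(missing_c0, collapse = ", "))
  unknown <- setdiff(constrained, net$proteins)
  if (length(unknown))
    stop("constrained protein(s) not in network: ",
         paste(unknown, collapse = ", "))
  n_int <- n_interfaces(net)
  m_edge <- n_edges(net)
  A <- matrix(0, n_int, m_edge)
  for (j in seq_len(m_edge)) {
    a <- net$edges[j, 1L]; b <- net$edges[j, 2L]
    if (a == b) A[a, j] <- 2 else A[cbind(c(a, b), j)] <- 1
  }
  prot <- net$interfaces$protein
  H <- matrix(0, n_int, n_int)
  for (s in split(seq_len(n_int), prot)) {
    k <- length(s)
    if (k > 1L) H[s, s] <- diag(k, k) - 1
  }
  z <- as.numeric(prot %in% constrained)
  c0_int <- ifelse(z > 0, unname(c0[prot]), 0)
  c0_int[is.na(c0_int)] <- 0
  rownames(A) <- interface_keys(net)
  colnames(A) <- edge_keys(net)
  structure(list(A = A, H = H, Z = diag(z, n_int), c0_int = c0_int,
                 alpha = alpha, net = net),
            class = "stoich_system")
}

edge_keys <- function(net) {
  k <- interface_keys(net)
  paste(k[net$edges[, 1L]], k[net$edges[, 2L]], sep = "--")
}

#' @export
print.stoich_system <- function(x, ...) {
  cat(sprintf("Stoichiometric system: %d interfaces, %d pairwise complexes, alpha = %g\n",
              nrow(x$A), ncol(x$A), x$alpha))
  invisible(x)
}

# Difference-operator factorization of H: rows (e_i - e_j) over all interface
# pairs within each protein, so that t(M) %*% M == H.
h_factor_ <- function(net) {
  prot <- net$interfaces$protein
  n_int <- length(prot)
  rows <- list()
  for (s in split(seq_len(n_int), prot)) {
    k <- length(s)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      r <- numeric(n_int); r[s[i]] <- 1; r[s[j]] <- -1
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) matrix(0, 0L, n_int) else do.call(rbind, rows)
}

#' Solve the balance quadratic program
#'
#' Minimizes the convex objective of [build_system()] subject to `x >= 0`.
#' Because both terms are squared seminorms, the problem is recast exactly as
#' nonnegative least squares
#' \deqn{\min_{x \ge 0} \| B x - b \|^2, \quad
#'       B = \begin{pmatrix}\sqrt{\alpha} Z^{1/2} A \\ M A\end{pmatrix},}
#' with `t(M) %*% M = H`, and solved with the deterministic Lawson-Hanson
#' active-set algorithm ([pracma::lsqnonneg()]). When `B` is rank-deficient
#' (the quadratic form has a null space, so optima are non-unique) a tiny
#' ridge augmentation selects the approximately minimum-norm minimizer and
#' the result is flagged `degenerate`.
#'
#' @param sys a `stoich_system` from [build_system()]
#' @return an object of class `balance_result`: `x_min` (desired pairwise
#'   complexes per edge), `c_balanced_int` (`A %*% x_min`, balanced interface
#'   copies), `objective` (value of the original objective at the optimum),
#'   `fit_distance` (the `alpha`-weighted distance term alone),
#'   `degenerate`, `alpha`, and the network.
#' @examples
#' net <- read_iin(system.file("extdata", "toy_balanced.tsv",
#'                             package = "stoichbal"))
#' res <- solve_balance(build_system(net, c(A = 50, B = 100, C = 50)))
#' protein_copies(res)  # already balanced: recovers the input
#' @export
solve_balance <- function(sys) {
  stopifnot(inherits(sys, "stoich_system"))
  A <- sys$A
  sq_z <- sqrt(diag(sys$Z))
  M <- h_factor_(sys$net)
  B <- rbind(sqrt(sys$alpha) * (sq_z * A),
             if (nrow(M)) M %*% A else NULL)
  b <- c(sqrt(sys$alpha) * sq_z * sys$c0_int, numeric(nrow(M)))
  degenerate <- qr(B)$rank < ncol(B)
  if (degenerate) {
    lam <- sqrt(1e-10 * max(colSums(B^2), 1e-12))
    B <- rbind(B, diag(lam, ncol(A)))
    b <- c(b, numeric(ncol(A)))
  }
  fit <- tryCatch(pracma::lsqnonneg(B, b),
                  error = function(e)
                    stop("balance QP solver failed: ", conditionMessage(e)))
  x <- pmax(fit$x, 0)
  names(x) <- colnames(A)
  c_int <- drop(A %*% x)
  resid <- c_int - sys$c0_int
  fit_distance <- sys$alpha * sum(diag(sys$Z) * resid^2)
  objective <- fit_distance + drop(crossprod(c_int, sys$H %*% c_int))
  structure(list(x_min = x, c_balanced_int = c_int, objective = objective,
                 fit_distance = fit_distance, degenerate = degenerate,
                 alpha = sys$alpha, net = sys$net, c0_int = sys$c0_int,
                 Z = diag(sys$Z)),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("Balance solution: objective %.6g%s\n", x$objective,
              if (x$degenerate) " (degenerate optimum, minimum-norm x)" else ""))
  print(round(protein_copies(x), 3))
  invisible(x)
}

#' Balanced protein copy numbers
#'
#' The balanced copy number of a protein is the arithmetic mean of the
#' balanced copy numbers assigned to its interfaces.
#'
#' @param res a `balance_result` from [solve_balance()]
#' @return named numeric vector of balanced protein copies, in network
#'   protein order
#' @export
protein_copies <- function(res) {
  stopifnot(inherits(res, "balance_result"))
  prot <- res$net$interfaces$protein
  out <- tapply(res$c_balanced_int, prot, mean)
  out <- as.numeric(out[res$net$proteins])
  names(out) <- res$net$proteins
  out
}

#' Interface copy-number noise per protein
#'
#' Noise is the population variance of the copy numbers assigned to the
#' interfaces of a protein divided by the square of their mean
#' (sigma^2/mu^2). Single-interface proteins have zero noise by definition;
#' a protein whose interfaces average zero copies but vary reports infinite
#' noise.
#'
#' @param res a `balance_result` from [solve_balance()]
#' @return named numeric vector, one entry per protein
#' @export
interface_noise <- function(res) {
  stopifnot(inherits(res, "balance_result"))
  prot <- res$net$interfaces$protein
  noise1 <- function(v) {
    if (length(v) < 2L) return(0)
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    if (mu == 0) { if (s2 == 0) 0 else Inf } else s2 / mu^2
  }
  out <- vapply(split(res$c_balanced_int, prot), noise1, 1.0)
  out <- out[res$net$proteins]
  names(out) <- res$net$proteins
  out
}

#' Expression ratio of observed to balanced copy numbers
#'
#' The per-protein ratio `c_real / c_balanced`. Values above 1 flag proteins
#' overexpressed relative to the stoichiometric demand of the network,
#' values below 1 underexpressed. Proteins with zero balanced copies have an
#' undefined ratio, reported as `NaN`.
#'
#' @param c_real named numeric vector of observed protein copies
#' @param c_balanced named numeric vector of balanced protein copies (e.g.
#'   from [protein_copies()])
#' @return named numeric vector of ratios over the shared protein set
#' @export
expression_ratio <- function(c_real, c_balanced) {
  if (is.null(names(c_real)) || is.null(names(c_balanced)))
    stop("both vectors must be named by protein id")
  shared <- intersect(names(c_real), names(c_balanced))
  if (length(shared) == 0L) stop("no shared proteins")
  num <- c_real[shared]
  den <- c_balanced[shared]
  out <- ifelse(den == 0, NaN, num / den)
  names(out) <- shared
  out
}

#' Balance a network's copy numbers in one call
#'
#' Convenience wrapper: builds the system with [build_system()], solves it
#' with [solve_balance()], and returns the result.
#'
#' @inheritParams build_system
#' @return a `balance_result`
#' @export
balance_network <- function(net, c0, constrained = names(c0), alpha = 1) {
  solve_balance(build_system(net, c0, constrained = constrained, alpha = alpha))
}
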