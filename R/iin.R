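#' Interface-interaction networks
#'
#' An interface-interaction network (IIN) refines a protein-protein
#' interaction network (PPIN) by resolving which binding interface each
#' protein uses for each interaction. Nodes of the IIN are interfaces, each
#' belonging to exactly one protein; edges are binding interactions between
#' interfaces. Two interactions sharing an interface are competitive; using
#' distinct interfaces on a protein they are noncompetitive. Self-edges
#' (an interface binding a copy of itself, e.g. homodimerization) are
#' allowed.
#'
#' @param interfaces data.frame with character columns `protein` and
#'   `interface`; one row per interface. Interface ids are scoped to their
#'   protein, so `i1` on protein A and `i1` on protein B are distinct nodes.
#' @param edges two-column integer matrix (or data.frame) of interface row
#'   indices into `interfaces`; one row per undirected edge. Self-edges have
#'   both entries equal.
#' @return An object of class `iin`, a list with elements `proteins`
#'   (character), `interfaces` (data.frame `protein`, `interface`), and
#'   `edges` (M x 2 integer matrix, each row sorted, rows unique).
#' @examples
#' net <- iin(
#'   interfaces = data.frame(protein = c("A", "B", "B", "C"),
#'                           interface = c("i1", "i1", "i2", "i1")),
#'   edges = rbind(c(1, 2), c(3, 4))
#' )
#' net
#' @export
iin <- function(interfaces, edges) {
  stopifnot(is.data.frame(interfaces),
            all(c("protein", "interface") %in% names(interfaces)))
  interfaces <- data.frame(protein = as.character(interfaces$protein),
                           interface = as.character(interfaces$interface),
                           stringsAsFactors = FALSE)
  key <- paste(interfaces$protein, interfaces$interface, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (protein, interface) declarations")
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("edges must have two columns")
  n_int <- nrow(interfaces)
  if (n_int < 1L) stop("network must have at least one interface")
  if (nrow(edges) < 1L) stop("network must have at least one edge")
  if (any(edges < 1L) || any(edges > n_int))
    stop("edge endpoint refers to an undeclared interface")
  edges <- t(apply(edges, 1L, sort))
  dimnames(edges) <- NULL
  if (anyDuplicated(edges))
    stop("duplicate edges are not allowed")
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  net <- structure(
    list(proteins = unique(interfaces$protein),
         interfaces = interfaces,
         edges = edges),
    class = "iin")
  net
}

#' @export
print.iin <- function(x, ...) {
  cat(sprintf("Interface-interaction network: %d proteins, %d interfaces, %d edges\n",
              length(x$proteins), nrow(x$interfaces), nrow(x$edges)))
  invisible(x)
}

#' @rdname iin
#' @param x object to test or print
#' @export
is.iin <- function(x) inherits(x, "iin")

n_interfaces <- function(net) nrow(net$interfaces)
n_edges <- function(net) nrow(net$edges)

#' Interface labels of an IIN
#'
#' @param net an [iin] network
#' @return character vector `protein.interface`, one entry per interface, in
#'   the network's interface order.
#' @export
interface_keys <- function(net) {
  paste(net$interfaces$protein, net$interfaces$interface, sep = ".")
}

#' Project an IIN onto its parent protein-protein network
#'
#' Collapses interfaces onto their proteins. The result is the set of
#' unordered protein pairs that share at least one interface-level edge
#' (self-pairs retained for homo-interactions).
#'
#' @param net an [iin] network
#' @return two-column character matrix of protein pairs, rows sorted and
#'   unique.
#' @export
parent_ppin <- function(net) {
  pa <- net$interfaces$protein[net$edges[, 1L]]
  pb <- net$interfaces$protein[net$edges[, 2L]]
  pairs <- cbind(pmin(pa, pb), pmax(pa, pb))
  unique(pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE])
}

#' Read an interface-interaction network from a TSV file
#'
#' The file dialect is four whitespace/tab-separated columns per line:
#' `protein_a interface_a protein_b interface_b`, one binding interaction per
#' line. Lines starting with `#` (and blank lines) are ignored; duplicate
#' edge lines collapse to a single edge. A self-interaction is a line whose
#' two (protein, interface) tokens are identical.
#'
#' @param path file path
#' @return an [iin] network
#' @seealso [write_iin()]
#' @export
read_iin <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no edge lines in ", path)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected 4 columns, got %d",
                 keep[bad[1L]], path, length(toks[[bad[1L]]])))
  m <- do.call(rbind, toks)
  ikey <- unique(rbind(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE]))
  ikey <- ikey[order(ikey[, 1L], ikey[, 2L]), , drop = FALSE]
  interfaces <- data.frame(protein = ikey[, 1L], interface = ikey[, 2L],
                           stringsAsFactors = FALSE)
  lookup <- function(p, i)
    match(paste(p, i, sep = "\r"), paste(ikey[, 1L], ikey[, 2L], sep = "\r"))
  e <- cbind(lookup(m[, 1L], m[, 2L]), lookup(m[, 3L], m[, 4L]))
  e <- unique(t(apply(e, 1L, sort)))
  iin(interfaces, e)
}

#' Write an interface-interaction network to a TSV file
#'
#' Output is byte-stable: interfaces are ordered lexicographically by protein
#' then interface id, edges are emitted in that canonical order, and each
#' edge (including self-edges) appears exactly once.
#'
#' @param net an [iin] network
#' @param path output file path
#' @return invisibly, `path`
#' @seealso [read_iin()]
#' @export
write_iin <- function(net, path) {
  stopifnot(is.iin(net))
  ifc <- net$interfaces
  ord <- order(ifc$protein, ifc$interface)
  rank <- match(seq_len(nrow(ifc)), ord)
  a <- rank[net$edges[, 1L]]
  b <- rank[net$edges[, 2L]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  eord <- order(lo, hi)
  lines <- sprintf("%s\t%s\t%s\t%s",
                   ifc$protein[ord][lo[eord]], ifc$interface[ord][lo[eord]],
                   ifc$protein[ord][hi[eord]], ifc$interface[ord][hi[eord]])
  writeLines(c("# protein_a\tinterface_a\tprotein_b\tinterface_b", lines), path)
  invisible(path)
}

# Run code under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random interface network with the static (fitness) model
#'
#' Samples a random graph in which node `i` (of `n_nodes`) carries weight
#' proportional to `i^-gamma`; edges are drawn between distinct nodes with
#' probability proportional to the product of their weights, and redrawn
#' until `n_edges` unique edges exist. `gamma = 0` gives an Erdos-Renyi
#' (binomial) graph; as `gamma` approaches 1 the degree distribution becomes
#' power-law like ("scale-free"). Each node is an interface on its own
#' protein, so the protein network coincides with the interface network.
#'
#' @param n_nodes number of nodes (proteins = interfaces)
#' @param n_edges number of unique edges to place (no self-edges)
#' @param gamma weight exponent in `[0, 1)`
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is untouched
#' @param max_tries sampling attempts before giving up
#' @return an [iin] network with one interface per protein
#' @examples
#' net <- generate_goh_iin(20, 25, gamma = 0.5, seed = 1)
#' count_motifs(net)
#' @export
generate_goh_iin <- function(n_nodes, n_edges, gamma = 0, seed = NULL,
                             max_tries = 200L * n_edges + 10000L) {
  stopifnot(n_nodes >= 2L, n_edges >= 1L, gamma >= 0, gamma < 1)
  if (n_edges > n_nodes * (n_nodes - 1L) / 2L)
    stop("n_edges exceeds the number of distinct node pairs")
  with_seed(seed, {
    w <- seq_len(n_nodes)^(-gamma)
    seen <- new.env(hash = TRUE, size = 2L * n_edges)
    got <- 0L; tries <- 0L
    out <- matrix(0L, n_edges, 2L)
    while (got < n_edges) {
      k <- min(4L * (n_edges - got) + 16L, max_tries - tries)
      if (k <= 0L)
        stop("could not place the requested number of unique edges")
      a <- sample.int(n_nodes, k, replace = TRUE, prob = w)
      b <- sample.int(n_nodes, k, replace = TRUE, prob = w)
      for (j in seq_len(k)) {
        if (a[j] == b[j]) next
        key <- paste0(min(a[j], b[j]), "_", max(a[j], b[j]))
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        out[got, ] <- c(min(a[j], b[j]), max(a[j], b[j]))
        if (got == n_edges) break
      }
      tries <- tries + k
    }
    nm <- sprintf("P%03d", seq_len(n_nodes))
    iin(data.frame(protein = nm, interface = rep("i1", n_nodes),
                   stringsAsFactors = FALSE),
        out)
  })
}
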