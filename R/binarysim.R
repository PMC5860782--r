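#' Competitive binary binding models
#'
#' A binding model lists species (interfaces, one per protein, all binding
#' competitive), their copy numbers, and every allowed unordered species
#' pair classified as either specific (functional) or nonspecific
#' (misinteraction), each with a dissociation constant. Rate constants use a
#' fixed dissociation rate `koff` for every pair, with
#' `kon = koff / KD` after converting `KD` from concentration to copy units
#' via `copies_per_uM` (the effective reaction volume; the default makes 50
#' copies correspond to 1 uM). Absolute volume shifts only the free
#' fraction; misinteraction costs depend mainly on the specific/nonspecific
#' KD ratio.
#'
#' @param species character vector of species names
#' @param copies numeric copies per species (scalar recycled, or named)
#' @param specific data.frame with columns `a`, `b`, `kd` (uM): functional
#'   pairs (`a == b` allowed for homodimers)
#' @param nonspecific data.frame with the same columns: misinteraction pairs
#' @param copies_per_uM copies corresponding to 1 uM
#' @param koff dissociation rate, s^-1, applied to every pair
#' @return an object of class `binding_model`
#' @export
binding_model <- function(species, copies, specific,
                          nonspecific = NULL, copies_per_uM = 50, koff = 1) {
  stopifnot(length(species) >= 1L, !anyDuplicated(species))
  if (length(copies) == 1L) copies <- stats::setNames(rep(copies, length(species)), species)
  if (!is.null(names(copies))) copies <- copies[species]
  stopifnot(length(copies) == length(species), all(copies >= 0))
  norm_pairs <- function(df, spec_flag) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(a = character(), b = character(), kd = numeric(),
                        specific = logical()))
    stopifnot(all(c("a", "b", "kd") %in% names(df)), all(df$kd > 0))
    data.frame(a = pmin(as.character(df$a), as.character(df$b)),
               b = pmax(as.character(df$a), as.character(df$b)),
               kd = df$kd, specific = spec_flag, stringsAsFactors = FALSE)
  }
  pairs <- rbind(norm_pairs(specific, TRUE), norm_pairs(nonspecific, FALSE))
  if (anyDuplicated(pairs[c("a", "b")]))
    stop("each species pair may be specific or nonspecific, not both")
  bad <- !(pairs$a %in% species) | !(pairs$b %in% species)
  if (any(bad)) stop("pair references unknown species")
  structure(list(species = species,
                 copies = as.integer(round(unname(copies))),
                 pairs = pairs, copies_per_uM = copies_per_uM, koff = koff),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Binding model: %d species, %d specific + %d nonspecific pairs\n",
              length(x$species), sum(x$pairs$specific), sum(!x$pairs$specific)))
  invisible(x)
}

#' Binding model for a specificity motif
#'
#' Builds the competitive binding model of one of the five interface-network
#' motifs. The motif edges are the specific interactions (all at `kd_spec`);
#' every remaining unordered species pair, including every self pair, is a
#' nonspecific misinteraction at `kd_spec * kd_ratio`.
#'
#' Motif node/edge sets: `triangle` A-B-C-A; `chain` A-B-C (path);
#' `square` 4-cycle A1-B1-A2-B2; `hub` H bound to A, B, C; `flag` triangle
#' A-B-C plus pendant C-D.
#'
#' @param name motif name
#' @param kd_spec specific dissociation constant, uM (default 1 nM)
#' @param kd_ratio nonspecific/specific KD ratio (>= 1)
#' @param copies copies per species (scalar or named vector)
#' @inheritParams binding_model
#' @return a [binding_model()]
#' @examples
#' m <- motif_model("triangle", copies = 50)
#' m$pairs  # 3 specific pairs, 3 self misinteractions
#' @export
motif_model <- function(name = c("triangle", "chain", "square", "hub", "flag"),
                        kd_spec = 0.001, kd_ratio = 1000, copies = 50,
                        copies_per_uM = 50, koff = 1) {
  name <- match.arg(name)
  if (kd_ratio < 1) stop("kd_ratio must be >= 1")
  def <- switch(name,
    triangle = list(sp = c("A", "B", "C"),
                    ed = rbind(c("A", "B"), c("B", "C"), c("A", "C"))),
    chain = list(sp = c("A", "B", "C"),
                 ed = rbind(c("A", "B"), c("B", "C"))),
    square = list(sp = c("A1", "B1", "A2", "B2"),
                  ed = rbind(c("A1", "B1"), c("B1", "A2"),
                             c("A2", "B2"), c("B2", "A1"))),
    hub = list(sp = c("H", "A", "B", "C"),
               ed = rbind(c("H", "A"), c("H", "B"), c("H", "C"))),
    flag = list(sp = c("A", "B", "C", "D"),
                ed = rbind(c("A", "B"), c("B", "C"), c("A", "C"), c("C", "D"))))
  spec <- data.frame(a = def$ed[, 1L], b = def$ed[, 2L], kd = kd_spec,
                     stringsAsFactors = FALSE)
  all_pairs <- t(utils::combn(def$sp, 2L))
  all_pairs <- rbind(all_pairs, cbind(def$sp, def$sp))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ns_idx <- !(key(all_pairs[, 1L], all_pairs[, 2L]) %in% key(spec$a, spec$b))
  nonspec <- data.frame(a = all_pairs[ns_idx, 1L], b = all_pairs[ns_idx, 2L],
                        kd = kd_spec * kd_ratio, stringsAsFactors = FALSE)
  binding_model(def$sp, copies, spec, nonspec,
                copies_per_uM = copies_per_uM, koff = koff)
}

#' Simulate a binding model to steady state
#'
#' Runs the exact Gillespie algorithm on the association/dissociation
#' network of a [binding_model()]. Each run is declared at steady state when
#' the time-averaged totals of specific complexes, nonspecific complexes,
#' and free proteins drift by less than `rel_tol` between two consecutive
#' averaging windows of length `window` (default ten mean bond lifetimes,
#' `10 / koff`). Reported counts are time averages over the final window,
#' averaged over `n_runs` independent runs seeded from `seed`.
#'
#' @param model a [binding_model()]
#' @param n_runs number of replicate runs
#' @param seed optional integer master seed
#' @param window averaging window, seconds
#' @param rel_tol relative drift threshold between windows
#' @param max_windows cap on windows per run (non-converged runs are counted)
#' @param max_events cap on reaction events per run
#' @return an object of class `cost_result` with mean `n_specific`,
#'   `n_nonspecific`, `n_free`, per-pair mean complex counts
#'   (`pair_counts`), per-species mean free counts, costs in both modes, and
#'   the converged-run count.
#' @examples
#' res <- simulate_to_steady_state(motif_model("triangle", copies = 50),
#'                                 n_runs = 20, seed = 1)
#' res$pair_counts[res$pair_counts$specific, ]
#' @export
simulate_to_steady_state <- function(model, n_runs = 1000L, seed = NULL,
                                     window = 10 / model$koff, rel_tol = 0.01,
                                     max_windows = 60L, max_events = 5e7) {
  stopifnot(inherits(model, "binding_model"), n_runs >= 1L)
  idx <- stats::setNames(seq_along(model$species) - 1L, model$species)
  kd_copies <- model$pairs$kd * model$copies_per_uM
  kon <- model$koff / kd_copies
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  out <- binary_gillespie_cpp(
    length(model$species), model$copies,
    idx[model$pairs$a], idx[model$pairs$b],
    kon, rep(model$koff, nrow(model$pairs)), model$pairs$specific,
    as.integer(n_runs), seeds, window, rel_tol,
    as.integer(max_windows), max_events, TRUE)
  if (!out$conservation_ok)
    stop("molecule conservation violated in simulation")
  pair_counts <- cbind(model$pairs[c("a", "b", "specific")],
                       mean_count = out$mean_complex)
  structure(list(
    n_specific = out$n_specific, n_nonspecific = out$n_nonspecific,
    n_free = out$n_free, pair_counts = pair_counts,
    free_counts = stats::setNames(out$mean_free, model$species),
    n_runs = n_runs, converged_runs = out$converged_runs, seed = seed),
    class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf(paste0("Steady state over %d runs (%d converged):\n",
                     "  specific %.2f  nonspecific %.2f  free %.2f\n",
                     "  cost (complex) %.4g   cost (protein) %.4g\n"),
              x$n_runs, x$converged_runs, x$n_specific, x$n_nonspecific,
              x$n_free, binding_cost(x, "complex"), binding_cost(x, "protein")))
  invisible(x)
}

#' Misinteraction cost of a steady state
#'
#' Complex mode compares numbers of bound states:
#' `N_nonspecific / (N_specific + N_free)`. Protein mode compares numbers of
#' individual proteins in each state:
#' `2 N_nonspecific / (2 N_specific + N_free)`. A zero denominator yields 0
#' when the numerator is zero, otherwise `Inf`.
#'
#' @param counts a `cost_result` from [simulate_to_steady_state()], or a
#'   list/vector with `n_specific`, `n_nonspecific`, `n_free`
#' @param mode `"complex"` or `"protein"`
#' @return nonnegative scalar
#' @export
binding_cost <- function(counts, mode = c("complex", "protein")) {
  mode <- match.arg(mode)
  cs <- as.list(counts)[c("n_specific", "n_nonspecific", "n_free")]
  if (any(vapply(cs, is.null, TRUE))) stop("counts lack the required fields")
  ns <- cs$n_specific; nn <- cs$n_nonspecific; nf <- cs$n_free
  num <- if (mode == "complex") nn else 2 * nn
  den <- if (mode == "complex") ns + nf else 2 * ns + nf
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

#' Misinteraction cost surface over two variable proteins
#'
#' Varies the copy numbers of two species of a motif model over a grid while
#' the remaining species stay at `fixed_copies`, simulating each grid point
#' to steady state and recording the misinteraction cost. Axes are reported
#' normalized by the fixed-protein abundance.
#'
#' @param name motif name (see [motif_model()])
#' @param variable character vector of the two variable species
#' @param grid numeric vector of copy numbers tried for each variable
#'   species
#' @param fixed_copies copy number of the non-variable species
#' @param n_runs runs per grid point
#' @param seed optional master seed
#' @param mode cost mode, see [binding_cost()]
#' @param ... further arguments to [motif_model()]
#' @return object of class `cost_surface`: normalized axes `x`, `y`, cost
#'   matrix `cost` (rows = x), the motif name and settings
#' @export
motif_surface <- function(name, variable = NULL, grid = seq(10, 150, by = 20),
                          fixed_copies = 50, n_runs = 200L, seed = NULL,
                          mode = "complex", ...) {
  template <- motif_model(name, copies = fixed_copies, ...)
  if (is.null(variable))
    variable <- utils::head(template$species, 2L)
  stopifnot(length(variable) == 2L, all(variable %in% template$species))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      length(grid)^2))
  cost <- matrix(NA_real_, length(grid), length(grid))
  k <- 0L
  for (ix in seq_along(grid)) for (iy in seq_along(grid)) {
    k <- k + 1L
    copies <- stats::setNames(rep(fixed_copies, length(template$species)),
                              template$species)
    copies[variable] <- c(grid[ix], grid[iy])
    m <- binding_model(template$species, copies,
                       template$pairs[template$pairs$specific, c("a", "b", "kd")],
                       template$pairs[!template$pairs$specific, c("a", "b", "kd")],
                       copies_per_uM = template$copies_per_uM,
                       koff = template$koff)
    res <- simulate_to_steady_state(m, n_runs = n_runs, seed = seeds[k])
    cost[ix, iy] <- binding_cost(res, mode)
  }
  structure(list(x = grid / fixed_copies, y = grid / fixed_copies,
                 cost = cost, motif = name, variable = variable,
                 fixed_copies = fixed_copies, mode = mode),
            class = "cost_surface")
}

#' Principal-component sensitivity of a cost surface
#'
#' Fits the first principal component of the lowest-cost decile of grid
#' points (the near-balanced region), then follows the line through the
#' surface optimum along that axis and reports the percent change in cost
#' relative to the optimum as a function of normalized distance. The scalar
#' `sensitivity` summarizes the curve as the mean absolute percent change
#' per unit normalized distance. Because a well-balanced motif can drive
#' the optimum cost arbitrarily close to zero, percent changes are taken
#' relative to `max(optimum cost, 2%` of the surface maximum`)`, which keeps
#' the curve finite without affecting surfaces whose optimum cost is
#' appreciable. If the principal axis has no extent inside the grid (an
#' optimum in a corner with the valley running out of the hull), the
#' perpendicular axis is used instead.
#'
#' @param surface a `cost_surface` from [motif_surface()]
#' @param n_steps points sampled along the principal axis (each direction)
#' @param optimum optional `c(x, y)` (normalized units) overriding the grid
#'   minimum as the expansion point, e.g. to study a local minimum
#' @return list with `curve` (data.frame `distance`, `pct_change`),
#'   `direction`, `optimum`, `sensitivity`
#' @export
pc_sensitivity <- function(surface, n_steps = 20L, optimum = NULL) {
  stopifnot(inherits(surface, "cost_surface"))
  z <- surface$cost
  if (max(z) - min(z) <= 0) stop("flat cost surface: sensitivity undefined")
  pts <- expand.grid(x = surface$x, y = surface$y)
  pts$z <- as.vector(z)  # expand.grid varies x fastest = rows of z
  keep <- pts$z <= stats::quantile(pts$z, 0.1)
  low <- pts[keep, c("x", "y")]
  dir <- if (nrow(low) >= 3L && stats::sd(low$x) + stats::sd(low$y) > 0) {
    stats::prcomp(low, center = TRUE, scale. = FALSE)$rotation[, 1L]
  } else c(1, 1) / sqrt(2)
  dir <- dir / sqrt(sum(dir^2))
  if (is.null(optimum)) {
    i0 <- which(z == min(z), arr.ind = TRUE)[1L, ]
    optimum <- c(surface$x[i0[1L]], surface$y[i0[2L]])
  }
  z0 <- interp_surface_(surface, optimum[1L], optimum[2L])
  # signed extent of the line through the optimum within the grid hull
  # (asymmetric: the optimum may sit at a grid edge)
  extent <- function(v) {
    d_lo <- -Inf; d_hi <- Inf
    rngs <- list(range(surface$x), range(surface$y))
    for (k in 1:2) {
      if (abs(v[k]) < 1e-9) next
      lims <- sort((rngs[[k]] - optimum[k]) / v[k])
      d_lo <- max(d_lo, lims[1L]); d_hi <- min(d_hi, lims[2L])
    }
    c(d_lo, d_hi)
  }
  ext <- extent(dir)
  min_span <- min(diff(surface$x)) / 2
  if (!all(is.finite(ext)) || diff(ext) < min_span) {
    dir <- c(-dir[2L], dir[1L])  # valley leaves the hull: use perpendicular
    ext <- extent(dir)
  }
  d <- unique(sort(c(seq(ext[1L], 0, length.out = n_steps + 1L),
                     seq(0, ext[2L], length.out = n_steps + 1L))))
  px <- optimum[1L] + d * dir[1L]
  py <- optimum[2L] + d * dir[2L]
  zc <- vapply(seq_along(d), function(i) interp_surface_(surface, px[i], py[i]), 1.0)
  pct <- 100 * (zc - z0) / max(z0, 0.02 * max(z), .Machine$double.eps)
  curve <- data.frame(distance = d, pct_change = pct)
  slope <- sum(abs(pct) * abs(d)) / max(sum(d^2), .Machine$double.eps)
  list(curve = curve, direction = dir, optimum = optimum,
       sensitivity = slope)
}

interp_surface_ <- function(surface, x, y) {
  x <- min(max(x, min(surface$x)), max(surface$x))
  y <- min(max(y, min(surface$y)), max(surface$y))
  pracma::interp2(surface$y, surface$x, surface$cost, y, x, method = "linear")
}

#' Balanced copy numbers for single-interface networks
#'
#' For networks where every protein carries one interface (so the protein
#' network equals the interface network), balanced copies follow directly
#' from the stoichiometry `C = A x`:
#'
#' * `"equal-complex"`: every pairwise complex gets the same target count
#'   `complexes_per_edge`, so protein copies are proportional to their
#'   number of partners (degree);
#' * `"balanced"`: `x` minimizes `||A x - c0||^2` subject to `x >= 0`
#'   (nonnegative least squares), and `C = A x_min` is the balanced vector
#'   closest to the input `c0`.
#'
#' @param net an [iin] network with one interface per protein
#' @param c0 named protein copy vector (required for `"balanced"`)
#' @param mode `"balanced"` or `"equal-complex"`
#' @param complexes_per_edge target complexes per edge for `"equal-complex"`
#' @return named numeric vector of balanced protein copies
#' @export
balance_iin_copies <- function(net, c0 = NULL,
                               mode = c("balanced", "equal-complex"),
                               complexes_per_edge = 50) {
  stopifnot(is.iin(net))
  mode <- match.arg(mode)
  if (anyDuplicated(net$interfaces$protein))
    stop("network must have a single interface per protein")
  sys <- build_system(net, stats::setNames(rep(1, length(net$proteins)),
                                           net$proteins))
  A <- sys$A
  rownames(A) <- net$interfaces$protein
  if (mode == "equal-complex") {
    cb <- drop(A %*% rep(complexes_per_edge, ncol(A)))
  } else {
    if (is.null(c0)) stop("mode 'balanced' requires c0")
    c0 <- c0[net$interfaces$protein]
    if (anyNA(c0)) stop("c0 must cover all proteins")
    fit <- pracma::lsqnonneg(A, unname(c0))
    cb <- drop(A %*% pmax(fit$x, 0))
  }
  stats::setNames(cb, net$interfaces$protein)
}

#' Misinteraction cost and balance sensitivity for large interface networks
#'
#' For each network, builds the full competitive binding model (network
#' edges specific at `kd_spec * kd_scale`; every other pair, self pairs
#' included, nonspecific at `kd_nonspec * kd_scale`), then simulates to
#' steady state under randomly sampled copy numbers and under the balanced
#' copy numbers obtained from those samples via [balance_iin_copies()]. The
#' protein-mode misinteraction cost is reported for both, and the
#' sensitivity ratio `cost(random) / cost(balanced)` quantifies how much
#' imbalance hurts that network.
#'
#' @param nets list of [iin] networks (one interface per protein)
#' @param dist an [abundance_distribution()] used to sample imbalanced
#'   copies
#' @param kd_spec specific KD, uM (default 100 nM)
#' @param kd_nonspec nonspecific KD, uM (default 100 uM)
#' @param kd_scale multiplicative sweep factor(s) applied to both KDs
#'   (mean-affinity sweep; the specific/nonspecific gap is preserved)
#' @param n_runs Gillespie runs per condition
#' @param n_samples random copy vectors per network
#' @param seed optional master seed
#' @param copies_per_uM effective volume, copies per uM
#' @return data.frame with one row per (network, kd_scale, sample):
#'   costs under random and balanced copies and the sensitivity ratio
#' @export
iin_misinteraction_study <- function(nets, dist, kd_spec = 0.1,
                                     kd_nonspec = 100, kd_scale = 1,
                                     n_runs = 20L, n_samples = 3L,
                                     seed = NULL, copies_per_uM = 50) {
  stopifnot(is.list(nets), length(nets) >= 1L)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      2L * length(nets) * length(kd_scale) * n_samples))
  rows <- list()
  k <- 0L
  for (ni in seq_along(nets)) {
    net <- nets[[ni]]
    sp <- net$interfaces$protein
    spec <- data.frame(a = sp[net$edges[, 1L]], b = sp[net$edges[, 2L]],
                       kd = NA_real_, stringsAsFactors = FALSE)
    all_pairs <- rbind(t(utils::combn(sp, 2L)), cbind(sp, sp))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ns_idx <- !(key(all_pairs[, 1L], all_pairs[, 2L]) %in% key(spec$a, spec$b))
    nonspec <- data.frame(a = all_pairs[ns_idx, 1L], b = all_pairs[ns_idx, 2L],
                          kd = NA_real_, stringsAsFactors = FALSE)
    for (sc in kd_scale) for (si in seq_len(n_samples)) {
      k <- k + 1L
      spec$kd <- kd_spec * sc
      nonspec$kd <- kd_nonspec * sc
      c_rand <- sample_copynumbers(dist, length(sp), 1L, seed = seeds[2L * k - 1L])[[1L]]
      names(c_rand) <- sp
      c_bal <- balance_iin_copies(net, c_rand, mode = "balanced")
      run_cost <- function(copies, s) {
        m <- binding_model(sp, copies, spec, nonspec,
                           copies_per_uM = copies_per_uM)
        binding_cost(simulate_to_steady_state(m, n_runs = n_runs, seed = s),
                     mode = "protein")
      }
      cost_rand <- run_cost(c_rand, seeds[2L * k - 1L])
      cost_bal <- run_cost(c_bal, seeds[2L * k])
      rows[[k]] <- data.frame(
        network = ni, n_nodes = length(sp), kd_scale = sc, sample = si,
        cost_random = cost_rand, cost_balanced = cost_bal,
        sensitivity = if (cost_bal > 0) cost_rand / cost_bal else Inf)
    }
  }
  do.call(rbind, rows)
}
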