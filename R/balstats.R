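#' Chi-square distance between copy-number vectors
#'
#' `sum((x - y)^2 / (x + y))` over components, with terms where
#' `x + y == 0` contributing zero. Symmetric and nonnegative; sensitive to
#' large absolute deviations, so a single strongly over-expressed protein
#' can dominate it.
#'
#' @param x,y nonnegative numeric vectors of equal length
#' @return nonnegative scalar
#' @examples
#' chi_square_distance(c(1, 0), c(0, 1))  # 2
#' @export
chi_square_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("inputs must be nonnegative")
  s <- x + y
  d <- (x - y)^2
  sum(ifelse(s == 0, 0, d / pmax(s, .Machine$double.xmin)))
}

#' Jensen-Shannon divergence between copy-number vectors
#'
#' Both vectors are normalized to distributions `p`, `q`; the divergence is
#' `(KL(p || m) + KL(q || m)) / 2` with `m = (p + q) / 2` and Kullback-Leibler
#' divergence in natural log units (nats), so the value lies in
#' `[0, log(2)]`. Scale-invariant in each argument.
#'
#' @param x,y nonnegative numeric vectors of equal length with positive sums
#' @return scalar in `[0, log(2)]`
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1))  # log(2)
#' @export
jensen_shannon_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("inputs must be nonnegative")
  if (sum(x) <= 0 || sum(y) <= 0) stop("vectors must have positive sums")
  p <- x / sum(x)
  q <- y / sum(y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Abundance distributions for random copy-number draws
#'
#' Describes the null model that random protein copy numbers are drawn from
#' when testing balance significance:
#'
#' * `"empirical"`: resample (with replacement) from a genome-wide abundance
#'   pool, emulating e.g. sampling random yeast protein concentrations;
#' * `"lognormal"`: parametric draws with `meanlog`/`sdlog` of log-copies;
#' * `"permute"`: shuffle a provided copy-number vector, preserving its
#'   multiset of values.
#'
#' @param pool positive numeric vector; the empirical abundance pool or (for
#'   `"permute"`) the vector to shuffle
#' @param meanlog,sdlog log-normal parameters (`sdlog > 0`)
#' @param mode sampling mode
#' @return an object of class `abundance_distribution`
#' @export
abundance_distribution <- function(pool = NULL, meanlog = NULL, sdlog = NULL,
                                   mode = c("empirical", "lognormal", "permute")) {
  mode <- match.arg(mode)
  if (mode %in% c("empirical", "permute")) {
    if (is.null(pool) || length(pool) < 2L)
      stop("empirical/permute mode needs a pool of at least 2 values")
    if (any(pool <= 0)) stop("pool values must be positive")
  } else {
    if (is.null(meanlog) || is.null(sdlog) || sdlog <= 0)
      stop("lognormal mode needs meanlog and sdlog > 0")
  }
  structure(list(pool = pool, meanlog = meanlog, sdlog = sdlog, mode = mode),
            class = "abundance_distribution")
}

#' Draw random copy-number vectors
#'
#' @param dist an [abundance_distribution()]
#' @param n_proteins length of each drawn vector (for `"permute"` mode this
#'   must equal the pool length)
#' @param n_rand number of vectors to draw
#' @param seed optional integer for reproducible draws
#' @return list of `n_rand` numeric vectors of length `n_proteins`
#' @export
sample_copynumbers <- function(dist, n_proteins, n_rand, seed = NULL) {
  stopifnot(inherits(dist, "abundance_distribution"),
            n_proteins >= 1L, n_rand >= 1L)
  with_seed(seed, {
    replicate(n_rand, simplify = FALSE, switch(
      dist$mode,
      empirical = sample(dist$pool, n_proteins, replace = TRUE),
      lognormal = stats::rlnorm(n_proteins, dist$meanlog, dist$sdlog),
      permute = {
        if (length(dist$pool) != n_proteins)
          stop("permute mode requires pool length == n_proteins")
        sample(dist$pool)
      }))
  })
}

#' Empirical significance of stoichiometric balance
#'
#' Tests whether observed protein copy numbers are closer to their balanced
#' counterparts than random copy numbers would be. For the observed vector
#' and for each of `n_rand` random vectors drawn from `dist`, the balance
#' optimization is solved and the chi-square and Jensen-Shannon distances
#' between the input and balanced protein copies are computed. One-sided
#' p-values (small distance = balanced) use the add-one estimator
#' `p = (1 + #\{null <= observed\}) / (n_rand + 1)`, which is never zero and
#' is super-uniform under the null.
#'
#' @param net an [iin] network
#' @param c_real named numeric vector of observed protein copy numbers
#'   covering the constrained proteins
#' @param dist an [abundance_distribution()] null model
#' @param alpha balance parameter passed to [build_system()]
#' @param n_rand number of random copy-number vectors
#' @param seed optional integer for reproducible draws
#' @param constrained protein ids to constrain (default `names(c_real)`)
#' @return an object of class `significance_report`: observed `csd`/`jsd`,
#'   null sample vectors, p-values, and the count of solver failures among
#'   null draws (failed draws are dropped from the null and reported).
#' @export
balance_significance <- function(net, c_real, dist, alpha = 1,
                                 n_rand = 1000L, seed = NULL,
                                 constrained = names(c_real)) {
  stopifnot(is.iin(net))
  prots <- constrained
  dists_for <- function(c0) {
    res <- balance_network(net, c0, constrained = prots, alpha = alpha)
    cb <- protein_copies(res)[prots]
    c(csd = chi_square_distance(unname(c0[prots]), unname(cb)),
      jsd = jensen_shannon_distance(unname(c0[prots]), unname(cb)))
  }
  real <- dists_for(c_real)
  draws <- sample_copynumbers(dist, length(prots), n_rand, seed = seed)
  null_csd <- numeric(0); null_jsd <- numeric(0); failures <- 0L
  for (v in draws) {
    names(v) <- prots
    d <- tryCatch(dists_for(v), error = function(e) NULL)
    if (is.null(d)) { failures <- failures + 1L; next }
    null_csd <- c(null_csd, d[["csd"]])
    null_jsd <- c(null_jsd, d[["jsd"]])
  }
  n_ok <- length(null_csd)
  structure(list(
    csd = unname(real[["csd"]]), jsd = unname(real[["jsd"]]),
    null_csd = null_csd, null_jsd = null_jsd,
    p_csd = (1 + sum(null_csd <= real[["csd"]])) / (n_ok + 1),
    p_jsd = (1 + sum(null_jsd <= real[["jsd"]])) / (n_ok + 1),
    n_rand = n_rand, failures = failures, alpha = alpha),
    class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Balance significance (alpha = %g, %d null draws%s)\n",
    "  chi-square distance   %.6g  (p = %.4g)\n",
    "  Jensen-Shannon dist.  %.6g  (p = %.4g)\n"),
    x$alpha, x$n_rand,
    if (x$failures) sprintf(", %d failed", x$failures) else "",
    x$csd, x$p_csd, x$jsd, x$p_jsd))
  invisible(x)
}
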