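#' Rule model of ARP2/3 complex assembly
#'
#' Seven subunits wired around the core subunit ARC19, which binds five
#' partners (ARP2, ARP3, ARC40, ARC35, ARC15) on distinct interfaces; the
#' default periphery adds the ARP2-ARP3, ARC40-ARP2, ARP3-ARC18, ARC35-ARP3
#' and ARC40-ARC15 contacts of the assembled complex (see [arp23_edges()];
#' the wiring is configurable through `edges` and the default is a
#' documented convention, since only the subunit contact topology, not a
#' quantitative interface map, is available). Interactions with the core
#' subunit are `core_factor`-fold stronger than peripheral interactions.
#' Cooperativity: whenever two bonds of a correct trimer already hold three
#' subunits together, the closing rule of that triangle may fire within the
#' complex at `ring_rate`.
#'
#' Copy numbers: `"balanced"` gives every subunit `copies`; `"observed"`
#' reflects the measured ~5-fold underexpression of ARC19 (ARC19 at
#' `copies / 5`, the rest at `copies`).
#'
#' @param copies_mode `"observed"` or `"balanced"`
#' @param copies uniform subunit copy number
#' @param peripheral_kd dissociation constant of peripheral bonds, uM
#' @param core_factor fold-strengthening of ARC19 bonds
#' @param ring_rate intra-complex closure rate for the triangle rules, s^-1
#' @param misinteraction_kd `NULL`, or the KD (uM) of added nonspecific
#'   ARC19-ARC19 misinteraction rules between its five interfaces
#' @param copies_per_uM effective volume, copies per uM
#' @param koff dissociation rate for all bonds, s^-1
#' @param edges optional two-column character matrix of subunit pairs
#'   replacing the default peripheral wiring (ARC19 edges are derived from
#'   any pair involving ARC19)
#' @return a [rule_model()]
#' @examples
#' arp23_model("observed", copies = 500)
#' @export
arp23_model <- function(copies_mode = c("observed", "balanced"),
                        copies = 5000, peripheral_kd = 1, core_factor = 10,
                        ring_rate = 1000, misinteraction_kd = NULL,
                        copies_per_uM = 5000, koff = 1,
                        edges = arp23_edges()) {
  copies_mode <- match.arg(copies_mode)
  if (core_factor <= 0) stop("core_factor must be positive")
  subunits <- c("ARP2", "ARP3", "ARC40", "ARC35", "ARC18", "ARC15", "ARC19")
  if (!all(edges %in% subunits)) stop("edges reference unknown subunits")
  # one site per interaction partner, named by the partner
  site_of <- function(s, partner) paste(s, partner, sep = ".")
  sites <- stats::setNames(lapply(subunits, function(s) {
    partners <- c(edges[edges[, 1L] == s, 2L], edges[edges[, 2L] == s, 1L])
    vapply(partners, function(p) site_of(s, p), "")
  }), subunits)
  cp <- stats::setNames(rep(copies, length(subunits)), subunits)
  if (copies_mode == "observed") cp[["ARC19"]] <- copies / 5
  types <- lapply(subunits, function(s)
    list(name = s, copies = cp[[s]], sites = unname(sites[[s]])))
  # cooperative closure applies to every edge of a correct trimer: any edge
  # (a, b) such that some third subunit binds both a and b
  partners_of <- function(s)
    c(edges[edges[, 1L] == s, 2L], edges[edges[, 2L] == s, 1L])
  in_triangle <- function(a, b)
    length(intersect(partners_of(a), partners_of(b))) > 0L
  rules <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    core <- "ARC19" %in% c(a, b)
    data.frame(class_a = site_of(a, b), class_b = site_of(b, a),
               kd = if (core) peripheral_kd / core_factor else peripheral_kd,
               specific = TRUE, poly = FALSE,
               ring_rate = if (in_triangle(a, b)) ring_rate else 0,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(misinteraction_kd)) {
    mis_cls <- unname(sites[["ARC19"]])
    mis <- expand.grid(i = seq_along(mis_cls), j = seq_along(mis_cls))
    mis <- mis[mis$i <= mis$j, ]
    rules <- rbind(rules, data.frame(
      class_a = mis_cls[mis$i], class_b = mis_cls[mis$j],
      kd = misinteraction_kd, specific = FALSE, poly = FALSE,
      ring_rate = 0, stringsAsFactors = FALSE))
  }
  rule_model(types, rules, geometry = NULL, vesicle = NULL,
             koff = koff, copies_per_uM = copies_per_uM)
}

#' Default subunit contact map of the ARP2/3 complex
#'
#' The core subunit ARC19 (ARPC4) contacts five partners on distinct
#' interfaces; the periphery reflects the contacts of the assembled complex:
#' the ARP2-ARP3 pseudo-dimer, ARC40 (ARPC1) bridging ARP2 and ARC15
#' (ARPC5), ARC35 (ARPC2) contacting ARP3, and ARC18 (ARPC3) bound to ARP3.
#'
#' @return two-column character matrix of subunit pairs
#' @export
arp23_edges <- function() {
  rbind(c("ARC19", "ARP2"), c("ARC19", "ARP3"), c("ARC19", "ARC40"),
        c("ARC19", "ARC35"), c("ARC19", "ARC15"),
        c("ARP2", "ARP3"), c("ARP2", "ARC40"), c("ARP3", "ARC18"),
        c("ARC35", "ARP3"), c("ARC40", "ARC15"))
}

#' Maximum assembly yield over a rate-parameter sweep
#'
#' Simulates ARP2/3 assembly to a fixed time for each peripheral KD in
#' `kd_sweep` (with core bonds `core_factor`-fold stronger and cooperative
#' ring closure throughout) and reports the yield ([assembly_yield()]) at
#' each point plus the maximum over the sweep.
#'
#' @inheritParams arp23_model
#' @param kd_sweep peripheral KDs to try, uM
#' @param t_end simulated time per run, seconds
#' @param n_runs replicate runs per sweep point (yields averaged)
#' @param seed integer master seed
#' @param ... further arguments to [arp23_model()]
#' @return list with `sweep` (data.frame `kd`, `yield`) and `max_yield`
#' @export
arp23_yield_sweep <- function(copies_mode = c("observed", "balanced"),
                              kd_sweep = 10^seq(1, -2), copies = 5000,
                              t_end = 50, n_runs = 2L, seed = 1L, ...) {
  copies_mode <- match.arg(copies_mode)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      length(kd_sweep) * n_runs))
  yields <- vapply(seq_along(kd_sweep), function(i) {
    model <- arp23_model(copies_mode, copies = copies,
                         peripheral_kd = kd_sweep[i], ...)
    mean(vapply(seq_len(n_runs), function(r) {
      traj <- simulate_rules(model, t_end = t_end,
                             seed = seeds[(i - 1L) * n_runs + r])
      assembly_yield(traj)
    }, 1.0))
  }, 1.0)
  list(sweep = data.frame(kd = kd_sweep, yield = yields),
       max_yield = max(yields))
}
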