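#' Rule-based multi-site assembly models
#'
#' A rule model consists of molecule types carrying named binding sites,
#' bimolecular binding rules between site classes, optional two-compartment
#' geometry (cytosol + plasma membrane) with a pooled lipid population, and
#' an optional vesicle-completion rule. Site classes are labels such as
#' `"CHC.leg"`; several sites of one molecule may share a class (the three
#' polymerization legs of a clathrin trimer). Rules bind free sites of two
#' classes in distinct complexes; `"L"` as `class_b` denotes the pooled
#' membrane lipid. With geometry present, every rule's association rate is
#' multiplied by `vol_cp / (sa_pm * 2 * sigma)` when both partners are
#' membrane-associated (the 2D rate enhancement `KD_2D = KD_3D / (2 sigma)`).
#' Rules with `ring_rate > 0` may additionally fire within a complex, at
#' that fixed rate, when the two molecules already share a bonded neighbor
#' (cooperative closure of a correct trimer).
#'
#' @param types list of molecule types, each a list with `name`, `sites`
#'   (character vector of site-class labels), `copies`, and optional
#'   `is_lipid`
#' @param rules data.frame with columns `class_a`, `class_b`, `kd` (uM) and
#'   optional `ring_rate` (s^-1), `specific` (logical), `poly` (logical;
#'   marks the polymerization rule for membrane-recruitment attribution)
#' @param geometry list with `vol_cp` (um^3), `sa_pm` (um^2), `sigma_nm`;
#'   `NULL` for a single well-mixed compartment
#' @param vesicle list with `type`, `full_class`, `threshold`, `k_dump`,
#'   `k_recyc`; `NULL` disables vesicle completion
#' @param koff dissociation rate applied to every rule (s^-1)
#' @param copies_per_uM copies corresponding to 1 uM; derived from
#'   `geometry$vol_cp` when geometry is given
#' @return an object of class `rule_model`
#' @export
rule_model <- function(types, rules, geometry = NULL, vesicle = NULL,
                       koff = 1, copies_per_uM = NULL) {
  stopifnot(is.list(types), length(types) >= 1L)
  for (ty in types)
    stopifnot(!is.null(ty$name), !is.null(ty$sites), !is.null(ty$copies))
  stopifnot(all(c("class_a", "class_b", "kd") %in% names(rules)))
  if (is.null(rules$ring_rate)) rules$ring_rate <- 0
  if (is.null(rules$specific)) rules$specific <- TRUE
  if (is.null(rules$poly)) rules$poly <- FALSE
  stopifnot(all(rules$kd > 0))
  if (!is.null(geometry)) {
    stopifnot(all(c("vol_cp", "sa_pm", "sigma_nm") %in% names(geometry)))
    if (is.null(copies_per_uM))
      copies_per_uM <- 1e-6 * 6.02214076e23 * geometry$vol_cp * 1e-15
  } else if (is.null(copies_per_uM)) {
    copies_per_uM <- 50
  }
  structure(list(types = types, rules = rules, geometry = geometry,
                 vesicle = vesicle, koff = koff,
                 copies_per_uM = copies_per_uM),
            class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("Rule model: %d molecule types, %d rules (%d specific)%s%s\n",
              length(x$types), nrow(x$rules), sum(x$rules$specific),
              if (!is.null(x$geometry)) ", membrane compartment" else "",
              if (!is.null(x$vesicle)) ", vesicle completion" else ""))
  invisible(x)
}

#' Membrane 2D rate-enhancement factor
#'
#' Confinement to the membrane raises effective concentrations: with
#' `KD_2D = KD_3D / (2 sigma)`, association between two membrane-bound
#' partners speeds up by `vol_cp / (sa_pm * 2 sigma)` relative to solution.
#'
#' @param geometry list with `vol_cp` (um^3), `sa_pm` (um^2), `sigma_nm`
#' @return dimensionless enhancement factor
#' @examples
#' membrane_enhancement(list(vol_cp = 37.2, sa_pm = 75.7, sigma_nm = 1))
#' @export
membrane_enhancement <- function(geometry) {
  geometry$vol_cp / (geometry$sa_pm * 2 * geometry$sigma_nm * 1e-3)
}

#' Simulate a rule model
#'
#' Runs the network-free stochastic simulator on a [rule_model()]: an exact
#' SSA over rule firings, with per-rule propensity
#' `kon * (number of free reactant site pairs)`, per-bond dissociation at
#' `koff`, membrane-pair rate enhancement, vesicle dump/recycle, and
#' optional intra-complex ring closure. Molecule totals per type are
#' conserved throughout (including across vesicle recycling); this is
#' checked after every run.
#'
#' @param model a [rule_model()]
#' @param t_end simulated time, seconds
#' @param seed integer seed
#' @param max_events event cap
#' @param census record the final complex census (type composition and bond
#'   counts per complex)
#' @return an object of class `rule_traj`: vesicle log (`vesicle_time`,
#'   `vesicle_comp`, `vesicle_full`), membrane-arrival attribution counts,
#'   final complex census, event counters, and the model
#' @export
simulate_rules <- function(model, t_end, seed = 1L, max_events = 5e8,
                           census = TRUE) {
  stopifnot(inherits(model, "rule_model"))
  classes <- unique(unlist(lapply(model$types, `[[`, "sites")))
  cls_id <- stats::setNames(seq_along(classes) - 1L, classes)
  type_names <- vapply(model$types, `[[`, "", "name")
  is_lipid <- vapply(model$types, function(t) isTRUE(t$is_lipid), TRUE)
  if (sum(is_lipid) > 1L) stop("at most one lipid type is supported")
  types_arg <- list(
    name = type_names,
    site_class = lapply(model$types, function(t) unname(cls_id[t$sites])),
    copies = as.integer(round(vapply(model$types, `[[`, 1.0, "copies"))),
    is_lipid = as.integer(is_lipid),
    n_classes = length(classes))
  enh <- if (!is.null(model$geometry)) membrane_enhancement(model$geometry) else 1
  r <- model$rules
  kon3 <- model$koff / (r$kd * model$copies_per_uM)
  rules_arg <- list(
    class_a = unname(cls_id[as.character(r$class_a)]),
    class_b = ifelse(as.character(r$class_b) == "L", -1L,
                     unname(cls_id[as.character(r$class_b)])),
    kon = kon3,
    kon_extra = kon3 * (enh - 1),
    koff = rep(model$koff, nrow(r)),
    ring_rate = r$ring_rate,
    specific = as.integer(r$specific),
    poly = as.integer(r$poly))
  if (anyNA(rules_arg$class_a) || anyNA(rules_arg$class_b))
    stop("rule references an undeclared site class")
  ves <- model$vesicle
  ves_arg <- if (is.null(ves)) {
    list(type = -1L, full_class = -1L, threshold = -1L,
         k_dump = 0, k_recyc = 0)
  } else {
    list(type = match(ves$type, type_names) - 1L,
         full_class = unname(cls_id[ves$full_class]),
         threshold = as.integer(ves$threshold),
         k_dump = ves$k_dump, k_recyc = ves$k_recyc)
  }
  out <- rulesim_cpp(types_arg, rules_arg, ves_arg,
                     t_end, max_events, as.integer(seed), census)
  if (!out$conserved)
    stop("molecule conservation violated in rule simulation")
  out$model <- model
  class(out) <- "rule_traj"
  out
}

#' @export
print.rule_traj <- function(x, ...) {
  cat(sprintf(paste0("Rule simulation: t = %.3g s, %.3g events",
                     " (%.3g null), %d vesicles\n"),
              x$t_final, x$n_events, x$n_null, length(x$vesicle_time)))
  invisible(x)
}

#' Assembly yield of complete complexes
#'
#' Yield is `N_desired / (N_desired + N_undesired)` where `N_desired` is the
#' number of proteins in complete complexes (exactly one copy of each type
#' in `complete_types`, no nonspecific bonds) and `N_undesired` counts
#' proteins in incomplete or misassembled complexes. Completely free
#' proteins are ignored; when no complexes exist the yield is defined as 0.
#'
#' @param traj a `rule_traj` from [simulate_rules()] (with census)
#' @param complete_types character vector naming the subunits of the target
#'   complex (default: all non-lipid types of the model)
#' @return yield in `[0, 1]`
#' @export
assembly_yield <- function(traj, complete_types = NULL) {
  stopifnot(inherits(traj, "rule_traj"))
  cm <- traj$census
  if (is.null(cm) || nrow(cm) == 0L) return(0)
  type_names <- colnames(cm)
  if (is.null(complete_types)) {
    is_lipid <- vapply(traj$model$types, function(t) isTRUE(t$is_lipid), TRUE)
    complete_types <- type_names[!is_lipid[match(type_names,
      vapply(traj$model$types, `[[`, "", "name"))]]
  }
  size <- traj$census_size
  in_complex <- size >= 2L
  if (!any(in_complex)) return(0)
  want <- cm[, complete_types, drop = FALSE]
  complete <- in_complex &
    apply(want == 1L, 1L, all) &
    (rowSums(cm) == length(complete_types)) &
    traj$census_bonds_nonspecific == 0L
  n_desired <- sum(size[complete])
  n_undesired <- sum(size[in_complex & !complete])
  if (n_desired + n_undesired == 0) 0 else n_desired / (n_desired + n_undesired)
}

#' Composition statistics of completed vesicles
#'
#' Summarizes the vesicle log of a clathrin-module trajectory: per-vesicle
#' counts of adaptor/scaffold proteins and full triskelia, the mean
#' adaptors-per-full-triskelion ratio, and the membrane-recruitment
#' attribution (the percentage of triskelia whose first entry into a
#' membrane-associated complex happened through a bond other than
#' clathrin-clathrin polymerization).
#'
#' @param traj a `rule_traj` from [simulate_rules()]
#' @param adaptor_types type names counted as adaptor/scaffold proteins
#' @return list with `n_vesicles`, per-vesicle data.frame `vesicles`
#'   (time, adaptors, full triskelia, ratio), `adaptors_per_triskelion`
#'   (mean ratio), `pct_adaptor_recruited`, and raw attribution counts;
#'   with no vesicles the summary fields are `NA` (not an error)
#' @export
vesicle_stats <- function(traj,
                          adaptor_types = c("ENT", "SLA2", "SYP1", "EDE1",
                                            "YAP1801", "YAP1802")) {
  stopifnot(inherits(traj, "rule_traj"))
  nv <- length(traj$vesicle_time)
  adaptor_types <- intersect(adaptor_types, colnames(traj$vesicle_comp))
  att_tot <- traj$first_mem_adaptor + traj$first_mem_poly
  pct_adaptor <- if (att_tot > 0) 100 * traj$first_mem_adaptor / att_tot else NA_real_
  if (nv == 0L) {
    return(list(n_vesicles = 0L, vesicles = NULL,
                adaptors_per_triskelion = NA_real_,
                pct_adaptor_recruited = pct_adaptor,
                first_mem_adaptor = traj$first_mem_adaptor,
                first_mem_poly = traj$first_mem_poly))
  }
  adap <- rowSums(traj$vesicle_comp[, adaptor_types, drop = FALSE])
  full <- pmax(traj$vesicle_full, 1L)
  df <- data.frame(time = traj$vesicle_time, adaptors = adap,
                   full_triskelia = traj$vesicle_full,
                   ratio = adap / full)
  list(n_vesicles = nv, vesicles = df,
       adaptors_per_triskelion = mean(df$ratio),
       pct_adaptor_recruited = pct_adaptor,
       first_mem_adaptor = traj$first_mem_adaptor,
       first_mem_poly = traj$first_mem_poly)
}

#' Surface area per protein on a spherical vesicle
#'
#' Helper for judging the geometric plausibility of vesicle compositions: a
#' sphere of the given diameter divided evenly among `n_proteins`.
#'
#' @param n_proteins number of proteins sharing the surface
#' @param diameter_nm vesicle diameter in nm
#' @return area per protein, nm^2
#' @examples
#' sphere_area_per_protein(1900)  # ~16.5 nm^2 on a 100 nm vesicle
#' @export
sphere_area_per_protein <- function(n_proteins, diameter_nm = 100) {
  stopifnot(n_proteins > 0)
  4 * pi * (diameter_nm / 2)^2 / n_proteins
}

#' Specific/nonspecific energy gap
#'
#' The dissociation-constant ratio between nonspecific and specific binding
#' corresponds to a free-energy gap of `log(ratio)` in units of kT.
#'
#' @param kd_ratio nonspecific/specific KD ratio
#' @return energy gap in kT
#' @examples
#' energy_gap(1e4)  # ~9.21 kT
#' @export
energy_gap <- function(kd_ratio) {
  stopifnot(kd_ratio > 0)
  log(kd_ratio)
}
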