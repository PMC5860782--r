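#' Parameter table for the clathrin vesicle-forming module
#'
#' The default parameterization of the nine-protein clathrin-coat module:
#' literature dissociation constants for every binding interface
#' interaction, yeast copy numbers, compartment geometry, lipid density,
#' the vesicle-completion threshold, and the dump/recycle rates. The table
#' matches the packaged TSV (`inst/extdata/cme_parameters.tsv`)
#' column-for-column; [read_cme_parameters()] loads a user-edited copy.
#'
#' @return data.frame with columns `parameter`, `description`, `value`,
#'   `units`
#' @export
cme_parameters <- function() {
  p <- function(parameter, description, value, units)
    data.frame(parameter = parameter, description = description,
               value = value, units = units, stringsAsFactors = FALSE)
  rbind(
    p("Vol_CP", "Cytosol volume", 37.2, "um^3"),
    p("SA_PM", "Plasma membrane surface area", 75.7, "um^2"),
    p("sigma", "KD 3D-to-2D conversion lengthscale", 1, "nm"),
    p("Kd_CHC_CHC", "Clathrin heavy chain polymerization", 100, "uM"),
    p("Kd_CHC_ENT", "Clathrin heavy chain binding to ENT1/2", 22, "uM"),
    p("Kd_CHC_YAP", "Clathrin heavy chain binding to YAP1801/2", 160, "uM"),
    p("Kd_EDE_ENT", "EDE1 to ENT1/2 binding", 12, "uM"),
    p("Kd_EDE_YAP", "EDE1 to YAP1802 binding", 0.6, "uM"),
    p("Kd_EDE_EDE", "EDE1 dimerization", 0.127, "uM"),
    p("Kd_CHC_CLC", "Clathrin heavy chain to light chain binding", 1e-4, "uM"),
    p("Kd_CLC_SLA", "Clathrin light chain to SLA2 binding", 22, "uM"),
    p("Kd_SLA_SLA", "SLA2 dimerization", 0.001, "uM"),
    p("Kd_SYP_SYP", "SYP1 dimerization", 2.5, "uM"),
    p("Kd_SYP_EDE", "SYP1 to EDE1 binding", 0.227, "uM"),
    p("Kd_L_ENT", "ENT1/2 binding to lipid", 0.02, "uM"),
    p("Kd_L_YAP", "YAP1801 binding to lipid", 0.3, "uM"),
    p("Kd_L_SLA", "SLA2 binding to lipid", 0.2, "uM"),
    p("Kd_L_SYP", "SYP1 binding to lipid", 53, "uM"),
    p("k_off", "Dissociation rate for all bonds", 1, "s^-1"),
    p("L_0", "Density of membrane recruiter lipids", 25292, "lipids/um^2"),
    p("CHC1_0", "Total clathrin heavy chain trimers", 6426, "copies"),
    p("CLC1_0", "Total clathrin light chains", 14538, "copies"),
    p("EDE1_0", "EDE1 total proteins", 5964, "copies"),
    p("ENT_0", "ENT1/2 total proteins", 3075, "copies"),
    p("YAP1801_0", "YAP1801 total proteins", 357, "copies"),
    p("YAP1802_0", "YAP1802 total proteins", 264, "copies"),
    p("SLA2_0", "SLA2 total proteins", 3904, "copies"),
    p("SYP1_0", "SYP1 total proteins", 2467, "copies"),
    p("T_vesicle", "Full triskelia in a completed vesicle", 100, "count"),
    p("k_dump", "Deletion rate for completed vesicles", 1000, "s^-1"),
    p("k_recyc", "Protein recycling rate to the cytoplasm", 1000, "s^-1"))
}

#' @rdname cme_parameters
#' @param path TSV file with columns `parameter`, `description`, `value`,
#'   `units`
#' @export
read_cme_parameters <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("parameter", "description", "value", "units")
  if (!all(need %in% names(df)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname cme_parameters
#' @param params parameter data.frame
#' @export
write_cme_parameters <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

cme_param_ <- function(params, name) {
  i <- match(name, params$parameter)
  if (is.na(i)) stop("missing parameter table row: ", name)
  params$value[i]
}

#' Build the clathrin vesicle-forming module
#'
#' Constructs the rule model of the nine-protein clathrin-coat module:
#' clathrin heavy chains pre-assembled as trimers (three polymerization
#' legs, three light-chain sites, three adaptor sites), light chains,
#' the adaptor/scaffold proteins SLA2, ENT1/2 (merged: identical partners),
#' EDE1, SYP1, YAP1801, YAP1802, and a membrane lipid population that
#' recruits the five lipid-binding proteins. All dissociation constants,
#' copy numbers, geometry, and vesicle parameters come from the parameter
#' table; every bond dissociates at `k_off`, and membrane-pair association
#' is enhanced by `Vol_CP / (SA_PM * 2 sigma)`. Vesicle completion deletes
#' any membrane complex with at least `T_vesicle` full triskelia (a trimer
#' carrying all three light chains) and recycles its proteins one at a time.
#'
#' When `misinteraction_f` is set, a nonspecific rule is added for every
#' protein site-class pair lacking a specific rule, with
#' `KD = f * sqrt(KD_mean_1 * KD_mean_2)` where each site's `KD_mean` is the
#' geometric mean of its specific dissociation constants (a geometric mean
#' of KDs corresponds to the arithmetic mean of binding energies). `f = 1e4`
#' gives weak misinteractions (energy gap ~9.21 kT), `f = 1e3` strong ones
#' (~6.91 kT). The lipid site itself takes no misinteractions.
#'
#' @param params parameter table from [cme_parameters()] or
#'   [read_cme_parameters()]
#' @param misinteraction_f `NULL` (no misinteractions) or the KD multiplier
#'   `f`
#' @param copy_overrides named numeric vector overriding protein copies
#'   (e.g. `c(SYP1 = 0)` for a knockout)
#' @param scale scale-down factor applied to all copies and to the
#'   compartment geometry (volume/area co-scaled so concentrations are
#'   unchanged), for fast exploratory runs
#' @return a [rule_model()]
#' @examples
#' mod <- cme_model(scale = 0.05)
#' mod
#' @export
cme_model <- function(params = cme_parameters(), misinteraction_f = NULL,
                      copy_overrides = NULL, scale = 1) {
  g <- function(n) cme_param_(params, n)
  geometry <- list(vol_cp = g("Vol_CP") * scale, sa_pm = g("SA_PM") * scale,
                   sigma_nm = g("sigma"))
  koff <- g("k_off")
  copies <- c(CHC = g("CHC1_0"), CLC = g("CLC1_0"), EDE1 = g("EDE1_0"),
              ENT = g("ENT_0"), YAP1801 = g("YAP1801_0"),
              YAP1802 = g("YAP1802_0"), SLA2 = g("SLA2_0"),
              SYP1 = g("SYP1_0"))
  copies <- round(copies * scale)
  if (!is.null(copy_overrides)) {
    unknown <- setdiff(names(copy_overrides), names(copies))
    if (length(unknown)) stop("unknown protein(s): ",
                              paste(unknown, collapse = ", "))
    copies[names(copy_overrides)] <- round(copy_overrides * scale)
  }
  n_lipid <- round(g("L_0") * geometry$sa_pm)
  types <- list(
    list(name = "CHC", copies = copies[["CHC"]],
         sites = c("CHC.leg", "CHC.leg", "CHC.leg",
                   "CHC.lc", "CHC.lc", "CHC.lc",
                   "CHC.ad", "CHC.ad", "CHC.ad")),
    list(name = "CLC", copies = copies[["CLC"]],
         sites = c("CLC.chc", "CLC.sla")),
    list(name = "SLA2", copies = copies[["SLA2"]],
         sites = c("SLA2.dim", "SLA2.clc", "SLA2.lip")),
    list(name = "ENT", copies = copies[["ENT"]],
         sites = c("ENT.lip", "ENT.chc", "ENT.ede")),
    list(name = "EDE1", copies = copies[["EDE1"]],
         sites = c("EDE1.dim", "EDE1.ent", "EDE1.yap", "EDE1.syp")),
    list(name = "SYP1", copies = copies[["SYP1"]],
         sites = c("SYP1.dim", "SYP1.lip", "SYP1.ede")),
    list(name = "YAP1801", copies = copies[["YAP1801"]],
         sites = c("YAP1801.lip", "YAP1801.chc")),
    list(name = "YAP1802", copies = copies[["YAP1802"]],
         sites = c("YAP1802.chc", "YAP1802.ede")),
    list(name = "L", copies = n_lipid, sites = "L.site", is_lipid = TRUE))
  rules <- data.frame(
    class_a = c("CHC.leg", "CHC.ad", "CHC.ad", "CHC.ad",
                "EDE1.ent", "EDE1.yap", "EDE1.dim", "CHC.lc",
                "CLC.sla", "SLA2.dim", "SYP1.dim", "SYP1.ede",
                "ENT.lip", "YAP1801.lip", "SLA2.lip", "SYP1.lip"),
    class_b = c("CHC.leg", "ENT.chc", "YAP1801.chc", "YAP1802.chc",
                "ENT.ede", "YAP1802.ede", "EDE1.dim", "CLC.chc",
                "SLA2.clc", "SLA2.dim", "SYP1.dim", "EDE1.syp",
                "L", "L", "L", "L"),
    kd = c(g("Kd_CHC_CHC"), g("Kd_CHC_ENT"), g("Kd_CHC_YAP"),
           g("Kd_CHC_YAP"), g("Kd_EDE_ENT"), g("Kd_EDE_YAP"),
           g("Kd_EDE_EDE"), g("Kd_CHC_CLC"), g("Kd_CLC_SLA"),
           g("Kd_SLA_SLA"), g("Kd_SYP_SYP"), g("Kd_SYP_EDE"),
           g("Kd_L_ENT"), g("Kd_L_YAP"), g("Kd_L_SLA"), g("Kd_L_SYP")),
    specific = TRUE,
    poly = FALSE,
    ring_rate = 0,
    stringsAsFactors = FALSE)
  rules$poly[1L] <- TRUE  # CHC-CHC polymerization, for recruitment tallies
  if (!is.null(misinteraction_f))
    rules <- rbind(rules, cme_misinteraction_rules(rules, misinteraction_f))
  vesicle <- list(type = "CHC", full_class = "CHC.lc",
                  threshold = g("T_vesicle"),
                  k_dump = g("k_dump"), k_recyc = g("k_recyc"))
  rule_model(types, rules, geometry = geometry, vesicle = vesicle,
             koff = koff)
}

#' Misinteraction rules from geometric-mean dissociation constants
#'
#' For every unordered pair of protein site classes without a specific rule,
#' generates a nonspecific rule with `KD = f * sqrt(KDm_a * KDm_b)`, where
#' `KDm` is the geometric mean of the class's specific KDs. Pairs involving
#' the lipid site are skipped.
#'
#' @param rules data.frame of specific rules (columns `class_a`, `class_b`,
#'   `kd`)
#' @param f KD multiplier (the energy gap is `log(f)` kT)
#' @return data.frame of nonspecific rules in [rule_model()] format
#' @export
cme_misinteraction_rules <- function(rules, f) {
  stopifnot(f > 0)
  rules <- rules[rules$specific %||% TRUE, , drop = FALSE]
  cls <- sort(unique(c(rules$class_a, rules$class_b)))
  cls <- setdiff(cls, "L")
  kd_mean <- vapply(cls, function(cl) {
    kds <- c(rules$kd[rules$class_a == cl], rules$kd[rules$class_b == cl])
    exp(mean(log(kds)))
  }, 1.0)
  have <- paste(pmin(rules$class_a, rules$class_b),
                pmax(rules$class_a, rules$class_b))
  out <- list()
  for (i in seq_along(cls)) for (j in seq(i, length(cls))) {
    a <- cls[i]; b <- cls[j]
    if (paste(a, b) %in% have) next
    out[[length(out) + 1L]] <- data.frame(
      class_a = a, class_b = b,
      kd = f * sqrt(kd_mean[[a]] * kd_mean[[b]]),
      specific = FALSE, poly = FALSE, ring_rate = 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
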