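test_that("membrane confinement geometry gives the documented rate enhancement", {
  geom <- list(vol_cp = 37.2, sa_pm = 75.7, sigma_nm = 1)
  expect_equal(membrane_enhancement(geom), 37.2 / (75.7 * 0.002),
               tolerance = 1e-12)                      # ~246
  # doubling sigma halves the enhancement exactly
  geom2 <- geom; geom2$sigma_nm <- 2
  expect_equal(membrane_enhancement(geom2), membrane_enhancement(geom) / 2)
})

test_that("the rule engine agrees with the binary engine on a shared two-species system", {
  types <- list(list(name = "X", copies = 60, sites = "X.s"),
                list(name = "Y", copies = 45, sites = "Y.s"))
  rules <- data.frame(class_a = "X.s", class_b = "Y.s", kd = 0.5)
  mod <- rule_model(types, rules, copies_per_uM = 50)
  dimers <- vapply(1:8, function(s) {
    traj <- simulate_rules(mod, t_end = 60, seed = 100 + s)
    sum(traj$census_size == 2)
  }, 1.0)
  c_eq <- pair_equilibrium(60, 45, 0.5 * 50)
  expect_lt(abs(mean(dimers) - c_eq), 3 * stats::sd(dimers) / sqrt(8) + 1)

  bm <- binding_model(c("X", "Y"), c(X = 60, Y = 45),
                      data.frame(a = "X", b = "Y", kd = 0.5))
  res <- simulate_to_steady_state(bm, n_runs = 200, seed = 3)
  expect_lt(abs(mean(dimers) - res$n_specific),
            3 * stats::sd(dimers) / sqrt(8) + 1)
})

test_that("molecule totals survive vesicle dump and recycle", {
  # a small membrane system engineered to dump frequently: conservation is
  # asserted inside simulate_rules after every run
  mod <- cme_model(scale = 0.03)
  mod$vesicle$threshold <- 5
  traj <- simulate_rules(mod, t_end = 8, seed = 2)
  expect_gt(length(traj$vesicle_time), 0)
  expect_s3_class(traj, "rule_traj")
  # every vesicle met the threshold
  expect_true(all(traj$vesicle_full >= 5))
})

test_that("clathrin module parameters build the documented rule set", {
  params <- cme_parameters()
  expect_equal(params$value[params$parameter == "Kd_CHC_CHC"], 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cme_parameters(params, f)
  expect_equal(read_cme_parameters(f)$value, params$value)

  mod <- cme_model()
  expect_equal(nrow(mod$rules), 16L)
  expect_equal(sum(mod$rules$poly), 1L)
  lipid <- vapply(mod$types, function(t) isTRUE(t$is_lipid), TRUE)
  expect_equal(vapply(mod$types, `[[`, 1.0, "copies")[lipid],
               round(25292 * 75.7))
  ko <- cme_model(copy_overrides = c(SYP1 = 0))
  syp <- vapply(ko$types, function(t) t$name == "SYP1", TRUE)
  expect_equal(vapply(ko$types, `[[`, 1.0, "copies")[syp], 0)
  expect_error(cme_model(copy_overrides = c(NOPE = 1)), "unknown")

  # geometric-mean misinteraction strengths: a site with specific KDs
  # {22, 160} has KD_mean = sqrt(3520) ~ 59.3
  rules <- data.frame(class_a = c("P.x", "P.x", "Q.y"),
                      class_b = c("R.a", "S.b", "R.a"),
                      kd = c(22, 160, 5), specific = TRUE)
  mis <- cme_misinteraction_rules(rules, f = 1)
  px_qy <- mis$kd[(mis$class_a == "P.x" & mis$class_b == "Q.y") |
                  (mis$class_a == "Q.y" & mis$class_b == "P.x")]
  expect_equal(px_qy, sqrt(sqrt(22 * 160) * 5), tolerance = 1e-10)
  full <- cme_model(misinteraction_f = 1e3)
  expect_gt(nrow(full$rules), 200L)
  expect_false(any(!full$rules$specific &
                     (full$rules$class_a == "L" | full$rules$class_b == "L")))
})

test_that("misinteraction strength maps to the stated energy gaps", {
  expect_equal(energy_gap(1e4), log(1e4))
  expect_equal(round(energy_gap(1e4), 2), 9.21)
  expect_equal(round(energy_gap(1e3), 2), 6.91)
})

test_that("assembly yield follows its definition on a constructed census", {
  subunits <- c("ARP2", "ARP3", "ARC40", "ARC35", "ARC18", "ARC15", "ARC19")
  cm <- rbind(rep(1L, 7),                       # one complete complex
              c(1L, 1L, 0L, 0L, 0L, 0L, 0L),   # a dimer
              c(1L, 0L, 0L, 0L, 0L, 0L, 0L))   # a free monomer (ignored)
  colnames(cm) <- subunits
  traj <- structure(list(
    census = cm, census_size = c(7L, 2L, 1L),
    census_bonds = c(7L, 1L, 0L), census_bonds_nonspecific = c(0L, 0L, 0L),
    model = arp23_model("balanced", copies = 10)), class = "rule_traj")
  expect_equal(assembly_yield(traj), 7 / 9)
  # all molecules complete
  traj$census <- cm[1, , drop = FALSE]
  traj$census_size <- 7L; traj$census_bonds <- 7L
  traj$census_bonds_nonspecific <- 0L
  expect_equal(assembly_yield(traj), 1)
  # only free monomers: 0/0 is defined as 0
  traj$census <- cm[3, , drop = FALSE]
  traj$census_size <- 1L; traj$census_bonds <- 0L
  expect_equal(assembly_yield(traj), 0)
  # a 7-mer with a misinteraction bond is misassembled, not complete
  traj$census <- cm[1, , drop = FALSE]
  traj$census_size <- 7L; traj$census_bonds <- 7L
  traj$census_bonds_nonspecific <- 1L
  expect_equal(assembly_yield(traj), 0)
})

test_that("ARP2/3 copy modes and misinteraction wiring follow the complex topology", {
  bal <- arp23_model("balanced", copies = 500)
  cp <- vapply(bal$types, `[[`, 1.0, "copies")
  expect_true(all(cp == 500))
  obs <- arp23_model("observed", copies = 500)
  nm <- vapply(obs$types, `[[`, "", "name")
  cp <- stats::setNames(vapply(obs$types, `[[`, 1.0, "copies"), nm)
  expect_equal(cp[["ARC19"]], 100)
  expect_true(all(cp[setdiff(nm, "ARC19")] == 500))
  # ARC19 bonds are stronger; triangle rules carry the cooperative closure
  r <- obs$rules
  core <- grepl("ARC19", r$class_a) | grepl("ARC19", r$class_b)
  expect_true(all(r$kd[core] < r$kd[!core][1]))
  expect_gt(sum(r$ring_rate > 0), 0)
  mis <- arp23_model("observed", copies = 100, misinteraction_kd = 50)
  expect_equal(sum(!mis$rules$specific), 15L)  # 5 interfaces, pairs incl self
  expect_error(arp23_model("observed", core_factor = -1), "positive")
})

test_that("balanced subunit copies out-yield ARC19-underexpressed copies", {
  for (kd in c(0.3, 0.1)) {
    y_bal <- mean(vapply(1:2, function(r)
      assembly_yield(simulate_rules(
        arp23_model("balanced", copies = 400, peripheral_kd = kd,
                    copies_per_uM = 400),
        t_end = 25, seed = 700 + r)), 1.0))
    y_obs <- mean(vapply(1:2, function(r)
      assembly_yield(simulate_rules(
        arp23_model("observed", copies = 400, peripheral_kd = kd,
                    copies_per_uM = 400),
        t_end = 25, seed = 700 + r)), 1.0))
    expect_gt(y_bal, y_obs)
  }
  # and with ARC19 misinteractions allowed
  y_bal_m <- assembly_yield(simulate_rules(
    arp23_model("balanced", copies = 400, peripheral_kd = 0.1,
                copies_per_uM = 400, misinteraction_kd = 100),
    t_end = 25, seed = 11))
  y_obs_m <- assembly_yield(simulate_rules(
    arp23_model("observed", copies = 400, peripheral_kd = 0.1,
                copies_per_uM = 400, misinteraction_kd = 100),
    t_end = 25, seed = 11))
  expect_gt(y_bal_m, y_obs_m)
})

test_that("vesicle statistics summarize composition and recruitment attribution", {
  comp <- rbind(c(CHC = 110, CLC = 310, SLA2 = 500, ENT = 400, EDE1 = 600,
                  SYP1 = 200, YAP1801 = 100, YAP1802 = 100, L = 40))
  traj <- structure(list(
    vesicle_time = 3.5, vesicle_comp = comp, vesicle_full = 100L,
    first_mem_adaptor = 90, first_mem_poly = 10,
    model = cme_model(scale = 0.01)), class = "rule_traj")
  st <- vesicle_stats(traj)
  expect_equal(st$adaptors_per_triskelion, 1900 / 100)
  expect_equal(st$pct_adaptor_recruited, 90)
  traj$first_mem_poly <- 0
  expect_equal(vesicle_stats(traj)$pct_adaptor_recruited, 100)
  # no vesicles: empty stats, not an error
  traj$vesicle_time <- numeric(0)
  traj$vesicle_comp <- comp[0, , drop = FALSE]
  traj$vesicle_full <- integer(0)
  empty <- vesicle_stats(traj)
  expect_equal(empty$n_vesicles, 0L)
  expect_true(is.na(empty$adaptors_per_triskelion))

  expect_equal(sphere_area_per_protein(1900), 4 * pi * 50^2 / 1900)
  expect_equal(sphere_area_per_protein(1900), 16.53, tolerance = 1e-3)
})

test_that("knocking out membrane adaptors suppresses vesicle formation", {
  n_ves <- function(overrides = NULL)
    length(simulate_rules(cme_model(copy_overrides = overrides),
                          t_end = 6, seed = 3)$vesicle_time)
  base <- n_ves()
  expect_gt(base, 1)
  expect_lt(n_ves(c(ENT = 0)), base / 2 + 1)
  expect_lt(n_ves(c(SLA2 = 0)), base / 2 + 1)
})
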