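test_that("simplified model has 19 laws sharing 36 distinct parameters", {
  kin <- fixture_kin()
  expect_length(kin$laws, 19)
  expect_equal(nrow(kin$specs), 36)
  expect_equal(length(unique(kin$specs$name)), 36)
  # per-law parameter lists sum to the registry with shared params once
  expect_equal(sum(vapply(kin$laws, function(l) length(l$parameters), 0L)),
               36L)
})

test_that("law structure matches the mechanistic forms", {
  kin <- fixture_kin()
  expect_setequal(kin$laws$PGM$required_metabolites, c("2pg", "3pg"))
  expect_setequal(kin$laws$PGM$parameters, c("kcat_PGM", "Keq_PGM"))
  expect_identical(kin$specs["Keq_ALDO", "units"], "mM")
  expect_identical(kin$specs["Kpyr_PDH", "units"], "mM^4")
  irr <- c("PTS", "PFK", "PYK", "PDH", "PPC", "G6PDH", "GND")
  expect_setequal(names(which(vapply(kin$laws, `[[`, TRUE, "irreversible"))),
                  irr)
})

test_that("fitted parameter table carries 36 values with half-widths", {
  fp <- load_fitted_parameters()
  expect_length(fp$theta, 36)
  expect_length(fp$half_width, 36)
  expect_equal(unname(fp$theta["Keq_PGI"]), 1.23)
  expect_equal(unname(fp$half_width["Keq_PGI"]), 0.29)
  expect_equal(unname(fp$theta["Keq_TPI"]), 0.114)
  expect_equal(unname(fp$half_width["Keq_TPI"]), 0.00031)
  expect_equal(unname(fp$theta["kcat_PTS"]), 20.7)
  expect_equal(unname(fp$theta["Kpyr_PDH"]), 2e-5)
  validate_parameters(fixture_kin(), fp$theta)
})

test_that("parameter bounds follow the global and equilibrium rules", {
  sp <- fixture_kin()$specs
  nk <- sp[sp$kind != "Keq", ]
  expect_true(all(nk$global_lb == 1e-6))
  expect_true(all(nk$global_ub == 1e4))
  ke <- sp[sp$kind == "Keq", ]
  expect_equal(ke$global_lb, 0.35 * ke$keq_ref)
  expect_equal(ke$global_ub, 2.85 * ke$keq_ref)
})

test_that("rate evaluation reproduces hand arithmetic and equilibria", {
  kin <- fixture_kin()
  v <- evaluate_rate(kin$laws$PGI, e = 0.1, conc = c(g6p = 1, f6p = 0.5),
                     theta = c(kcat_PGI = 40.2, Keq_PGI = 1.23))
  expect_equal(v, 40.2 * 0.1 * (1 - 0.5 / 1.23), tolerance = 1e-12)
  # equilibrium: zero net rate
  expect_equal(evaluate_rate(kin$laws$PGI, 0.1, c(g6p = 1, f6p = 1.23),
                             c(kcat_PGI = 40.2, Keq_PGI = 1.23)), 0)
  # knockout: zero enzyme
  expect_equal(evaluate_rate(kin$laws$ENO, 0, c(`2pg` = 1, pep = 0.2),
                             fitted_theta()), 0)
  expect_error(evaluate_rate(kin$laws$PGI, 0.1, c(g6p = 1), fitted_theta()),
               "missing required metabolite")
  expect_error(evaluate_rate(kin$laws$PTS, 0.1, c(pep = 1, pyr = 0),
                             fitted_theta()), "non-finite")
})

test_that("rates are homogeneous of degree one in the enzyme level", {
  kin <- fixture_kin()
  th <- fitted_theta()
  set.seed(5)
  for (rep in 1:5) {
    cc <- stats::setNames(exp(stats::runif(24, log(0.01), log(5))),
                          kin$metabolite_ids)
    alpha <- stats::runif(1, 0, 4)
    for (law in kin$laws) {
      v1 <- evaluate_rate(law, 1.3, cc, th)
      expect_equal(evaluate_rate(law, alpha * 1.3, cc, th), alpha * v1,
                   tolerance = 1e-10)
    }
  }
})

test_that("reversible laws change sign exactly at the equilibrium ratio", {
  kin <- fixture_kin()
  th <- fitted_theta()
  # sweep the product concentration through the equilibrium point
  sweeps <- list(
    PGI = list(fix = c(g6p = 2), var = "f6p", eq = 2 * th[["Keq_PGI"]]),
    TPI = list(fix = c(dhap = 1), var = "gap", eq = th[["Keq_TPI"]]),
    PGM = list(fix = c(`3pg` = 1.5), var = "2pg", eq = 1.5 * th[["Keq_PGM"]]),
    ENO = list(fix = c(`2pg` = 0.8), var = "pep", eq = 0.8 * th[["Keq_ENO"]]),
    RPE = list(fix = c(ru5pD = 1), var = "xu5pD", eq = th[["Keq_RPE"]]),
    RPI = list(fix = c(ru5pD = 1), var = "r5p", eq = th[["Keq_RPI"]]))
  for (nm in names(sweeps)) {
    sw <- sweeps[[nm]]
    law <- kin$laws[[nm]]
    for (frac in c(0.5, 0.9, 1.1, 2)) {
      cc <- c(sw$fix, stats::setNames(sw$eq * frac, sw$var))
      v <- evaluate_rate(law, 1, cc, th)
      expect_equal(sign(v), if (frac < 1) 1 else -1,
                   label = paste(nm, "at", frac, "x equilibrium"))
    }
  }
})

test_that("irreversible laws are nonnegative over the concentration box", {
  kin <- fixture_kin()
  th <- fitted_theta()
  set.seed(9)
  irr <- kin$laws[vapply(kin$laws, `[[`, TRUE, "irreversible")]
  for (rep in 1:40) {
    cc <- stats::setNames(exp(stats::runif(24, log(0.001), log(10))),
                          kin$metabolite_ids)
    for (law in irr)
      expect_gte(evaluate_rate(law, 1, cc, th), 0)
  }
})

test_that("adenylate energy charge follows its definition", {
  expect_equal(adenylate_energy_charge(1, 0, 0), 1)
  expect_equal(adenylate_energy_charge(0, 0, 1), 0)
  expect_equal(adenylate_energy_charge(0.8, 0.4, 0), 0.8 / 0.96)
  expect_error(adenylate_energy_charge(0, 0, 0), "zero")
  expect_error(adenylate_energy_charge(-1, 0, 1), "nonnegative")
})

test_that("kinetic model survives a JSON round trip", {
  kin <- fixture_kin()
  tmp <- tempfile(fileext = ".json")
  write_kinetic_json(kin, tmp)
  kin2 <- read_kinetic_json(tmp)
  expect_setequal(names(kin2$laws), names(kin$laws))
  th <- fitted_theta()
  cc <- stats::setNames(rep(0.5, 24), kin$metabolite_ids)
  for (k in names(kin$laws))
    expect_equal(evaluate_rate(kin2$laws[[k]], 1, cc, th),
                 evaluate_rate(kin$laws[[k]], 1, cc, th), tolerance = 1e-12)
})
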