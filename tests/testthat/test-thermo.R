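test_that("standard Gibbs energy follows -RT ln Keq", {
  expect_equal(delta_g_standard(1), 0)
  expect_equal(delta_g_standard(2.85, 298.15), -2.60, tolerance = 0.005)
  expect_equal(delta_g_standard(5512.1, 298.15), -21.36, tolerance = 0.01)
  expect_error(delta_g_standard(0), "positive")
  expect_error(delta_g_standard(-2), "positive")
})

test_that("condition-specific Gibbs energy adds the concentration term", {
  st <- c(A = -1, B = 1)
  # all concentrations 1 mM: the log terms vanish
  expect_equal(delta_g_condition(st, -5, c(A = 1, B = 1)), -5)
  # single-term arithmetic at RT = 2.4789 kJ/mol
  Tref <- 2.4789 / 8.314e-3
  expect_equal(delta_g_condition(st, 0, c(A = 1, B = exp(-1)), Tref),
               -2.4789, tolerance = 1e-6)
  # missing or non-positive participant: not computable, never a default
  expect_true(is.na(delta_g_condition(st, 0, c(A = 1))))
  expect_true(is.na(delta_g_condition(st, 0, c(A = 1, B = NA))))
  expect_true(is.na(delta_g_condition(st, 0, c(A = 1, B = 0))))
  # excluded species do not contribute
  st2 <- c(A = -1, B = 1, h = 1)
  expect_equal(delta_g_condition(st2, 0, c(A = 1, B = 1)), 0)
})

test_that("dG* is additive over reaction composition", {
  set.seed(3)
  for (rep in 1:10) {
    s1 <- c(A = -1, B = 1)
    s2 <- c(B = -2, C = 1)
    s3 <- c(A = -1, B = -1, C = 1)   # s1 + s2
    g1 <- stats::runif(1, -20, 5); g2 <- stats::runif(1, -20, 5)
    cc <- stats::setNames(exp(stats::runif(3, log(0.01), log(5))),
                          c("A", "B", "C"))
    expect_equal(delta_g_condition(s3, g1 + g2, cc),
                 delta_g_condition(s1, g1, cc) + delta_g_condition(s2, g2, cc),
                 tolerance = 1e-10)
  }
})

test_that("reversible laws and dG* agree on the direction of net flux", {
  model <- fixture_model()
  kin <- fixture_kin()
  th <- fitted_theta()
  S <- as.matrix(model$S)
  set.seed(17)
  for (k in c("PGI", "TPI", "PGM", "ENO", "RPE", "RPI")) {
    law <- kin$laws[[k]]
    keq <- th[[param_name(k, "Keq")]]
    dg0 <- delta_g_standard(keq)
    st <- S[, k]; st <- st[st != 0]
    for (rep in 1:25) {
      cc <- stats::setNames(exp(stats::runif(length(law$required_metabolites),
                                             log(0.005), log(5))),
                            law$required_metabolites)
      v <- evaluate_rate(law, 1, cc, th)
      dg <- delta_g_condition(st, dg0, cc)
      if (abs(v) > 1e-9)
        expect_equal(sign(dg), -sign(v),
                     label = paste(k, "thermodynamic sign consistency"))
    }
  }
})

test_that("thermo analysis covers reversible laws and skips missing data", {
  st <- small_study()
  kin <- fixture_kin()
  model <- fixture_model()
  conc <- st$truth$conc
  conc["s7p", 1] <- NA   # knock out one measurement
  res <- thermo_analysis(model, kin, st$theta_true, conc)
  expect_setequal(res$reaction,
                  names(which(!vapply(kin$laws, `[[`, TRUE, "irreversible"))))
  dstar <- attr(res, "dG_star")
  expect_true(is.na(dstar["TKT1", 1]))    # s7p participates
  expect_false(is.na(dstar["PGI", 1]))
  expect_equal(res["TKT1", "n_computable"], ncol(conc) - 1)
})

test_that("equilibrium classification applies the -10 kJ/mol rule", {
  df <- data.frame(reaction = c("a", "b", "c", "d"),
                   dG_standard = 0,
                   mean = c(-15, -0.3, -5, NA),
                   sd = 1, n_computable = c(3, 3, 3, 0))
  cl <- classify_equilibrium(df)
  expect_identical(cl$classification,
                   c("far", "near", "intermediate", "unclassified"))
})

test_that("metabolite effects report mode and strength from Km ratios", {
  kin <- fixture_kin()
  th <- fitted_theta()
  conc <- matrix(1, 24, 4,
                 dimnames = list(kin$metabolite_ids, paste0("c", 1:4)))
  conc["fdp", ] <- c(4, 5, 6, 5)    # >> Kfdp_PPC = 2.5? ratio 2 -> intermediate
  th["Kfdp_PPC"] <- 0.01            # force strong activation
  eff <- classify_metabolite_effects(kin, th, conc)
  ppc <- eff[eff$parameter == "Kfdp_PPC", ]
  expect_identical(ppc$mode, "activation")
  expect_identical(ppc$strength, "strong")
  aldo <- eff[eff$parameter == "Kfdp_ALDO", ]
  expect_identical(aldo$mode, "inhibition")
  # metabolite with all-missing concentrations emits no effect
  conc2 <- conc; conc2["pyr", ] <- NA
  eff2 <- classify_metabolite_effects(kin, th, conc2)
  expect_false(any(eff2$parameter == "Kpyr_PDH"))
  # Km of the same order as the concentration: intermediate
  th["Kpep_PPC"] <- 1
  eff3 <- classify_metabolite_effects(kin, th, conc)
  expect_identical(eff3$strength[eff3$parameter == "Kpep_PPC"],
                   "intermediate")
})
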