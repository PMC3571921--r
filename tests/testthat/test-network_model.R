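test_that("central fixture has the expected structure", {
  m <- fixture_model()
  expect_length(m$kinetic_rxns, 19)
  expect_setequal(m$kinetic_rxns, names(fixture_kin()$laws))
  expect_true(m$biomass_rxn %in% m$reactions$id)
  expect_true(m$glucose_uptake_rxn %in% m$reactions$id)
  expect_true(all(m$reactions$lb <= m$reactions$ub))
  expect_true(all(m$reactions$lb[!m$reactions$reversible] >= 0))
  # exchanges for glucose, oxygen, CO2 and fermentative secretion present
  expect_true(all(c("EX_glc", "EX_o2", "EX_co2") %in% m$reactions$id))
  expect_true(all(c("EX_ac", "EX_etoh", "EX_lac", "EX_for") %in%
                    m$reactions$id))
})

test_that("fixture admits a steady state at biomass flux 0.2", {
  m <- block_reactions(fixture_model(), fixture_model()$fermentative_rxns)
  lb <- m$reactions$lb; ub <- m$reactions$ub
  i <- match("BIOMASS", m$reactions$id)
  lb[i] <- ub[i] <- 0.2
  fe <- kfba:::lp_feasibility(as.matrix(m$S), rep(0, nrow(m$S)), lb, ub)
  expect_true(fe$feasible)
  expect_gt(sum(abs(fe$x)), 1)   # a genuinely nonzero flux distribution
})

test_that("every internal metabolite is producible and consumable", {
  m <- fixture_model()
  S <- as.matrix(m$S)
  internal <- m$metabolites$id[m$metabolites$compartment == "c"]
  for (met in internal) {
    expect_true(any(S[met, ] > 0), label = paste(met, "has a producer"))
    expect_true(any(S[met, ] < 0), label = paste(met, "has a consumer"))
  }
})

test_that("block_reactions zeroes bounds and downstream fluxes", {
  m <- fixture_model()
  mb <- block_reactions(m, c("PFL", "LDH"))
  expect_equal(mb$reactions$lb[mb$reactions$id == "PFL"], 0)
  expect_equal(mb$reactions$ub[mb$reactions$id == "PFL"], 0)
  expect_identical(block_reactions(m, character(0)), m)
  expect_error(block_reactions(m, "NOPE"), "unknown reaction")
  # blocked reactions carry zero flux in an FBA solution
  fba <- solve_fba(m, 0.2)
  expect_lt(max(abs(fba$v[m$fermentative_rxns])), 1e-8)
})

test_that("JSON round trip preserves the model", {
  m <- fixture_model()
  tmp <- tempfile(fileext = ".json")
  write_model_json(m, tmp)
  m2 <- read_model_json(tmp)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_identical(m2$kinetic_rxns, m$kinetic_rxns)
})

test_that("unknown fixture name errors", {
  expect_error(load_fixture("no_such_network"), "unknown fixture")
})

test_that("SBML round trip preserves stoichiometry, bounds, designations", {
  m <- fixture_model()
  for (lv in c(3, 2)) {
    tmp <- tempfile(fileext = ".xml")
    write_sbml(m, tmp, level = lv)
    m2 <- load_sbml(tmp)
    expect_equal(as.matrix(m2$S)[rownames(m$S), colnames(m$S)],
                 as.matrix(m$S), label = paste("level", lv))
    expect_equal(m2$reactions$lb, m$reactions$lb)
    expect_equal(m2$reactions$ub, m$reactions$ub)
    expect_setequal(m2$kinetic_rxns, m$kinetic_rxns)
    expect_identical(m2$biomass_rxn, m$biomass_rxn)
  }
})

test_that("minimal hand-written SBML documents parse with default bounds", {
  doc <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
<model id="toy"><listOfCompartments><compartment id="c"/></listOfCompartments>
<listOfSpecies>
<species id="M_A" compartment="c"/><species id="M_B" compartment="c"/>
</listOfSpecies>
<listOfReactions>
<reaction id="R_conv" reversible="true">
<listOfReactants><speciesReference species="M_A" stoichiometry="1"/></listOfReactants>
<listOfProducts><speciesReference species="M_B" stoichiometry="1"/></listOfProducts>
</reaction>
<reaction id="R_irrev" reversible="false">
<listOfReactants><speciesReference species="M_B" stoichiometry="1"/></listOfReactants>
</reaction>
</listOfReactions></model></sbml>'
  tmp <- tempfile(fileext = ".xml")
  writeLines(doc, tmp)
  m <- load_sbml(tmp)
  expect_equal(unname(as.matrix(m$S)[, "conv"]), c(-1, 1))
  expect_equal(m$reactions$lb, c(-1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000))
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></model>", bad)
  expect_error(load_sbml(bad), "malformed|zero reactions")
})
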