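test_that("FBA minimizes glucose uptake and matches an independent solver", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  mb <- block_reactions(model, model$fermentative_rxns)
  lb <- mb$reactions$lb; ub <- mb$reactions$ub
  i <- match("BIOMASS", mb$reactions$id)
  lb[i] <- ub[i] <- 0.2
  ref <- scipy_lp_objective(as.numeric(mb$reactions$id == "PTS"),
                            mb$S, lb, ub)
  expect_equal(fba$objective, ref, tolerance = 1e-6)
  expect_lt(max(abs(as.matrix(model$S) %*% fba$v)), 1e-7)
  expect_equal(unname(fba$v["BIOMASS"]), 0.2, tolerance = 1e-9)
})

test_that("zero growth with zero maintenance needs no glucose", {
  m <- fixture_model()
  m$reactions$lb[m$reactions$id == "ATPM"] <- 0
  fba <- solve_fba(m, 0)
  expect_equal(fba$objective, 0, tolerance = 1e-7)
})

test_that("growth beyond network capacity is infeasible", {
  expect_error(solve_fba(fixture_model(), 500), "infeasible")
})

test_that("min_violations matches exhaustive enumeration on small instances", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  v0 <- fba$v
  set.seed(21)
  base <- kfba:::kfba_base(model, 0.2)
  for (rep in 1:3) {
    kr <- sample(intersect(names(fixture_kin()$laws), names(v0)), 4)
    b <- data.frame(condition = "t", reaction = kr,
                    v_min = v0[kr] - stats::runif(4, 0.01, 0.3),
                    v_max = v0[kr] + stats::runif(4, 0.01, 0.3),
                    atp_ranged = FALSE)
    # randomly make some bounds conflict with the optimum
    flip <- stats::runif(4) < 0.5
    b$v_min[flip] <- v0[kr][flip] + 0.2
    b$v_max[flip] <- v0[kr][flip] + 0.4
    ns <- min_violations(model, b, 0.2)
    # exhaustive check over all 2^(2*4) binary assignments
    best <- Inf
    for (mask in 0:(2^8 - 1)) {
      y <- as.integer(intToBits(mask))[1:8]
      ym <- y[1:4]; yp <- y[5:8]
      lb <- base$lb; ub <- base$ub
      ik <- match(kr, base$rxn)
      ok <- TRUE
      for (q in 1:4) {
        lo <- if (ym[q] == 1) base$lb[ik[q]] else max(base$lb[ik[q]], b$v_min[q])
        hi <- if (yp[q] == 1) base$ub[ik[q]] else min(base$ub[ik[q]], b$v_max[q])
        if (lo > hi + 1e-9) { ok <- FALSE; break }
        lb[ik[q]] <- lo; ub[ik[q]] <- hi
      }
      if (!ok) next
      fe <- kfba:::lp_feasibility(base$S, rep(0, nrow(base$S)), lb, ub)
      if (fe$feasible) best <- min(best, sum(y))
    }
    expect_equal(as.integer(ns), as.integer(best),
                 label = paste("enumeration replicate", rep))
  }
})

test_that("bounds from a feasible distribution need no violations", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  kr <- intersect(names(fixture_kin()$laws), names(fba$v))
  b <- data.frame(condition = "t", reaction = kr,
                  v_min = fba$v[kr] - 0.05, v_max = fba$v[kr] + 0.05,
                  atp_ranged = FALSE)
  expect_equal(as.integer(min_violations(model, b, 0.2)), 0L)
  kf <- solve_kfba(model, b, 0.2)
  expect_true(kf$audit$ok)
  expect_true(all(kf$v[kr] >= b$v_min - 1e-6 & kf$v[kr] <= b$v_max + 1e-6))
  # empty bound set short-circuits to FBA
  empty <- b[0, ]
  expect_equal(as.integer(min_violations(model, empty, 0.2)), 0L)
})

test_that("relaxing every bound reproduces the FBA flux vector", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  kr <- intersect(names(fixture_kin()$laws), names(fba$v))
  b <- data.frame(condition = "t", reaction = kr,
                  v_min = fba$v[kr] + 1, v_max = fba$v[kr] + 2,
                  atp_ranged = FALSE)   # deliberately inconsistent bounds
  kf <- solve_kfba(model, b, 0.2, n_star = 2L * length(kr))
  expect_lt(max(abs(kf$v - fba$v)), 1e-6)
})

test_that("the KFBA objective is non-increasing in the violation budget", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  kr <- intersect(names(fixture_kin()$laws), names(fba$v))[1:6]
  set.seed(4)
  b <- data.frame(condition = "t", reaction = kr,
                  v_min = fba$v[kr] * stats::runif(6, 1.02, 1.2),
                  v_max = fba$v[kr] * stats::runif(6, 1.3, 1.6),
                  atp_ranged = FALSE)
  ns <- as.integer(min_violations(model, b, 0.2))
  objs <- vapply(ns:(ns + 3), function(n)
    solve_kfba(model, b, 0.2, n_star = n)$objective, 0)
  expect_true(all(diff(objs) <= 1e-7))
})

test_that("a binding kinetic lower bound raises the glucose demand", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  # force extra flux through pyruvate kinase (an ATP-neutral detour that
  # wastes PEP): KFBA must take up more glucose than FBA
  b <- data.frame(condition = "t", reaction = "PYK",
                  v_min = unname(fba$v["PYK"]) + 1.5, v_max = 1000,
                  atp_ranged = FALSE)
  kf <- solve_kfba(model, b, 0.2, n_star = 0L)
  expect_gt(kf$objective, fba$objective + 1e-4)
  expect_true(kf$audit$ok)
})

test_that("prediction evaluation deduplicates coupled reactions", {
  model <- fixture_model()
  fba <- solve_fba(model, 0.2)
  ev <- evaluate_predictions(fba$v, fba$v[c("PTS", "PGI", "GAPD")],
                             model, 0.2)
  expect_equal(ev$mean_residual, 0)
  expect_equal(unname(ev$yield), 0.2 / fba$objective, tolerance = 1e-6)
  # PGM and ENO are stoichiometrically coupled (linear chain): one group
  g <- coupling_groups(model)
  expect_equal(unname(g["PGM"]), unname(g["ENO"]))
  meas <- fba$v[c("PGM", "ENO")] + 0.3   # equal residual on both members
  ev2 <- evaluate_predictions(fba$v, meas, model, 0.2)
  expect_equal(ev2$n_groups, 1)
  expect_equal(ev2$mean_residual, 0.09, tolerance = 1e-9)
  # zero predicted uptake flags the yield as undefined
  vz <- fba$v; vz["PTS"] <- 0
  ev3 <- evaluate_predictions(vz, meas, model, 0.2)
  expect_true(ev3$yield_undefined)
})

test_that("sign test gives the exact two-sided binomial probabilities", {
  expect_equal(as.numeric(sign_test(rep(1, 5), rep(2, 5))), 0.0625)
  expect_equal(as.numeric(sign_test(c(1, 1, 1, 1, 3), rep(2, 5))), 0.375)
  expect_equal(as.numeric(sign_test(c(1, 1, 2, 2), c(2, 2, 1, 1))), 1)
  # ties are dropped before the test
  expect_equal(as.numeric(sign_test(c(1, 1, 1, 1, 1, 7), c(2, 2, 2, 2, 2, 7))),
               0.0625)
  expect_warning(p <- sign_test(c(1, 2), c(1, 2)), "tied")
  expect_true(is.na(p))
})
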