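# one-law kinetic model (phosphoglycerate mutase) for focused fits
pgm_only_kin <- function() {
  kin <- fixture_kin()
  structure(list(laws = kin$laws["PGM"],
                 specs = kin$specs[kin$specs$reaction == "PGM", ],
                 metabolite_ids = c("2pg", "3pg", "atp", "adp", "amp", "glc")),
            class = "kinetic_model")
}

pgm_toy_problem <- function(kcat = 10, keq = 0.5) {
  kin1 <- pgm_only_kin()
  ids <- c("c1", "c2", "c3")
  c3pg <- c(1.2, 0.8, 1.5)
  c2pg <- c(0.3, 0.25, 0.4)
  e <- c(0.5, 0.9, 0.7)
  v <- kcat * e * (1 - c2pg / (c3pg * keq))
  cond <- data.frame(condition_id = ids, dilution_rate = 0.2, knockout = NA)
  mm <- rbind(`2pg` = c2pg, `3pg` = c3pg, adp = c(0.5, 0.6, 0.4),
              amp = c(0.2, 0.15, 0.25), atp = NA_real_)
  colnames(mm) <- ids
  ms <- mm * 0.05
  em <- matrix(e, 1, 3, dimnames = list("PGM", ids))
  ds <- omics_dataset(cond, matrix(v, 1, 3, dimnames = list("PGM", ids)),
                      mm, ms, em, em * 0.05)
  W <- compute_weights(ds)
  vK <- matrix(v, 1, 3, dimnames = list("PGM", ids))
  wsls_problem(kin1, ds, W, vK)
}

test_that("single-reaction fit recovers kcat and Keq to 1e-4", {
  pb <- pgm_toy_problem()
  fit <- solve_wsls(pb, n_starts = 3, seed = 2)
  expect_lt(fit$wsls, 1e-8)
  expect_equal(unname(fit$theta["kcat_PGM"]), 10, tolerance = 1e-4)
  expect_equal(unname(fit$theta["Keq_PGM"]), 0.5, tolerance = 1e-4)
  # 2-D grid oracle around the optimum: no grid point beats the fit
  mats <- kfba:::problem_matrices(pb)
  grid_obj <- function(kc, kq) {
    f <- kc * (1 - mats$cexp["2pg", ] / (mats$cexp["3pg", ] * kq))
    ehat <- pb$vK[1, ] / f
    sum(mats$W_e[1, ] * (ehat - mats$eexp[1, ])^2)
  }
  kcs <- 10 * exp(seq(-0.5, 0.5, length.out = 21))
  kqs <- 0.5 * exp(seq(-0.3, 0.3, length.out = 21))
  vals <- outer(kcs, kqs, Vectorize(grid_obj))
  expect_lte(fit$wsls, min(vals) + 1e-8)
  best <- which(vals == min(vals), arr.ind = TRUE)
  expect_equal(kcs[best[1]], 10, tolerance = 0.06)
  expect_equal(kqs[best[2]], 0.5, tolerance = 0.04)
})

test_that("the inner problem at true parameters fits noiseless data exactly", {
  st <- small_study()
  tr <- noiseless_dataset(st)
  pb <- wsls_problem(fixture_kin(), tr, compute_weights(tr),
                     st$truth$v[names(fixture_kin()$laws), , drop = FALSE])
  fit <- solve_wsls(pb, n_starts = 1, seed = 1, theta_fixed = st$theta_true)
  expect_lt(fit$wsls, 1e-6)
  expect_equal(fit$enzyme_bound_violation, 0)
  expect_true(all(fit$aec >= 0.8 - 1e-9))
  # rate-law equality holds exactly by construction of the exact phase
  kin <- fixture_kin()
  for (l in seq_len(ncol(fit$e_hat))) {
    v <- pb$vK[, l]
    f <- vapply(names(kin$laws), function(k)
      kfba:::rate_factor(kin$laws[[k]], as.list(fit$c_hat[, l]),
                         fit$theta), 0)
    expect_lt(max(abs(fit$e_hat[, l] * f - v) / pmax(1, abs(v))), 1e-6)
  }
})

test_that("inner objective is separable across conditions at fixed theta", {
  st <- small_study()
  tr <- noiseless_dataset(st)
  ids <- st$split$train
  kin <- fixture_kin()
  vK <- st$truth$v[names(kin$laws), , drop = FALSE]
  wsls_of <- function(sel) {
    ds <- subset_conditions(tr, sel)
    pb <- wsls_problem(kin, ds, compute_weights(ds), vK[, sel, drop = FALSE])
    solve_wsls(pb, n_starts = 1, seed = 1, theta_fixed = st$theta_true)$wsls
  }
  a <- wsls_of(ids[1:2])
  b <- wsls_of(ids[3])
  ab <- wsls_of(ids[1:3])
  expect_equal(ab, a + b, tolerance = 1e-4)
})

test_that("an unattainable energy-charge floor is reported as infeasible", {
  st <- small_study()
  tr <- subset_conditions(st$dataset, st$split$train)
  expect_error(
    wsls_problem(fixture_kin(), tr, compute_weights(tr),
                 st$truth$v[names(fixture_kin()$laws), , drop = FALSE],
                 aec_min = 1.01),
    "infeasible")
})

test_that("profile CI reproduces the closed-form chi-square half-width", {
  theta_star <- 1; s <- 0.05
  fun <- function(lv) ((exp(lv) - theta_star) / s)^2
  q <- stats::qchisq(0.95, 1)
  ci <- kfba:::profile_param_ci(fun, log(theta_star), 0, delta = 0.05,
                                q = q, lb_log = log(1e-6), ub_log = log(1e4))
  expect_equal(ci$upper, theta_star + s * sqrt(q), tolerance = 0.05)
  expect_equal(ci$lower, theta_star - s * sqrt(q), tolerance = 0.05)
  expect_identical(ci$flag_lower, "ok")
})

test_that("a flat profile yields an interval spanning the global bounds", {
  fun <- function(lv) 0
  ci <- kfba:::profile_param_ci(fun, log(0.3), 0, delta = 0.1,
                                q = stats::qchisq(0.95, 1),
                                lb_log = log(1e-6), ub_log = log(1e4))
  expect_equal(ci$lower, 1e-6)
  expect_equal(ci$upper, 1e4)
  expect_identical(ci$flag_upper, "unbounded")
  expect_gt((ci$upper - ci$lower) / 0.3, 100)
})

test_that("fit coverage counts measurements within one standard deviation", {
  ids <- c("c1", "c2")
  mm <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("g6p", "f6p"), ids))
  em <- matrix(c(0.1, 0.2), 1, 2, dimnames = list("PGI", ids))
  ds <- omics_dataset(
    data.frame(condition_id = ids, dilution_rate = 0.2, knockout = NA),
    matrix(1, 1, 2, dimnames = list("PGI", ids)),
    mm, mm * 0.1, em, em * 0.1)
  perfect <- structure(list(c_hat = mm, e_hat = em,
                            problem = list(dataset = ds)),
                       class = "wsls_fit")
  cov <- fit_coverage(perfect, ds)
  expect_equal(cov$pooled, 1)
  off <- perfect
  off$c_hat <- mm + 2 * mm * 0.1
  off$e_hat <- em + 2 * em * 0.1
  cov2 <- fit_coverage(off, ds)
  expect_equal(cov2$pooled, 0)
})

test_that("simplification diagnostics flag extreme binding coefficients", {
  kin <- fixture_kin()
  th <- fitted_theta()
  c_hat <- matrix(1, 24, 3,
                  dimnames = list(kin$metabolite_ids, c("a", "b", "c")))
  mk_fit <- function(theta) structure(
    list(theta = theta, c_hat = c_hat, problem = list(kin = kin)),
    class = "wsls_fit")
  th1 <- th; th1["Kfdp_ALDO"] <- 1e-6
  d1 <- simplification_diagnostics(mk_fit(th1))
  expect_true(any(d1$name == "Kfdp_ALDO" & d1$flag == "km_negligible"))
  expect_true(any(d1$name == "Kfdp_ALDO" & d1$flag == "at_lower_bound"))
  expect_match(d1$suggestion[d1$flag == "km_negligible"][1], "drop Km")
  th2 <- th; th2["Kfdp_PPC"] <- 1e4
  d2 <- simplification_diagnostics(mk_fit(th2))
  expect_true(any(d2$name == "Kfdp_PPC" & d2$flag == "km_dominant"))
  expect_match(d2$suggestion[d2$flag == "km_dominant"][1], "drop metabolite")
  th3 <- th; th3["Kfdp_PPC"] <- 0.5   # well-scaled vs conc 1
  d3 <- simplification_diagnostics(mk_fit(th3))
  expect_false(any(d3$name == "Kfdp_PPC"))
})
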