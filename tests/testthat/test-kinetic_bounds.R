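test_that("flux_range is exact for a law linear in its only parameter", {
  kin <- fixture_kin()
  e <- 0.3; atp <- 2.5
  fr <- flux_range(kin$laws$PFK, e, list(atp = atp),
                   c(kcat_PFK = 10), c(kcat_PFK = 40))
  expect_equal(unname(fr), c(10 * e * atp, 40 * e * atp))
  # zero enzyme: degenerate interval at zero
  fr0 <- flux_range(kin$laws$PFK, 0, list(atp = atp),
                    c(kcat_PFK = 10), c(kcat_PFK = 40))
  expect_equal(unname(fr0), c(0, 0))
  # point interval: collapses to the evaluated rate
  th <- fitted_theta()
  frp <- flux_range(kin$laws$PFK, e, list(atp = atp),
                    th["kcat_PFK"], th["kcat_PFK"])
  expect_equal(frp[["v_min"]], frp[["v_max"]])
  expect_equal(frp[["v_min"]],
               evaluate_rate(kin$laws$PFK, e, c(atp = atp), th))
})

test_that("vertex enumeration matches a dense parameter grid on every law", {
  kin <- fixture_kin()
  th <- fitted_theta()
  cc <- c(glc = 0.1, g6p = 1.5, f6p = 0.6, fdp = 1, dhap = 0.25, gap = 0.02,
          `13dpg` = 0.05, `3pg` = 1, `2pg` = 0.3, pep = 0.25, pyr = 0.8,
          `6pg` = 0.5, ru5pD = 1, xu5pD = 0.45, r5p = 0.8, s7p = 0.8,
          e4p = 0.0085, atp = 3, adp = 0.5, amp = 0.2, nad = 1.5,
          nadh = 0.1, nadp = 0.15, nadph = 0.25)
  for (k in names(kin$laws)) {
    law <- kin$laws[[k]]
    lo <- th[law$parameters] * 0.6
    hi <- th[law$parameters] * 1.7
    fr <- flux_range(law, 0.2, as.list(cc[law$required_metabolites]),
                     lo, hi)
    # 5-point grid per parameter
    grids <- lapply(law$parameters, function(p)
      seq(lo[[p]], hi[[p]], length.out = 5))
    names(grids) <- law$parameters
    g <- expand.grid(grids)
    f <- vapply(seq_len(nrow(g)), function(i) {
      thi <- unlist(g[i, , drop = FALSE]); names(thi) <- law$parameters
      0.2 * kfba:::rate_factor(law, as.list(cc[law$required_metabolites]),
                               thi)
    }, 0)
    expect_lte(fr[["v_min"]], min(f) + 1e-6 * max(1, abs(min(f))))
    expect_gte(fr[["v_max"]], max(f) - 1e-6 * max(1, abs(max(f))))
    expect_equal(fr[["v_min"]], min(f),
                 tolerance = 1e-6, label = paste(k, "grid min"))
    expect_equal(fr[["v_max"]], max(f),
                 tolerance = 1e-6, label = paste(k, "grid max"))
  }
})

test_that("enlarging a confidence box never shrinks the flux interval", {
  kin <- fixture_kin()
  th <- fitted_theta()
  cc <- list(fdp = 1, gap = 0.05, dhap = 0.3)
  lo <- th[kin$laws$ALDO$parameters] * 0.8
  hi <- th[kin$laws$ALDO$parameters] * 1.2
  fr1 <- flux_range(kin$laws$ALDO, 0.5, cc, lo, hi)
  fr2 <- flux_range(kin$laws$ALDO, 0.5, cc, lo * 0.5, hi * 2)
  expect_lte(fr2[["v_min"]], fr1[["v_min"]])
  expect_gte(fr2[["v_max"]], fr1[["v_max"]])
})

test_that("condition-level bounds honor data availability rules", {
  st <- small_study()
  kin <- fixture_kin()
  th <- st$theta_true
  ci_point <- data.frame(value = th[kin$specs$name],
                         lower = th[kin$specs$name],
                         upper = th[kin$specs$name])
  rownames(ci_point) <- kin$specs$name
  ds <- noiseless_dataset(st)
  cid <- st$split$test[1]
  b <- compute_kinetic_bounds(kin, ds, cid, ci_point)
  # point parameters + exact concentrations, except ATP which is ranged:
  # non-ATP laws pin the true flux exactly
  vtrue <- st$truth$v[, cid]
  atp_laws <- names(which(vapply(kin$laws, function(l)
    "atp" %in% l$required_metabolites, TRUE)))
  for (i in seq_len(nrow(b))) {
    r <- b$reaction[i]
    expect_lte(b$v_min[i], vtrue[r] + 1e-7, label = paste(r, "lower"))
    expect_gte(b$v_max[i], vtrue[r] - 1e-7, label = paste(r, "upper"))
    if (!r %in% atp_laws)
      expect_equal(b$v_min[i], b$v_max[i], tolerance = 1e-9,
                   label = paste(r, "pinned"))
    expect_identical(b$atp_ranged[i], r %in% atp_laws)
  }
  # a missing pyruvate measurement removes the PTS and PDH bounds
  ds2 <- ds
  ds2$met_mean["pyr", cid] <- NA
  b2 <- compute_kinetic_bounds(kin, ds2, cid, ci_point)
  expect_false(any(b2$reaction %in% c("PTS", "PDH")))
  expect_true("PGI" %in% b2$reaction)
})
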