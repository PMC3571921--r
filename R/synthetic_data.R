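#' Synthetic chemostat studies with known ground truth
#'
#' Emulates a glucose-limited chemostat study of E. coli: a parental strain
#' grown at several dilution rates plus single-knockout strains at a
#' reference dilution rate.  For every condition the generator (1) samples a
#' steady-state flux distribution from the stoichiometric model with
#' fermentation blocked, the biomass flux fixed to the dilution rate, a
#' sampled glucose yield, and a sampled oxidative pentose phosphate split;
#' (2) solves for metabolite and enzyme concentrations that satisfy every
#' rate law exactly (`v = e f(c; theta_true)`), the adenylate energy charge
#' constraint and the concentration/enzyme boxes; and (3) emits noisy
#' multiplicative log-normal measurements with per-cell standard deviations
#' `truth * noise_cv`.  ATP is never reported measured, mirroring the data
#' situation the energy-charge constraint was designed for.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

# conservative cap on the flux a floor-level enzyme can carry: box maximum of
# |f| over the concentration box at theta_true (laws are monotone per
# concentration, so box vertices suffice)
law_flux_cap <- function(law, theta, conc_bounds = c(0.001, 10),
                         e_floor = 0.001) {
  mets <- law$required_metabolites
  grid <- expand.grid(rep(list(conc_bounds), length(mets)))
  names(grid) <- mets
  fmax <- 0
  for (i in seq_len(nrow(grid))) {
    f <- rate_factor(law, as.list(grid[i, , drop = FALSE]), theta)
    if (is.finite(f)) fmax <- max(fmax, abs(f))
  }
  max(1e-4, 0.8 * e_floor * fmax)
}

# base metabolite concentrations (mM): a glycolytic steady state displaced
# forward from equilibrium under the shipped equilibrium constants
.base_conc <- c(
  glc = 0.1, g6p = 1.5, f6p = 0.6, fdp = 1.0, dhap = 0.25, gap = 0.02,
  `13dpg` = 0.05, `3pg` = 1.0, `2pg` = 0.3, pep = 0.25, pyr = 0.8,
  `6pg` = 0.5, ru5pD = 1.0, xu5pD = 0.45, r5p = 0.8, s7p = 0.8,
  e4p = 0.0085, atp = 3.0, adp = 0.5, amp = 0.2,
  nad = 1.5, nadh = 0.1, nadp = 0.15, nadph = 0.25)

# sample one steady-state flux distribution
sample_condition_fluxes <- function(model, D, knockout, theta, kin) {
  mb <- block_reactions(model, model$fermentative_rxns)
  r <- mb$reactions
  lb <- r$lb; ub <- r$ub
  lb[r$id == model$biomass_rxn] <- ub[r$id == model$biomass_rxn] <- D
  ipts <- which(r$id == model$glucose_uptake_rxn)
  if (!is.na(knockout)) {
    cap0 <- law_flux_cap(kin$laws[[knockout]], theta)
    ik0 <- which(r$id == knockout)
    lb[ik0] <- max(lb[ik0], min(0.005, 0.5 * cap0))
    ub[ik0] <- max(min(ub[ik0], cap0), lb[ik0])
  }
  # chemostat cells run close to, but not exactly at, the maximal biomass
  # yield: sample the glucose uptake 8-30% above the minimal feasible
  # uptake at this dilution rate (which depends on maintenance and any
  # knockout caps)
  fobj <- numeric(nrow(r)); fobj[ipts] <- 1
  umin <- lp_solve(fobj, Aeq = as.matrix(mb$S), beq = rep(0, nrow(mb$S)),
                   lb = lb, ub = ub)
  if (umin$status != "optimal") return(NULL)
  uptake <- umin$obj * stats::runif(1, 1.08, 1.30)
  lb[ipts] <- uptake * 0.97; ub[ipts] <- uptake * 1.03
  # pyruvate kinase is minimum-norm-fragile (PTS and PPC can cover all PEP
  # drain); keep it carrying a realistic share of uptake unless knocked out
  if (is.na(knockout) || knockout != "PYK") {
    ipyk <- which(r$id == "PYK")
    if (length(ipyk)) lb[ipyk] <- max(lb[ipyk], 0.03 * uptake)
  }
  # keep the oxidative PPP active (a sampled share of uptake flows through
  # G6PDH) except when G6PDH itself is depleted; upper-glycolysis knockouts
  # route extra carbon through the PPP on top of this floor
  if (is.na(knockout) || knockout != "G6PDH") {
    ig <- which(r$id == "G6PDH")
    lb[ig] <- max(lb[ig], stats::runif(1, 0.15, 0.35) * uptake)
  }
  t <- stats::rnorm(nrow(r), 0, 0.3 * uptake)
  s <- qp_solve(f = -2 * t, H = diag(2, nrow(r)),
                Aeq = as.matrix(mb$S), beq = rep(0, nrow(mb$S)),
                lb = lb, ub = ub)
  if (s$status != "optimal") return(NULL)
  stats::setNames(s$x, r$id)
}

# solve for concentrations/enzymes consistent with given kinetic fluxes
solve_condition_state <- function(kin, vk, theta, knockout,
                                  c_tgt, aec_min = 0.8,
                                  conc_bounds = c(0.001, 10),
                                  enzyme_bounds = c(0.001, 10)) {
  M <- setdiff(kin$metabolite_ids, "glc")
  krxn <- names(kin$laws)
  cexp <- matrix(c_tgt[M], length(M), 1, dimnames = list(M, "cond"))
  W_c <- matrix(1 / (0.2 * cexp)^2, length(M), 1, dimnames = dimnames(cexp))
  W_c["atp", ] <- 0
  e_tgt <- rep(0.1, length(krxn))
  names(e_tgt) <- krxn
  if (!is.na(knockout)) e_tgt[knockout] <- enzyme_bounds[1]
  eexp <- matrix(e_tgt, length(krxn), 1, dimnames = list(krxn, "cond"))
  W_e <- matrix(1 / (1.0 * eexp)^2, length(krxn), 1, dimnames = dimnames(eexp))
  if (!is.na(knockout)) W_e[knockout, ] <- 1 / (0.05 * eexp[knockout, ])^2
  vK <- matrix(vk[krxn], length(krxn), 1, dimnames = list(krxn, "cond"))
  obA <- make_wsls_objective(kin, vK, cexp, W_c, eexp, W_e, aec_min,
                             conc_bounds, enzyme_bounds, theta_fixed = theta,
                             e_free = TRUE)
  ob <- make_wsls_objective(kin, vK, cexp, W_c, eexp, W_e, aec_min,
                            conc_bounds, enzyme_bounds, theta_fixed = theta)
  Mf <- setdiff(M, "atp")
  nB <- length(ob$lower)
  emin <- enzyme_bounds[1]; emax <- enzyme_bounds[2]
  for (s in 1:5) {
    c0 <- pmin(pmax(cexp[Mf, 1] * exp(stats::rnorm(length(Mf), 0,
                                                   if (s == 1) 0 else 0.2)),
                    conc_bounds[1] * 1.5), conc_bounds[2] / 1.5)
    x0A <- c(log(c0), 0.25, log(pmax(pmin(e_tgt, enzyme_bounds[2] / 2),
                                     enzyme_bounds[1] * 2)))
    fitA <- tryCatch(
      stats::optim(x0A, fn = obA$fn, gr = obA$gr, method = "L-BFGS-B",
                   lower = obA$lower, upper = obA$upper,
                   control = list(maxit = 1000, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(fitA)) next
    fit <- tryCatch(
      stats::optim(fitA$par[seq_len(nB)], fn = ob$fn, gr = ob$gr,
                   method = "L-BFGS-B", lower = ob$lower, upper = ob$upper,
                   control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    d <- ob$detail(fit$par)
    if (min(d$E) >= emin - 1e-9 && max(d$E) <= emax + 1e-9)
      return(list(C = d$C[, 1], E = d$E[, 1]))
  }
  NULL
}

#' Generate a synthetic multi-omic chemostat study
#'
#' @param model A `stoich_model` (the central fixture by default usage).
#' @param kin A `kinetic_model`.
#' @param n_train,n_test Numbers of training and held-out test conditions
#'   (defaults 20 and 5, the canonical study design).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise on metabolite and enzyme concentrations (the
#'   quantities carrying mean/sd columns and inverse-variance weights in
#'   the estimation objective).
#' @param flux_noise_cv Optional noise on the reported fluxes (default 0:
#'   fluxes are reported as the steady-state values the estimator fixes
#'   them to; flux uncertainty is outside the WSLS error model).
#' @param seed Integer seed; the study is a deterministic function of it.
#' @param theta_true Ground-truth parameters (default: the shipped fitted
#'   values).
#' @param dilution_rates Parental-strain dilution rates (1/h).
#' @param knockout_candidates Reactions eligible for knockout conditions;
#'   defaults to every kinetic reaction except the ones whose depletion to
#'   the enzyme floor cannot sustain chemostat growth in the central
#'   network: glucose uptake (PTS), pyruvate dehydrogenase (sole acetyl-CoA
#'   source with fermentation blocked), phosphofructokinase/aldolase
#'   (their flux caps at the enzyme floor force carbon through oxidative
#'   pentose phosphate cycling, which wastes too much CO2 to meet biomass
#'   demand), and enolase (the only route from 2-phosphoglycerate to PEP,
#'   with a catalytic constant too small to carry growth-level flux at the
#'   enzyme floor).  Real knockout panels likewise avoid essential genes.
#' @param max_retry Per-condition resampling cap before erroring.
#' @return A `synthetic_study`: `dataset` (noisy `omics_dataset`), `truth`
#'   (noise-free fluxes, concentrations, enzymes), `theta_true`, `split`
#'   (train/test condition ids) and `seed`.
#' @export
generate_study <- function(model, kin, n_train = 20, n_test = 5,
                           noise_cv = 0.05, flux_noise_cv = 0, seed = 1,
                           theta_true = load_fitted_parameters()$theta,
                           dilution_rates = c(0.1, 0.2, 0.4, 0.5, 0.7),
                           knockout_candidates = NULL,
                           max_retry = 8) {
  validate_parameters(kin, theta_true)
  if (is.null(knockout_candidates))
    knockout_candidates <- setdiff(names(kin$laws),
                                   c(model$glucose_uptake_rxn,
                                     "PDH", "PFK", "ALDO", "ENO"))
  n <- n_train + n_test
  with_seed(seed, {
    n_par <- min(length(dilution_rates), n)
    ko <- rep(NA_character_, n)
    D <- rep(0.2, n)
    D[seq_len(n_par)] <- dilution_rates[seq_len(n_par)]
    if (n > n_par)
      ko[(n_par + 1):n] <- rep(sample(knockout_candidates),
                               length.out = n - n_par)
    ids <- ifelse(is.na(ko), sprintf("WT_D%.2g", D), paste0("d", ko))
    ids <- make.unique(ids, sep = "_")

    krxn <- names(kin$laws)
    meas_rxns <- c(krxn, "EX_glc", "EX_o2", "EX_co2", model$biomass_rxn)
    meas_rxns <- intersect(meas_rxns, model$reactions$id)
    M <- setdiff(kin$metabolite_ids, "glc")
    V <- matrix(NA_real_, nrow(model$reactions), n,
                dimnames = list(model$reactions$id, ids))
    Cmat <- matrix(NA_real_, length(M) + 1, n,
                   dimnames = list(c(M, "glc"), ids))
    Emat <- matrix(NA_real_, length(krxn), n, dimnames = list(krxn, ids))

    for (l in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(max_retry)) {
        v <- sample_condition_fluxes(model, D[l], ko[l], theta_true, kin)
        if (is.null(v) || any(abs(v[krxn]) < 1e-4)) next
        c_tgt <- pmin(pmax(.base_conc * exp(stats::rnorm(length(.base_conc),
                                                         0, 0.15)),
                           0.0015), 9)
        names(c_tgt) <- names(.base_conc)
        st <- solve_condition_state(kin, v[krxn], theta_true, ko[l], c_tgt)
        if (is.null(st)) next
        resid <- abs(st$E * vapply(krxn, function(k)
          rate_factor(kin$laws[[k]], as.list(st$C), theta_true), 0) - v[krxn])
        if (max(resid / pmax(1, abs(v[krxn]))) > 1e-6) next
        V[, l] <- v
        Cmat[M, l] <- st$C[M]
        Cmat["glc", l] <- c_tgt["glc"]
        Emat[, l] <- st$E
        done <- TRUE
        break
      }
      if (!done)
        stop("could not generate a consistent condition for ", ids[l],
             " after ", max_retry, " attempts")
    }

    sigma <- sqrt(log(1 + noise_cv^2))
    noisy <- function(x) x * exp(stats::rnorm(length(x), 0, sigma))
    met_mean <- Cmat
    met_mean[] <- noisy(Cmat)
    met_sd <- Cmat * noise_cv
    met_mean["atp", ] <- NA; met_sd["atp", ] <- NA   # ATP unmeasured
    enz_mean <- Emat; enz_mean[] <- noisy(Emat)
    enz_sd <- Emat * noise_cv
    fl <- V[meas_rxns, , drop = FALSE]
    sigf <- sqrt(log(1 + flux_noise_cv^2))
    fl[] <- fl * exp(stats::rnorm(length(fl), 0, sigf))

    conditions <- data.frame(condition_id = ids, dilution_rate = D,
                             knockout = ko, stringsAsFactors = FALSE)
    ds <- omics_dataset(conditions, fl, met_mean, met_sd, enz_mean, enz_sd)
    test <- sort(sample(n, n_test))
    structure(list(
      dataset = ds,
      truth = list(v = V, conc = Cmat, enz = Emat),
      theta_true = theta_true,
      split = list(train = ids[-test], test = ids[test]),
      seed = seed, noise_cv = noise_cv, model = model, kin = kin),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic chemostat study:", length(x$split$train), "training +",
      length(x$split$test), "test conditions, noise CV", x$noise_cv,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' Flag a fraction of concentration measurements as missing
#'
#' Deterministically (under `seed`) marks an exact fraction of the currently
#' observed metabolite and enzyme cells as missing, emulating incomplete
#' metabolome/proteome coverage.
#'
#' @param study A `synthetic_study`.
#' @param missing_fraction Fraction in `[0, 1)` of observed cells to drop.
#' @param seed Integer seed.
#' @return The study with its dataset's missing flags updated.
#' @export
corrupt_measurements <- function(study, missing_fraction, seed = 1) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  if (missing_fraction == 0) return(study)
  ds <- study$dataset
  with_seed(seed, {
    cells <- rbind(
      cbind(which(!is.na(ds$met_mean), arr.ind = TRUE), table = 1),
      cbind(which(!is.na(ds$enz_mean), arr.ind = TRUE), table = 2))
    k <- round(missing_fraction * nrow(cells))
    drop <- cells[sample(nrow(cells), k), , drop = FALSE]
    for (i in seq_len(nrow(drop))) {
      if (drop[i, "table"] == 1) {
        ds$met_mean[drop[i, 1], drop[i, 2]] <- NA
        ds$met_sd[drop[i, 1], drop[i, 2]] <- NA
      } else {
        ds$enz_mean[drop[i, 1], drop[i, 2]] <- NA
        ds$enz_sd[drop[i, 1], drop[i, 2]] <- NA
      }
    }
    study$dataset <- ds
    study
  })
}
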