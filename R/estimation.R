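#' Weighted-sum-of-least-squares estimation of in vivo kinetic parameters
#'
#' The estimation problem treats per-condition metabolite concentrations,
#' enzyme concentrations and the kinetic parameter vector as decision
#' variables.  Fluxes through kinetic reactions are fixed to the adjusted
#' (steady-state-projected) measurements, and each enzyme concentration is
#' eliminated through the rate law, `e_kl = v_kl / f_k(c_l; theta)`, so the
#' rate-law constraint holds exactly at every iterate.  The adenylate energy
#' charge constraint is enforced exactly by reparameterizing the unmeasured
#' ATP concentration over the AEC-feasible interval.  Enzyme box bounds are
#' handled by a smooth quadratic penalty and audited at the solution.
#'
#' @name estimation
NULL

#' Construct a WSLS estimation problem
#'
#' @param kin A `kinetic_model`.
#' @param dataset An `omics_dataset` of training conditions.
#' @param weights Weight matrices from [compute_weights()] on `dataset`.
#' @param adjusted An `adjusted_fluxes` object (or reaction x condition
#'   matrix) covering every kinetic reaction and training condition.
#' @param aec_min Minimum adenylate energy charge (default 0.8).
#' @param conc_bounds,enzyme_bounds Global concentration bounds, mM and
#'   mg protein/gDCW (defaults 0.001 to 10).
#' @return A `wsls_problem`.
#' @export
wsls_problem <- function(kin, dataset, weights, adjusted,
                         aec_min = 0.8, conc_bounds = c(0.001, 10),
                         enzyme_bounds = c(0.001, 10)) {
  V <- if (inherits(adjusted, "adjusted_fluxes")) adjusted$v else adjusted
  ids <- dataset$conditions$condition_id
  krxn <- names(kin$laws)
  if (!all(krxn %in% rownames(V)))
    stop("adjusted fluxes missing kinetic reaction(s): ",
         paste(setdiff(krxn, rownames(V)), collapse = ", "))
  if (!all(ids %in% colnames(V)))
    stop("adjusted fluxes missing condition(s)")
  if (aec_min <= 0) stop("aec_min must be positive")
  aec_max <- (conc_bounds[2] + 0.5 * conc_bounds[1]) /
    (conc_bounds[2] + 2 * conc_bounds[1])
  if (aec_min > aec_max)
    stop("infeasible problem: the adenylate energy charge cannot reach ",
         aec_min, " within the concentration bounds (maximum attainable ",
         signif(aec_max, 6), ")")
  structure(list(kin = kin, dataset = dataset, weights = weights,
                 vK = V[krxn, ids, drop = FALSE],
                 aec_min = aec_min, conc_bounds = conc_bounds,
                 enzyme_bounds = enzyme_bounds),
            class = "wsls_problem")
}

# ---------------------------------------------------------------------------
# objective machinery (shared with the synthetic-study generator)
#
# Variable vector: [log theta (P, optional) | vec(log C_free) (Mf x L) | a (L)
#                   | vec(log E) (K x L, only when e_free)]
# where C_free excludes ATP; ATP is (1-a)*lo + a*cmax with
# lo = max(cmin, ka*adp + kb*amp), the AEC-feasible lower end.
#
# Two modes handle the pole of e = v/f at f = 0:
#  * e_free = TRUE ("relaxation phase"): enzymes are box-bounded variables
#    and the rate-law equality enters as a smooth penalty
#    lambda * (e f - v)^2 / max(1, v)^2, so rate factors can cross zero and
#    settle on the sign of the flux;
#  * e_free = FALSE ("exact phase"): e is eliminated as v/f, making the
#    rate-law constraint hold exactly; used to polish from a warm start
#    whose rate-factor signs already match the fluxes.

make_wsls_objective <- function(kin, vK, cexp, W_c, eexp, W_e,
                                aec_min, conc_bounds, enzyme_bounds,
                                theta_fixed = NULL, e_free = FALSE,
                                lambda = 1e6,
                                kappa_e = 1e6, kappa_aec = 1e8) {
  laws <- kin$laws
  krxn <- names(laws)
  M <- setdiff(kin$metabolite_ids, "glc")
  Mf <- setdiff(M, "atp")
  L <- ncol(vK)
  P <- nrow(kin$specs)
  pnames <- kin$specs$name
  theta_free <- is.null(theta_fixed)
  if (!theta_free) {
    if (is.null(names(theta_fixed)) ||
        !all(kin$specs$name %in% names(theta_fixed)))
      stop("theta_fixed must be named with every registry parameter")
    theta_fixed <- theta_fixed[kin$specs$name]
  }
  cmin <- conc_bounds[1]; cmax <- conc_bounds[2]
  emin <- enzyme_bounds[1]; emax <- enzyme_bounds[2]
  ka <- (aec_min - 0.5) / (1 - aec_min)
  kb <- aec_min / (1 - aec_min)
  iadp <- match("adp", Mf); iamp <- match("amp", Mf)
  np <- if (theta_free) P else 0
  nC <- length(Mf) * L
  nK <- length(krxn)
  nE <- if (e_free) nK * L else 0
  wv <- vK; wv[] <- 1 / pmax(1, abs(vK))^2   # pmax would drop the dim

  # W_c/cexp rows aligned to M (atp row present, weight 0 if unmeasured)
  stopifnot(identical(rownames(cexp), M), identical(rownames(W_c), M))
  stopifnot(identical(rownames(eexp), krxn), identical(rownames(W_e), krxn))
  cexp0 <- cexp; cexp0[is.na(cexp0)] <- 0
  eexp0 <- eexp; eexp0[is.na(eexp0)] <- 0

  # per-law index caches
  lawidx <- lapply(laws, function(l) {
    list(mets = match(l$required_metabolites, M),
         par = match(l$parameters, pnames),
         nm = length(l$required_metabolites))
  })

  eval_all <- function(x) {
    theta <- if (theta_free) exp(x[seq_len(P)]) else theta_fixed
    names(theta) <- pnames
    Cf <- matrix(exp(x[np + seq_len(nC)]), length(Mf), L,
                 dimnames = list(Mf, NULL))
    a <- x[np + nC + seq_len(L)]
    Efree <- if (e_free)
      matrix(exp(x[np + nC + L + seq_len(nE)]), nK, L,
             dimnames = list(krxn, NULL)) else NULL
    adp <- Cf[iadp, ]; amp <- Cf[iamp, ]
    r <- ka * adp + kb * amp
    lo <- pmax(cmin, r)
    over <- pmax(lo - cmax, 0)                   # AEC box conflict
    lo2 <- pmin(lo, cmax)
    atp <- (1 - a) * lo2 + a * cmax
    C <- matrix(0, length(M), L, dimnames = list(M, NULL))
    C[Mf, ] <- Cf
    C["atp", ] <- atp

    obj <- kappa_aec * sum(over^2)
    gC <- matrix(0, length(M), L)                # d obj / d C (linear scale)
    gTheta <- numeric(P)
    E <- matrix(NA_real_, length(krxn), L, dimnames = list(krxn, NULL))

    # concentration residuals
    dc <- C - cexp0
    obj <- obj + sum(W_c * dc * dc)
    gC <- gC + 2 * W_c * dc

    # AEC conflict gradient (through lo where lo > cmax)
    gadp_extra <- numeric(L); gamp_extra <- numeric(L)
    sel <- over > 0 & r > cmin
    if (any(sel)) {
      gadp_extra[sel] <- gadp_extra[sel] + 2 * kappa_aec * over[sel] * ka
      gamp_extra[sel] <- gamp_extra[sel] + 2 * kappa_aec * over[sel] * kb
    }

    gE <- if (e_free) matrix(0, nK, L) else NULL
    for (k in seq_along(krxn)) {
      li <- lawidx[[k]]
      conc_l <- lapply(li$mets, function(i) C[i, ])
      names(conc_l) <- M[li$mets]
      rg <- rate_factor_grad(laws[[k]], conc_l, theta)
      f <- rg$f
      v <- vK[k, ]
      we <- W_e[k, ]
      G <- rg$grad
      if (L == 1) G <- matrix(G, nrow = 1)
      if (e_free) {
        e <- Efree[k, ]
        E[k, ] <- e
        res <- e - eexp0[k, ]
        r2 <- e * f - v
        obj <- obj + sum(we * res * res) + lambda * sum(wv[k, ] * r2 * r2)
        gE[k, ] <- 2 * we * res + 2 * lambda * wv[k, ] * r2 * f
        gmul <- 2 * lambda * wv[k, ] * r2 * e   # d obj / d f
      } else {
        fs <- ifelse(abs(f) < 1e-12, ifelse(f < 0, -1e-12, 1e-12), f)
        e <- v / fs
        E[k, ] <- e
        de_df <- -v / (fs * fs)
        res <- e - eexp0[k, ]
        obj <- obj + sum(we * res * res)
        # enzyme box penalty, scale-invariant in the bound
        lowv <- pmin(e - emin, 0) / emin
        highv <- pmax(e - emax, 0) / emax
        obj <- obj + kappa_e * sum(lowv^2 + highv^2)
        gmul <- (2 * we * res +
                   2 * kappa_e * (lowv / emin + highv / emax)) * de_df
      }
      for (j in seq_len(li$nm))
        gC[li$mets[j], ] <- gC[li$mets[j], ] + gmul * G[, j]
      if (theta_free)
        for (j in seq_along(li$par))
          gTheta[li$par[j]] <- gTheta[li$par[j]] +
            sum(gmul * G[, li$nm + j])
    }

    # chain rule into the variable vector
    gatp <- gC["atp", ]
    ga <- gatp * (cmax - lo2)
    dlo <- gatp * (1 - a) * (r > cmin & r < cmax)
    gCf <- gC[Mf, , drop = FALSE]
    gCf[iadp, ] <- gCf[iadp, ] + dlo * ka + gadp_extra
    gCf[iamp, ] <- gCf[iamp, ] + dlo * kb + gamp_extra
    glogC <- gCf * Cf
    grad <- c(if (theta_free) gTheta * theta else NULL,
              as.numeric(glogC), ga,
              if (e_free) as.numeric(gE * Efree) else NULL)
    list(obj = obj, grad = grad, theta = theta, C = C, E = E)
  }

  cache <- new.env(parent = emptyenv())
  compute <- function(x) {
    key <- x
    if (!is.null(cache$x) && identical(cache$x, key)) return(cache$val)
    val <- eval_all(x)
    cache$x <- key; cache$val <- val
    val
  }
  lower <- c(if (theta_free) log(kin$specs$global_lb) else NULL,
             rep(log(cmin), nC), rep(0, L),
             if (e_free) rep(log(emin), nE) else NULL)
  upper <- c(if (theta_free) log(kin$specs$global_ub) else NULL,
             rep(log(cmax), nC), rep(1, L),
             if (e_free) rep(log(emax), nE) else NULL)
  list(fn = function(x) compute(x)$obj,
       gr = function(x) compute(x)$grad,
       detail = compute, lower = lower, upper = upper,
       M = M, Mf = Mf, L = L, np = np, nC = nC, nE = nE, krxn = krxn)
}

# Residual/Jacobian system for the exact phase (e = v/f), consumed by the
# damped Gauss-Newton solver lm_box().  Residual blocks: weighted
# concentration residuals, weighted enzyme residuals, scale-invariant
# enzyme-box hinges, and the AEC box-conflict hinge.  Same variable layout
# as make_wsls_objective with e_free = FALSE.
make_wsls_lm <- function(kin, vK, cexp, W_c, eexp, W_e,
                         aec_min, conc_bounds, enzyme_bounds,
                         theta_fixed = NULL,
                         kappa_e = 1e6, kappa_aec = 1e8) {
  laws <- kin$laws
  krxn <- names(laws)
  M <- setdiff(kin$metabolite_ids, "glc")
  Mf <- setdiff(M, "atp")
  L <- ncol(vK)
  P <- nrow(kin$specs)
  pnames <- kin$specs$name
  theta_free <- is.null(theta_fixed)
  if (!theta_free) theta_fixed <- theta_fixed[pnames]
  cmin <- conc_bounds[1]; cmax <- conc_bounds[2]
  emin <- enzyme_bounds[1]; emax <- enzyme_bounds[2]
  ka <- (aec_min - 0.5) / (1 - aec_min)
  kb <- aec_min / (1 - aec_min)
  iadp <- match("adp", Mf); iamp <- match("amp", Mf)
  iatp <- match("atp", M)
  np <- if (theta_free) P else 0
  nC <- length(Mf) * L
  nv <- np + nC + L
  cexp0 <- cexp; cexp0[is.na(cexp0)] <- 0
  eexp0 <- eexp; eexp0[is.na(eexp0)] <- 0
  sWc <- sqrt(W_c); sWe <- sqrt(W_e)
  cm_idx <- which(W_c > 0, arr.ind = TRUE)       # measured conc cells
  nK <- length(krxn)
  lawidx <- lapply(laws, function(l)
    list(mets = match(l$required_metabolites, M),
         par = match(l$parameters, pnames),
         nm = length(l$required_metabolites)))
  n_res <- nrow(cm_idx) + 3 * nK * L + L

  forward <- function(x) {
    theta <- if (theta_free) exp(x[seq_len(P)]) else theta_fixed
    names(theta) <- pnames
    Cf <- matrix(exp(x[np + seq_len(nC)]), length(Mf), L,
                 dimnames = list(Mf, NULL))
    a <- x[np + nC + seq_len(L)]
    adp <- Cf[iadp, ]; amp <- Cf[iamp, ]
    r <- ka * adp + kb * amp
    lo <- pmax(cmin, r)
    over <- pmax(lo - cmax, 0)
    lo2 <- pmin(lo, cmax)
    atp <- (1 - a) * lo2 + a * cmax
    C <- matrix(0, length(M), L, dimnames = list(M, NULL))
    C[Mf, ] <- Cf
    C["atp", ] <- atp
    list(theta = theta, Cf = Cf, a = a, C = C, lo = lo, lo2 = lo2,
         over = over, r = r)
  }

  resid <- function(x) {
    fw <- forward(x)
    out <- numeric(n_res)
    out[seq_len(nrow(cm_idx))] <- sWc[cm_idx] * (fw$C[cm_idx] - cexp0[cm_idx])
    pos <- nrow(cm_idx)
    for (k in seq_len(nK)) {
      li <- lawidx[[k]]
      conc_l <- lapply(li$mets, function(i) fw$C[i, ])
      names(conc_l) <- M[li$mets]
      f <- rate_factor(laws[[k]], conc_l, fw$theta)
      f <- ifelse(abs(f) < 1e-12, ifelse(f < 0, -1e-12, 1e-12), f)
      e <- vK[k, ] / f
      out[pos + seq_len(L)] <- sWe[k, ] * (e - eexp0[k, ])
      out[pos + L + seq_len(L)] <- sqrt(kappa_e) * pmin(e - emin, 0) / emin
      out[pos + 2 * L + seq_len(L)] <- sqrt(kappa_e) * pmax(e - emax, 0) / emax
      pos <- pos + 3 * L
    }
    out[pos + seq_len(L)] <- sqrt(kappa_aec) * fw$over
    out
  }

  # Jacobian assembled as a sparse matrix: each residual row touches at
  # most a handful of variables, which makes the Gauss-Newton normal
  # equations essentially free compared to a dense factorization.
  jac <- function(x) {
    fw <- forward(x)
    ti <- list(); tj <- list(); tx <- list()
    put <- function(i, j, v) {
      n <- length(ti) + 1L
      ti[[n]] <<- i; tj[[n]] <<- j; tx[[n]] <<- v
    }
    # d atp / d (a, log adp, log amp)
    datp_da <- cmax - fw$lo2
    act <- (fw$r > cmin & fw$r < cmax)
    datp_dadp <- (1 - fw$a) * ka * act * fw$Cf[iadp, ]   # wrt log adp
    datp_damp <- (1 - fw$a) * kb * act * fw$Cf[iamp, ]
    lseq <- seq_len(L)
    col_logC <- function(i, l) np + (l - 1) * length(Mf) + i
    col_a <- np + nC + lseq
    # concentration residual rows
    if (nrow(cm_idx)) {
      ii <- cm_idx[, 1]; ll <- cm_idx[, 2]
      w <- sWc[cm_idx]
      q <- seq_len(nrow(cm_idx))
      at <- ii == iatp
      if (any(at)) {
        put(q[at], col_a[ll[at]], w[at] * datp_da[ll[at]])
        put(q[at], col_logC(iadp, ll[at]), w[at] * datp_dadp[ll[at]])
        put(q[at], col_logC(iamp, ll[at]), w[at] * datp_damp[ll[at]])
      }
      if (any(!at)) {
        ifree <- match(M[ii[!at]], Mf)
        put(q[!at], col_logC(ifree, ll[!at]),
            w[!at] * fw$Cf[cbind(ifree, ll[!at])])
      }
    }
    pos <- nrow(cm_idx)
    for (k in seq_len(nK)) {
      li <- lawidx[[k]]
      conc_l <- lapply(li$mets, function(i) fw$C[i, ])
      names(conc_l) <- M[li$mets]
      rg <- rate_factor_grad(laws[[k]], conc_l, fw$theta)
      f <- rg$f
      f <- ifelse(abs(f) < 1e-12, ifelse(f < 0, -1e-12, 1e-12), f)
      G <- rg$grad
      if (L == 1) G <- matrix(G, nrow = 1)
      e <- vK[k, ] / f
      de_df <- -vK[k, ] / (f * f)
      wrow <- rbind(sWe[k, ],
                    sqrt(kappa_e) * (e - emin < 0) / emin,
                    sqrt(kappa_e) * (e - emax > 0) / emax)
      for (b in 1:3) {
        rows <- pos + (b - 1) * L + lseq
        coef <- wrow[b, ] * de_df
        if (!any(coef != 0)) next
        for (j in seq_len(li$nm)) {
          m_global <- li$mets[j]
          dfd <- coef * G[, j]
          if (m_global == iatp) {
            put(rows, col_a, dfd * datp_da)
            put(rows, col_logC(iadp, lseq), dfd * datp_dadp)
            put(rows, col_logC(iamp, lseq), dfd * datp_damp)
          } else {
            ii <- match(M[m_global], Mf)
            put(rows, col_logC(ii, lseq), dfd * fw$Cf[ii, ])
          }
        }
        if (theta_free)
          for (j in seq_along(li$par))
            put(rows, rep(li$par[j], L),
                coef * G[, li$nm + j] * fw$theta[li$par[j]])
      }
      pos <- pos + 3 * L
    }
    # AEC conflict rows
    sel <- which(fw$over > 0)
    if (length(sel)) {
      put(pos + sel, col_logC(iadp, sel), sqrt(kappa_aec) * ka * fw$Cf[iadp, sel])
      put(pos + sel, col_logC(iamp, sel), sqrt(kappa_aec) * kb * fw$Cf[iamp, sel])
    }
    Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                         dims = c(n_res, nv))
  }
  list(resid = resid, jac = jac, n_res = n_res, nv = nv)
}

# Box-constrained damped Gauss-Newton (Levenberg-Marquardt style) on a
# residual system.  The normal equations are formed with BLAS crossprod and
# solved by Cholesky, which is an order of magnitude cheaper than a dense
# QR of the Jacobian at this problem shape (~1500 residuals x ~500
# variables).  Steps are projected onto the box; coordinates with
# lower == upper are masked out (used to pin a parameter during profiling).
lm_box <- function(resid, jac, x0, lower, upper, maxiter = 150,
                   ftol = 1e-12) {
  x <- pmin(pmax(x0, lower), upper)
  free <- which(upper > lower)
  r <- resid(x)
  f <- sum(r * r)
  if (!is.finite(f)) return(list(par = x, value = f, converged = FALSE))
  lambda <- 1e-3
  stalls <- 0L
  for (it in seq_len(maxiter)) {
    J <- jac(x)[, free, drop = FALSE]
    g <- as.numeric(Matrix::crossprod(J, r))
    H <- as.matrix(Matrix::crossprod(J))
    d <- pmax(diag(H), 1e-10)
    improved <- FALSE
    for (inner in 1:12) {
      M <- H
      diag(M) <- diag(H) + lambda * d
      step <- tryCatch({
        R <- chol(M)
        -backsolve(R, backsolve(R, g, transpose = TRUE))
      }, error = function(e) NULL)
      if (!is.null(step)) {
        xn <- x
        xn[free] <- pmin(pmax(x[free] + step, lower[free]), upper[free])
        rn <- resid(xn)
        fn <- sum(rn * rn)
        if (is.finite(fn) && fn < f) {
          if (f - fn < ftol * max(1, f)) stalls <- stalls + 1L
          else stalls <- 0L
          x <- xn; r <- rn; f <- fn
          lambda <- max(lambda * 0.35, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e14) break
    }
    if (!improved || stalls >= 2L) break
  }
  list(par = x, value = f, converged = TRUE)
}

# pure WSLS value (no penalties) at a solution
wsls_value <- function(obFull, x, cexp, W_c, eexp, W_e) {
  d <- obFull$detail(x)
  cexp0 <- cexp; cexp0[is.na(cexp0)] <- 0
  eexp0 <- eexp; eexp0[is.na(eexp0)] <- 0
  sum(W_c * (d$C - cexp0)^2) + sum(W_e * (d$E - eexp0)^2)
}

# assemble experiment matrices aligned to the objective layout
problem_matrices <- function(problem) {
  kin <- problem$kin; ds <- problem$dataset
  M <- setdiff(kin$metabolite_ids, "glc")
  krxn <- names(kin$laws)
  L <- nrow(ds$conditions)
  cexp <- matrix(NA_real_, length(M), L, dimnames = list(M, ds$conditions$condition_id))
  W_c <- matrix(0, length(M), L, dimnames = dimnames(cexp))
  common <- intersect(M, rownames(ds$met_mean))
  cexp[common, ] <- ds$met_mean[common, ]
  W_c[common, ] <- problem$weights$W_c[common, ]
  eexp <- matrix(NA_real_, length(krxn), L, dimnames = list(krxn, colnames(cexp)))
  W_e <- matrix(0, length(krxn), L, dimnames = dimnames(eexp))
  comme <- intersect(krxn, rownames(ds$enz_mean))
  eexp[comme, ] <- ds$enz_mean[comme, ]
  W_e[comme, ] <- problem$weights$W_e[comme, ]
  list(cexp = cexp, W_c = W_c, eexp = eexp, W_e = W_e)
}

# per-law least-squares pre-fit of theta from the raw measurements: with
# measured enzyme and metabolite concentrations and the adjusted fluxes,
# each law's 1-3 parameters are fit independently (unmeasured ATP is proxied
# by the low end of the AEC-feasible interval).  This produces the
# data-informed starting point for the joint optimization.
init_theta_from_data <- function(problem, mats) {
  kin <- problem$kin
  sp <- kin$specs
  theta0 <- stats::setNames(sqrt(sp$global_lb * sp$global_ub), sp$name)
  Cm <- mats$cexp
  if (all(c("adp", "amp") %in% rownames(Cm))) {
    atp_proxy <- pmax(problem$conc_bounds[1],
                      (problem$aec_min - 0.5) / (1 - problem$aec_min) *
                        Cm["adp", ] + problem$aec_min /
                        (1 - problem$aec_min) * Cm["amp", ]) * 1.15
    Cm["atp", ] <- pmin(atp_proxy, problem$conc_bounds[2])
  }
  for (k in names(kin$laws)) {
    law <- kin$laws[[k]]
    idx <- match(law$parameters, sp$name)
    lbk <- log(sp$global_lb[idx]); ubk <- log(sp$global_ub[idx])
    use <- which(!is.na(mats$eexp[k, ]) &
                   colSums(is.na(Cm[law$required_metabolites, , drop = FALSE])) == 0)
    if (!length(use)) next
    conc <- lapply(law$required_metabolites, function(m) Cm[m, use])
    names(conc) <- law$required_metabolites
    e <- mats$eexp[k, use]; v <- problem$vK[k, use]
    wv <- 1 / pmax(1, abs(v))^2
    hfun <- function(lt) {
      th <- stats::setNames(exp(lt), law$parameters)
      f <- rate_factor(law, conc, th)
      sum(wv * (e * f - v)^2)
    }
    starts <- list((lbk + ubk) / 2)
    kq <- match(param_name(k, "Keq"), law$parameters)
    if (!is.na(kq)) {
      th0 <- stats::setNames(exp((lbk + ubk) / 2), law$parameters)
      qmed <- law_keq_median_q(law, conc, lbk[kq], ubk[kq], th0)
      if (!is.null(qmed)) {
        s2 <- (lbk + ubk) / 2; s2[kq] <- log(qmed)
        starts <- c(starts, list(s2))
      }
    }
    for (s in 1:3) starts <- c(starts, list(stats::runif(length(idx), lbk, ubk)))
    best <- NULL
    for (lt0 in starts) {
      r <- tryCatch(stats::optim(lt0, hfun, method = "L-BFGS-B",
                                 lower = lbk, upper = ubk,
                                 control = list(maxit = 300)),
                    error = function(e) NULL)
      if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
    }
    if (!is.null(best)) theta0[law$parameters] <- exp(best$par)
  }
  theta0
}

# starting point: concentrations at measurements (fallback 0.1 mM),
# AEC variable mildly above the constraint, parameters around the
# data-informed pre-fit (jittered), with occasional log-uniform exploration
wsls_start <- function(problem, mats, theta0, start_index = 1) {
  kin <- problem$kin
  M <- setdiff(kin$metabolite_ids, "glc")
  Mf <- setdiff(M, "atp")
  L <- ncol(mats$cexp)
  jitter_sd <- if (start_index == 1) 0 else 0.2
  th <- if (start_index == 1) theta0
  else if (start_index %% 5 == 0)
    exp(stats::runif(nrow(kin$specs), log(kin$specs$global_lb),
                     log(kin$specs$global_ub)))
  else theta0 * exp(stats::rnorm(length(theta0), 0, 0.5))
  th <- pmin(pmax(th, kin$specs$global_lb), kin$specs$global_ub)
  C0 <- mats$cexp[Mf, , drop = FALSE]
  C0[is.na(C0)] <- 0.1
  C0 <- pmin(pmax(C0 * exp(stats::rnorm(length(C0), 0, jitter_sd)),
                  problem$conc_bounds[1]), problem$conc_bounds[2])
  c(log(th), log(as.numeric(C0)), rep(0.25, L))
}

# median mass-action ratio of a reversible law: per condition, the Keq at
# which the rate factor vanishes (f is monotone in Keq).  For reactions
# operating near equilibrium this is an excellent Keq estimate and a basin
# selector that pure descent cannot find.
law_keq_median_q <- function(law, conc, lb_log, ub_log, theta0) {
  if (!"Keq" %in% law$local_params) return(NULL)
  kq <- param_name(law$reaction_id, "Keq")
  L <- length(conc[[1]])
  qs <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    cl <- lapply(conc, `[`, l)
    fk <- function(lk) {
      th <- theta0; th[[kq]] <- exp(lk)
      rate_factor(law, cl, th)
    }
    r <- tryCatch(stats::uniroot(fk, c(lb_log, ub_log), tol = 1e-10),
                  error = function(e) NULL)
    if (!is.null(r)) qs[l] <- r$root
  }
  if (all(is.na(qs))) return(NULL)
  exp(stats::median(qs, na.rm = TRUE))
}

# re-fit each law's parameters against the current concentration estimates
# (tiny independent least-squares problems with their own restarts); jumps
# out of joint local basins where a shared parameter got stuck on the wrong
# side of its per-condition mass-action ratios
refit_laws <- function(x, ob, problem, mats) {
  kin <- problem$kin
  emin <- problem$enzyme_bounds[1]; emax <- problem$enzyme_bounds[2]
  d <- ob$detail(x)
  for (k in names(kin$laws)) {
    law <- kin$laws[[k]]
    idx <- match(law$parameters, kin$specs$name)
    conc <- lapply(law$required_metabolites, function(m) d$C[m, ])
    names(conc) <- law$required_metabolites
    v <- problem$vK[k, ]; we <- mats$W_e[k, ]
    ee <- mats$eexp[k, ]; ee[is.na(ee)] <- 0
    gfun <- function(lt) {
      th <- stats::setNames(exp(lt), law$parameters)
      f <- rate_factor(law, conc, th)
      f <- ifelse(abs(f) < 1e-12, ifelse(f < 0, -1e-12, 1e-12), f)
      e <- v / f
      sum(we * (e - ee)^2) +
        1e6 * sum((pmin(e - emin, 0) / emin)^2 +
                    (pmax(e - emax, 0) / emax)^2)
    }
    starts <- list(x[idx])
    kq <- match(param_name(k, "Keq"), kin$specs$name[idx])
    if (!is.na(kq)) {
      th0 <- stats::setNames(exp(x[idx]), law$parameters)
      qmed <- law_keq_median_q(law, conc, ob$lower[idx][kq],
                               ob$upper[idx][kq], th0)
      if (!is.null(qmed)) {
        s2 <- x[idx]; s2[kq] <- log(qmed)
        starts <- c(starts, list(s2))
      }
    }
    for (s in 1:3)
      starts <- c(starts, list(stats::runif(length(idx), ob$lower[idx],
                                            ob$upper[idx])))
    best <- list(par = x[idx], value = gfun(x[idx]))
    for (lt0 in starts) {
      r <- tryCatch(stats::optim(lt0, gfun, method = "L-BFGS-B",
                                 lower = ob$lower[idx],
                                 upper = ob$upper[idx],
                                 control = list(maxit = 300)),
                    error = function(e) NULL)
      if (!is.null(r) && r$value < best$value) best <- r
    }
    x[idx] <- best$par
  }
  x
}

#' Solve the WSLS parameter-estimation problem
#'
#' Multi-start bound-constrained quasi-Newton optimization (L-BFGS-B with
#' analytic gradients) over kinetic parameters (log scale) and per-condition
#' concentrations.  The feasible space is non-convex, so several starting
#' points are explored and the feasible solution with the lowest objective
#' is returned.
#'
#' @param problem A `wsls_problem`.
#' @param n_starts Number of starting points (the first start initializes
#'   concentrations at their measured values).
#' @param seed Integer seed making the whole run reproducible.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param theta_fixed Optional named parameter vector: when supplied, only
#'   concentrations are optimized (used for diagnostics and by the study
#'   generator).
#' @return A `wsls_fit`: `theta`, `c_hat` (metabolite x condition, including
#'   the reconstructed ATP), `e_hat`, `wsls`, `aec`, per-start objective
#'   values and convergence metadata.
#' @export
solve_wsls <- function(problem, n_starts = 24, seed = 1, maxit = 4000,
                       theta_fixed = NULL) {
  stopifnot(inherits(problem, "wsls_problem"), n_starts >= 1)
  mats <- problem_matrices(problem)
  obA <- make_wsls_objective(problem$kin, problem$vK, mats$cexp, mats$W_c,
                             mats$eexp, mats$W_e, problem$aec_min,
                             problem$conc_bounds, problem$enzyme_bounds,
                             theta_fixed = theta_fixed, e_free = TRUE)
  ob <- make_wsls_objective(problem$kin, problem$vK, mats$cexp, mats$W_c,
                            mats$eexp, mats$W_e, problem$aec_min,
                            problem$conc_bounds, problem$enzyme_bounds,
                            theta_fixed = theta_fixed)
  lmsys <- make_wsls_lm(problem$kin, problem$vK, mats$cexp, mats$W_c,
                        mats$eexp, mats$W_e, problem$aec_min,
                        problem$conc_bounds, problem$enzyme_bounds,
                        theta_fixed = theta_fixed)
  E0 <- mats$eexp
  E0[is.na(E0)] <- 0.1
  E0 <- pmin(pmax(E0, problem$enzyme_bounds[1]), problem$enzyme_bounds[2])
  nB <- length(ob$lower)
  best <- NULL; objs <- numeric(0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  theta0 <- if (is.null(theta_fixed))
    init_theta_from_data(problem, mats)
  else theta_fixed[problem$kin$specs$name]
  for (s in seq_len(n_starts)) {
    set.seed(seed + 7919L * (s - 1L))
    x0 <- wsls_start(problem, mats, theta0 = theta0, start_index = s)
    if (!is.null(theta_fixed)) x0 <- x0[-seq_len(nrow(problem$kin$specs))]
    x0A <- c(x0, log(as.numeric(E0)))
    # relaxation phase: enzymes free, rate law as smooth penalty (lets rate
    # factors cross zero so their signs settle on the fluxes)
    fitA <- tryCatch(
      stats::optim(x0A, fn = obA$fn, gr = obA$gr, method = "L-BFGS-B",
                   lower = obA$lower, upper = obA$upper,
                   control = list(maxit = min(maxit, 600), factr = 1e4)),
      error = function(e) NULL)
    # exact phase: enzymes eliminated through the rate laws; warm up both
    # the relaxation solution and the raw start, keep the better
    starts_b <- list(x0)
    if (!is.null(fitA)) starts_b <- c(list(fitA$par[seq_len(nB)]), starts_b)
    fit <- NULL
    for (xB in starts_b) {
      # alternate bound-constrained quasi-Newton sweeps with Gauss-Newton
      # polish; the second-order step crosses the ill-conditioned valleys
      # that first-order steps crawl along, and the quasi-Newton sweep
      # renegotiates active bounds in between
      x <- xB
      val <- Inf
      for (cycle in 1:6) {
        fb <- tryCatch(
          stats::optim(x, fn = ob$fn, gr = ob$gr, method = "L-BFGS-B",
                       lower = ob$lower, upper = ob$upper,
                       control = list(maxit = min(maxit, 600), factr = 1e4)),
          error = function(e) NULL)
        if (!is.null(fb) && is.finite(fb$value) && fb$value < val) {
          x <- fb$par; val <- fb$value
        }
        lmf <- tryCatch(
          lm_box(lmsys$resid, lmsys$jac, x, ob$lower, ob$upper,
                 maxiter = 250, ftol = 1e-14),
          error = function(e) NULL)
        improved <- FALSE
        if (!is.null(lmf)) {
          vlm <- ob$fn(lmf$par)
          if (is.finite(vlm) && vlm < val * (1 - 1e-8) - 1e-12) {
            x <- lmf$par; val <- vlm; improved <- TRUE
          }
        }
        # per-law parameter refits against the current concentration
        # estimates escape joint basins the smooth steps cannot leave
        if (is.null(theta_fixed)) {
          xr <- tryCatch(refit_laws(x, ob, problem, mats),
                         error = function(e) NULL)
          if (!is.null(xr)) {
            vr <- ob$fn(xr)
            if (is.finite(vr) && vr < val * (1 - 1e-8)) {
              x <- xr; val <- vr; improved <- TRUE
            } else {
              # even when not an immediate improvement, give the polished
              # refit one chance to relocate the basin
              lmr <- tryCatch(
                lm_box(lmsys$resid, lmsys$jac, xr, ob$lower, ob$upper,
                       maxiter = 250, ftol = 1e-14),
                error = function(e) NULL)
              if (!is.null(lmr)) {
                vlr <- ob$fn(lmr$par)
                if (is.finite(vlr) && vlr < val * (1 - 1e-8)) {
                  x <- lmr$par; val <- vlr; improved <- TRUE
                }
              }
            }
          }
        }
        if (!improved && cycle > 1) break
      }
      if (!is.finite(val)) next
      if (is.null(fit) || val < fit$value)
        fit <- list(par = x, value = val)
    }
    if (is.null(fit)) next
    objs <- c(objs, fit$value)
    if (is.null(best) || fit$value < best$value) {
      best <- fit; best$start <- s
    }
  }
  if (is.null(best))
    stop("no feasible start found: all ", n_starts,
         " optimizations failed (check flux signs and bounds)")
  conv <- sum(objs <= best$value * (1 + 1e-4) + 1e-10)
  d <- ob$detail(best$par)
  wsls <- wsls_value(ob, best$par, mats$cexp, mats$W_c, mats$eexp, mats$W_e)
  # audit the penalty-handled constraints
  eviol <- max(0, problem$enzyme_bounds[1] - min(d$E),
               max(d$E) - problem$enzyme_bounds[2])
  aec <- adenylate_energy_charge(d$C["atp", ], d$C["adp", ], d$C["amp", ])
  ids <- problem$dataset$conditions$condition_id
  colnames(d$C) <- colnames(d$E) <- ids
  c_hat <- d$C
  if ("glc" %in% rownames(problem$dataset$met_mean))
    c_hat <- rbind(c_hat, glc = problem$dataset$met_mean["glc", ])
  structure(list(theta = d$theta, c_hat = c_hat, e_hat = d$E,
                 wsls = wsls, objective = best$value,
                 aec = stats::setNames(aec, ids),
                 enzyme_bound_violation = eviol,
                 n_starts = n_starts, n_converged = conv,
                 best_start = best$start, start_objectives = objs,
                 par = best$par, problem = problem, theta_free = is.null(theta_fixed)),
            class = "wsls_fit")
}

#' @export
print.wsls_fit <- function(x, ...) {
  cat("WSLS fit: objective", format(x$wsls, digits = 6), "over",
      ncol(x$e_hat), "conditions;", x$n_converged, "of", x$n_starts,
      "starts converged (best: start", x$best_start, ")\n")
  invisible(x)
}

# quadratic extrapolation of a one-parameter WSLS profile to the chi-square
# threshold; fun(log_value) must return the re-optimized WSLS.  Each side is
# probed at delta and 3*delta and the wider (more conservative) quadratic
# extrapolation is kept, so profiles that steepen locally but flatten
# further out (compensable parameter directions) are not cut short.
profile_param_ci <- function(fun, center_log, wsls_opt, delta, q,
                             lb_log, ub_log, flat_tol = 1e-9) {
  one_side <- function(sgn) {
    bound <- if (sgn > 0) ub_log else lb_log
    room <- abs(bound - center_log)
    if (room < 1e-12) return(list(limit = bound, flag = "at_bound"))
    d1 <- min(delta, room)
    dW1 <- fun(center_log + sgn * d1) - wsls_opt
    if (!is.finite(dW1) || dW1 <= flat_tol * max(1, wsls_opt))
      return(list(limit = bound, flag = "unbounded"))
    hw <- d1 * sqrt(q / dW1)
    if (hw < room && 3 * delta < room) {
      # second probe further out guards against profiles that flatten
      d2 <- 3 * delta
      dW2 <- fun(center_log + sgn * d2) - wsls_opt
      if (is.finite(dW2)) {
        if (dW2 <= flat_tol * max(1, wsls_opt)) hw <- Inf
        else hw <- max(hw, d2 * sqrt(q / dW2))
      }
    }
    if (hw >= room) list(limit = bound, flag = "truncated")
    else list(limit = center_log + sgn * hw, flag = "ok")
  }
  lo <- one_side(-1); hi <- one_side(1)
  list(lower = exp(lo$limit), upper = exp(hi$limit),
       flag_lower = lo$flag, flag_upper = hi$flag)
}

#' Profile confidence intervals for fitted kinetic parameters
#'
#' Each parameter is perturbed one at a time on the log scale while all other
#' variables (remaining parameters and every per-condition concentration) are
#' re-optimized; the increase of the weighted least-squares objective is
#' extrapolated quadratically to the chi-square quantile (1 degree of
#' freedom) to obtain a likelihood-ratio style interval.  Parameters whose
#' profile stays flat are flagged unbounded and truncated at the global
#' bounds.
#'
#' @param fit A `wsls_fit` with free parameters.
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @param delta Relative (log-scale) perturbation used to probe the profile.
#' @param maxit Iteration cap for each re-optimization.
#' @return A `param_ci` data.frame: value, lower, upper, relative width
#'   `(upper - lower)/value`, and per-side flags.
#' @export
estimate_confidence_intervals <- function(fit, alpha = 0.05, delta = 0.1,
                                          maxit = 40) {
  stopifnot(inherits(fit, "wsls_fit"), fit$theta_free)
  problem <- fit$problem
  mats <- problem_matrices(problem)
  ob <- make_wsls_objective(problem$kin, problem$vK, mats$cexp, mats$W_c,
                            mats$eexp, mats$W_e, problem$aec_min,
                            problem$conc_bounds, problem$enzyme_bounds)
  lmsys <- make_wsls_lm(problem$kin, problem$vK, mats$cexp, mats$W_c,
                        mats$eexp, mats$W_e, problem$aec_min,
                        problem$conc_bounds, problem$enzyme_bounds)
  q <- stats::qchisq(1 - alpha, df = 1)
  sp <- problem$kin$specs
  P <- nrow(sp)
  xhat <- fit$par
  wopt <- fit$objective
  rows <- vector("list", P)
  for (j in seq_len(P)) {
    fun <- function(lv) {
      lower <- ob$lower; upper <- ob$upper
      lower[j] <- upper[j] <- lv
      x0 <- xhat; x0[j] <- lv
      r <- tryCatch(
        lm_box(lmsys$resid, lmsys$jac, x0, lower, upper,
               maxiter = maxit, ftol = 1e-9),
        error = function(e) NULL)
      if (is.null(r)) Inf else ob$fn(r$par)
    }
    ci <- profile_param_ci(fun, log(fit$theta[j]), wopt, delta, q,
                           log(sp$global_lb[j]), log(sp$global_ub[j]))
    rows[[j]] <- data.frame(
      name = sp$name[j], value = unname(fit$theta[j]),
      lower = ci$lower, upper = ci$upper,
      relative_width = (ci$upper - ci$lower) / fit$theta[j],
      flag_lower = ci$flag_lower, flag_upper = ci$flag_upper,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$name
  class(out) <- c("param_ci", "data.frame")
  out
}

#' Fraction of measurements matched within one standard deviation
#'
#' @param fit A `wsls_fit`.
#' @param dataset The `omics_dataset` whose measurements are compared with
#'   the fitted concentration estimates (default: the training set of the
#'   fit).
#' @return List with metabolite, enzyme and pooled coverage fractions and
#'   the counts of assessed measurements.
#' @export
fit_coverage <- function(fit, dataset = fit$problem$dataset) {
  cover <- function(est, mean, sd) {
    keep <- intersect(rownames(est), rownames(mean))
    est <- est[keep, colnames(mean), drop = FALSE]
    mean <- mean[keep, , drop = FALSE]; sd <- sd[keep, , drop = FALSE]
    ok <- !is.na(mean)
    sd[is.na(sd)] <- 0
    hit <- abs(est - mean) <= sd
    c(hits = sum(hit[ok], na.rm = TRUE), n = sum(ok))
  }
  m <- cover(fit$c_hat, dataset$met_mean, dataset$met_sd)
  e <- cover(fit$e_hat, dataset$enz_mean, dataset$enz_sd)
  list(metabolite = unname(m["hits"] / m["n"]),
       enzyme = unname(e["hits"] / e["n"]),
       pooled = unname((m["hits"] + e["hits"]) / (m["n"] + e["n"])),
       n_metabolite = unname(m["n"]), n_enzyme = unname(e["n"]))
}

#' Rate-law simplification diagnostics
#'
#' Flags parameters that the fitted optimum has pushed to a regime where the
#' rate law is insensitive to them: (a) parameters within 1% of a global
#' bound, and (b) binding coefficients far smaller or far larger than the
#' (power-matched) concentrations of their metabolite across conditions.
#' Each flag carries the suggested algebraic simplification: a negligible
#' binding coefficient can be dropped from its denominator
#' (`K + c ~ c`), while a dominating one absorbs the metabolite
#' (`K + c ~ K`).
#'
#' @param fit A `wsls_fit`.
#' @param bound_tol Relative closeness to a global bound that triggers a
#'   flag (default 0.01).
#' @param ratio_tol Orders-of-magnitude factor for the concentration
#'   comparison (default 1e3).
#' @return data.frame with one row per flagged parameter.
#' @export
simplification_diagnostics <- function(fit, bound_tol = 0.01,
                                       ratio_tol = 1e3) {
  sp <- fit$problem$kin$specs
  th <- fit$theta
  rows <- list()
  for (j in seq_len(nrow(sp))) {
    nm <- sp$name[j]; v <- th[[nm]]
    if (v <= sp$global_lb[j] * (1 + bound_tol))
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, flag = "at_lower_bound",
        suggestion = "parameter negligible; consider removing it",
        stringsAsFactors = FALSE)
    else if (v >= sp$global_ub[j] * (1 - bound_tol))
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, flag = "at_upper_bound",
        suggestion = "parameter saturating; consider removing its term",
        stringsAsFactors = FALSE)
    if (sp$kind[j] == "Km" && !is.na(sp$km_met[j]) &&
        sp$km_met[j] %in% rownames(fit$c_hat)) {
      cc <- fit$c_hat[sp$km_met[j], ]^sp$km_power[j]
      if (v < min(cc) / ratio_tol)
        rows[[length(rows) + 1]] <- data.frame(
          name = nm, flag = "km_negligible",
          suggestion = sprintf(
            "drop Km from denominator (K + c ~ c for metabolite %s)",
            sp$km_met[j]), stringsAsFactors = FALSE)
      else if (v > max(cc) * ratio_tol)
        rows[[length(rows) + 1]] <- data.frame(
          name = nm, flag = "km_dominant",
          suggestion = sprintf(
            "drop metabolite, keep Km (K + c ~ K for metabolite %s)",
            sp$km_met[j]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), flag = character(),
                      suggestion = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
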