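# Internal convex-programming layer used by flux adjustment, FBA/KFBA and the
# synthetic-study generator.  All problems here are small (<= ~100 variables),
# so a dense dual active-set QP (quadprog) is used throughout.  LPs are solved
# by a proximal-point sequence of strictly convex QPs started from the origin;
# on polyhedral problems the sequence terminates finitely and its limit is the
# minimum-norm point of the optimal face, which doubles as a deterministic
# tie-break for alternate LP optima.

#' @importFrom quadprog solve.QP
NULL

# Solve min 1/2 x'Hx + f'x  s.t.  Aeq x = beq, Ain x >= bin, lb <= x <= ub.
# H may be NULL (pure linear objective; a ridge is then mandatory).
# Variables with lb == ub are promoted to equality rows: quadprog treats
# paired opposing inequalities poorly.
qp_solve <- function(f, H = NULL, Aeq = NULL, beq = NULL,
                     Ain = NULL, bin = NULL,
                     lb = NULL, ub = NULL, ridge = 0) {
  n <- length(f)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub + 1e-12))

  fixed <- is.finite(lb) & is.finite(ub) & (ub - lb < 1e-12)
  Aeq2 <- if (is.null(Aeq)) matrix(0, 0, n) else as.matrix(Aeq)
  beq2 <- if (is.null(beq)) numeric(0) else as.numeric(beq)
  if (any(fixed)) {
    Efix <- diag(n)[fixed, , drop = FALSE]
    Aeq2 <- rbind(Aeq2, Efix)
    beq2 <- c(beq2, (lb[fixed] + ub[fixed]) / 2)
  }

  # normalize constraint rows: quadprog's dual active-set method is
  # sensitive to mixed row scales (stoichiometric rows ~1 vs big-M rows
  # ~1e3)
  if (nrow(Aeq2)) {
    sc <- pmax(apply(abs(Aeq2), 1, max), 1e-12)
    Aeq2 <- Aeq2 / sc; beq2 <- beq2 / sc
  }
  # quadprog requires linearly independent equality rows; reduce to a row
  # basis (conserved moieties make stoichiometric matrices rank-deficient)
  # and verify the dropped rows afterwards.
  Aeq_full <- Aeq2; beq_full <- beq2
  if (nrow(Aeq2) > 1) {
    qrA <- qr(t(Aeq2))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    Aeq2 <- Aeq2[keep, , drop = FALSE]
    beq2 <- beq2[keep]
  }

  D <- if (is.null(H)) matrix(0, n, n) else as.matrix(H)
  if (ridge > 0) D <- D + diag(ridge, n)

  # inequality columns: lower bounds (x_i >= lb_i), upper bounds (-x_i >= -ub_i)
  ilb <- which(is.finite(lb) & !fixed)
  iub <- which(is.finite(ub) & !fixed)
  Alb <- diag(n)[ilb, , drop = FALSE]
  Aub <- -diag(n)[iub, , drop = FALSE]
  Ain2 <- if (is.null(Ain)) matrix(0, 0, n) else as.matrix(Ain)
  bin2 <- if (is.null(bin)) numeric(0) else as.numeric(bin)
  if (nrow(Ain2)) {
    sci <- pmax(apply(abs(Ain2), 1, max), 1e-12)
    Ain2 <- Ain2 / sci; bin2 <- bin2 / sci
  }
  Amat <- t(rbind(Aeq2, Ain2, Alb, Aub))
  bvec <- c(beq2, bin2, lb[ilb], -ub[iub])
  meq <- nrow(Aeq2)

  sol <- tryCatch(
    quadprog::solve.QP(Dmat = D, dvec = -f, Amat = Amat, bvec = bvec, meq = meq),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    return(list(status = "infeasible", message = conditionMessage(sol),
                x = NULL, obj = NA_real_))
  }
  x <- sol$solution
  if (nrow(Aeq_full)) {
    viol <- max(abs(Aeq_full %*% x - beq_full))
    if (viol > 1e-6 * max(1, max(abs(beq_full))))
      return(list(status = "infeasible", x = NULL, obj = NA_real_,
                  message = sprintf("dropped equality rows violated by %.3g", viol)))
  }
  Hx <- if (is.null(H)) 0 else 0.5 * sum(x * (as.matrix(H) %*% x))
  list(status = "optimal", x = x, obj = Hx + sum(f * x))
}

# Solve min f'x s.t. Aeq x = beq, lb <= x <= ub (all-finite boxes assumed).
# Proximal-point on the polyhedron; returns the minimum-norm optimum.
lp_solve <- function(f, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                     lb = NULL, ub = NULL,
                     rho = NULL, max_iter = 25L, tol = 1e-9) {
  n <- length(f)
  if (is.null(rho)) rho <- 1e-6 * max(1, max(abs(f)))
  x <- rep(0, n)
  fails <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- qp_solve(f = f - rho * x, H = diag(rho, n),
                  Aeq = Aeq, beq = beq, Ain = Ain, bin = bin,
                  lb = lb, ub = ub)
    if (s$status != "optimal") {
      # a larger proximal weight conditions the subproblem better; the
      # fixed point is the same LP optimum for any rho > 0
      fails <- fails + 1L
      if (fails > 4L)
        return(list(status = s$status, x = NULL, obj = NA_real_,
                    message = s$message))
      rho <- rho * 100
      next
    }
    delta <- max(abs(s$x - x))
    x <- s$x
    if (delta < tol) break
  }
  list(status = "optimal", x = x, obj = sum(f * x), iterations = it)
}

# Feasibility of {Aeq x = beq, lb <= x <= ub}.  First attempt: an exact
# projection with the equalities enforced as constraints (machine-precision
# when it succeeds).  Fallback: bounded-variable least squares on the
# equality residual, whose accuracy floor is set by the squared condition
# number of Aeq.
lp_feasibility <- function(Aeq, beq, lb, ub, tol = 1e-6) {
  A <- as.matrix(Aeq)
  n <- ncol(A)
  s0 <- qp_solve(f = rep(0, n), H = diag(1, n), Aeq = A, beq = beq,
                 lb = lb, ub = ub)
  if (s0$status == "optimal") {
    res <- sqrt(sum((A %*% s0$x - beq)^2))
    if (res <= tol * max(1, sqrt(sum(beq^2))))
      return(list(feasible = TRUE, residual = res, x = s0$x))
  }
  H <- crossprod(A) + diag(1e-10, n)
  f <- -as.numeric(crossprod(A, beq))
  s <- qp_solve(f = f, H = H, lb = lb, ub = ub)
  if (s$status != "optimal") {
    # box itself inconsistent (lb > ub) is ruled out upstream
    return(list(feasible = FALSE, residual = Inf, x = NULL))
  }
  res <- sqrt(sum((A %*% s$x - beq)^2))
  list(feasible = res <= tol * max(1, sqrt(sum(beq^2))), residual = res, x = s$x)
}
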