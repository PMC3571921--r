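#' Project measured fluxes onto the steady-state space
#'
#' Measured flux distributions rarely satisfy the model's mass balances
#' exactly.  This projection finds the steady-state flux vector closest (in
#' Euclidean distance over the measured reactions) to the measurements,
#' subject to `S v = 0`, the default flux bounds, and the biomass flux fixed
#' to the chemostat dilution rate.  Energy requirements enter through the
#' model's ATP-maintenance lower bound.  Unmeasured fluxes are free; an
#' infinitesimal ridge (1e-9) on them makes the projection unique and
#' reproducible.
#'
#' @param model A `stoich_model`.
#' @param measured Named numeric vector of measured fluxes (mmol/gDW/h);
#'   names must be reactions of the model.  May be empty.
#' @param dilution_rate Chemostat dilution rate (1/h); the biomass flux is
#'   fixed to it.
#' @return List with `v` (named flux vector over all reactions), `distance`
#'   (Euclidean norm of the adjustment over measured reactions) and
#'   `residuals` (per-measured-reaction adjustment).
#' @export
adjust_fluxes <- function(model, measured, dilution_rate) {
  r <- model$reactions
  unknown <- setdiff(names(measured), r$id)
  if (length(unknown))
    stop("measured fluxes reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(r)
  lb <- r$lb; ub <- r$ub
  ib <- match(model$biomass_rxn, r$id)
  lb[ib] <- ub[ib] <- dilution_rate
  w <- rep(1e-9, n)
  f <- rep(0, n)
  if (length(measured)) {
    im <- match(names(measured), r$id)
    w[im] <- 1
    f[im] <- -as.numeric(measured)
  }
  s <- qp_solve(f = 2 * f, H = diag(2 * w, n),
                Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
                lb = lb, ub = ub)
  if (s$status != "optimal")
    stop("no steady-state flux distribution at dilution rate ",
         dilution_rate, " is consistent with the model bounds (",
         s$message %||% "infeasible", ")")
  v <- stats::setNames(s$x, r$id)
  resid <- if (length(measured)) v[names(measured)] - measured else numeric(0)
  list(v = v, distance = sqrt(sum(resid^2)), residuals = resid)
}

#' Adjust all conditions of an omics dataset
#'
#' Applies [adjust_fluxes()] per condition and collects the results.
#'
#' @param model A `stoich_model`.
#' @param ds An `omics_dataset`; its flux matrix supplies the measured
#'   fluxes (NA entries are unmeasured).
#' @return An `adjusted_fluxes` object: `v` (reaction x condition matrix)
#'   and `distance` (per condition).
#' @export
adjust_dataset <- function(model, ds) {
  ids <- ds$conditions$condition_id
  V <- matrix(NA_real_, nrow(model$reactions), length(ids),
              dimnames = list(model$reactions$id, ids))
  dist <- stats::setNames(numeric(length(ids)), ids)
  for (j in seq_along(ids)) {
    m <- ds$fluxes[, j]
    m <- m[!is.na(m)]
    a <- adjust_fluxes(model, m, ds$conditions$dilution_rate[j])
    V[, j] <- a$v
    dist[j] <- a$distance
  }
  structure(list(v = V, distance = dist), class = "adjusted_fluxes")
}
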