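#' Kinetic flux bounds from concentrations and parameter uncertainty
#'
#' For a test condition with measured metabolite and enzyme concentrations,
#' each rate law yields an interval of achievable fluxes when its kinetic
#' parameters range over their 95% confidence box:
#' `v_min = min_theta e f(c; theta)`, `v_max = max_theta e f(c; theta)`.
#' Every law of the simplified model is monotone in each parameter at fixed
#' concentrations, so the extrema are attained at vertices of the box;
#' [flux_range()] evaluates all vertices (at most 2^3 per law) and is
#' verified against a dense parameter grid in the test suite.  The
#' unmeasured ATP concentration is ranged over its energy-charge-feasible
#' interval, which widens the bounds honestly rather than pinning ATP to a
#' guess.
#'
#' @name kinetic_bounds
NULL

#' Flux range of one rate law over a parameter confidence box
#'
#' @param law A `rate_law`.
#' @param e Measured enzyme concentration (mg protein/gDCW).
#' @param conc Named concentrations in mM; entries may be length-2 vectors
#'   `c(lo, hi)` to range a concentration (used for unmeasured ATP).
#' @param ci_lower,ci_upper Named vectors of parameter interval endpoints
#'   (registry names); parameters of the law absent from them collapse to
#'   a point at `theta`.
#' @param theta Named central parameter values (used for absent intervals).
#' @return `c(v_min, v_max)` in mmol/gDW/h.
#' @export
flux_range <- function(law, e, conc, ci_lower, ci_upper, theta = NULL) {
  if (e < 0) stop("enzyme concentration must be nonnegative")
  dims <- list()
  for (p in law$parameters) {
    lo <- if (p %in% names(ci_lower)) ci_lower[[p]] else theta[[p]]
    hi <- if (p %in% names(ci_upper)) ci_upper[[p]] else theta[[p]]
    dims[[p]] <- unique(c(lo, hi))
  }
  for (m in law$required_metabolites) {
    v <- conc[[m]]
    if (is.null(v) || any(is.na(v)))
      stop("missing required metabolite: ", m)
    dims[[paste0("c_", m)]] <- unique(range(v))
  }
  grid <- expand.grid(dims, KEEP.OUT.ATTRS = FALSE)
  f <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    th <- unlist(grid[i, law$parameters, drop = FALSE])
    names(th) <- law$parameters
    cc <- as.list(grid[i, paste0("c_", law$required_metabolites),
                       drop = FALSE])
    names(cc) <- law$required_metabolites
    f[i] <- rate_factor(law, cc, th)
  }
  if (any(!is.finite(f))) stop("rate law evaluated non-finite on the box")
  c(v_min = e * min(f), v_max = e * max(f))
}

#' Kinetic flux bounds for every reaction of a condition
#'
#' @param kin A `kinetic_model`.
#' @param dataset An `omics_dataset` containing the condition.
#' @param condition_id Condition to bound (should be outside the training
#'   set of the parameter fit; by contract, not enforced).
#' @param ci A `param_ci` (from [estimate_confidence_intervals()]) or a
#'   list with `lower`/`upper` named vectors; intervals are truncated at
#'   the global parameter bounds.
#' @param aec_min Energy-charge floor used to range unmeasured ATP.
#' @param conc_bounds Concentration box (mM).
#' @return A `flux_bounds` data.frame: `condition`, `reaction`, `v_min`,
#'   `v_max`, `atp_ranged` flag; reactions with unmeasured requirements are
#'   omitted (they contribute no constraint).
#' @export
compute_kinetic_bounds <- function(kin, dataset, condition_id, ci,
                                   aec_min = 0.8, conc_bounds = c(0.001, 10)) {
  l <- match(condition_id, dataset$conditions$condition_id)
  if (is.na(l)) stop("unknown condition: ", condition_id)
  if (inherits(ci, "data.frame")) {
    lower <- stats::setNames(ci$lower, rownames(ci))
    upper <- stats::setNames(ci$upper, rownames(ci))
    value <- stats::setNames(ci$value, rownames(ci))
  } else {
    lower <- ci$lower; upper <- ci$upper
    value <- ci$value %||% (lower + upper) / 2
  }
  sp <- kin$specs
  lower <- pmax(lower[sp$name], sp$global_lb)
  upper <- pmin(upper[sp$name], sp$global_ub)
  names(lower) <- names(upper) <- sp$name

  cm <- dataset$met_mean[, l]
  em <- dataset$enz_mean[, l]
  atp_int <- if (!is.na(cm["adp"]) && !is.na(cm["amp"])) {
    lo <- max(conc_bounds[1],
              (aec_min - 0.5) / (1 - aec_min) * cm[["adp"]] +
                aec_min / (1 - aec_min) * cm[["amp"]])
    c(min(lo, conc_bounds[2]), conc_bounds[2])
  } else conc_bounds

  rows <- list()
  for (k in names(kin$laws)) {
    law <- kin$laws[[k]]
    if (!k %in% names(em) || is.na(em[k])) next
    conc <- list()
    ok <- TRUE; atp_ranged <- FALSE
    for (m in law$required_metabolites) {
      if (m == "atp" && (!"atp" %in% names(cm) || is.na(cm["atp"]))) {
        conc[[m]] <- atp_int
        atp_ranged <- TRUE
      } else if (m %in% names(cm) && !is.na(cm[m])) {
        conc[[m]] <- cm[[m]]
      } else { ok <- FALSE; break }
    }
    if (!ok) next
    fr <- flux_range(law, em[[k]], conc, lower, upper, value)
    rows[[k]] <- data.frame(condition = condition_id, reaction = k,
                            v_min = fr[["v_min"]], v_max = fr[["v_max"]],
                            atp_ranged = atp_ranged,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(condition = character(), reaction = character(),
                  v_min = numeric(), v_max = numeric(),
                  atp_ranged = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("flux_bounds", "data.frame")
  out
}
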