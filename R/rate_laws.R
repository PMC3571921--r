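#' Simplified kinetic rate laws for central E. coli metabolism
#'
#' Every rate law has the form `v = e * f(c; theta)`: flux (mmol/gDW/h) is
#' proportional to the enzyme concentration `e` (mg protein/gDCW) times a
#' mechanistic function `f` of metabolite concentrations `c` (mM) and kinetic
#' parameters.  The shipped simplified model covers 19 reactions of
#' glycolysis and the pentose phosphate pathway with 36 distinct parameters
#' of three kinds: catalytic rate constants (`kcat`), equilibrium constants
#' (`Keq`) and binding coefficients (`Km`).
#'
#' Two functional forms are interpretive reconstructions (documented in the
#' methods vignette): the GND law
#' `kcat * c_nadp * c_6pg / (c_nadph * c_atp * (K6pg + c_6pg))`, chosen as the
#' unique form consistent with the fitted parameter units, and the PTS/PYK
#' ratio forms `c_pep/c_pyr` and `c_adp/c_atp`.
#'
#' @name rate_laws
NULL

# law table: id, f expression (R arithmetic), irreversible flag, local
# parameter kinds and units.  Concentration variables are named c_<met>.
.law_defs <- list(
  PTS   = list(expr = quote(kcat * (c_pep / c_pyr)), irr = TRUE,
               params = c(kcat = "kcat"),
               units = c(kcat = "mmol/mg protein/hr")),
  PGI   = list(expr = quote(kcat * (1 - c_f6p / (c_g6p * Keq))), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/hr", Keq = "dimensionless")),
  PFK   = list(expr = quote(kcat * c_atp), irr = TRUE,
               params = c(kcat = "kcat"),
               units = c(kcat = "mmol/mg protein/mM/hr")),
  ALDO  = list(expr = quote(kcat * (c_fdp - c_gap * c_dhap / Keq) / (Kfdp + c_fdp)),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq", Kfdp = "Km"),
               units = c(kcat = "mmol/mg protein/mM/hr", Keq = "mM", Kfdp = "mM"),
               km = list(Kfdp = list(met = "fdp", power = 1, role = "denominator"))),
  TPI   = list(expr = quote(kcat * (1 - c_gap / (c_dhap * Keq))), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/hr", Keq = "dimensionless")),
  GAPD  = list(expr = quote(kcat * (c_nad * c_gap - c_13dpg * c_nadh / Keq)),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM^2/hr", Keq = "dimensionless")),
  PGK   = list(expr = quote(kcat * (1 - c_atp * c_3pg / (c_adp * c_13dpg * Keq))),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/hr", Keq = "dimensionless")),
  PGM   = list(expr = quote(kcat * (1 - c_2pg / (c_3pg * Keq))), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/hr", Keq = "dimensionless")),
  ENO   = list(expr = quote(kcat * (c_2pg - c_pep / Keq)), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM/hr", Keq = "dimensionless")),
  PYK   = list(expr = quote(kcat * (c_adp / c_atp)), irr = TRUE,
               params = c(kcat = "kcat"),
               units = c(kcat = "mmol/mg protein/hr")),
  PDH   = list(expr = quote(kcat * c_pyr^4 / (Kpyr + c_pyr^4)), irr = TRUE,
               params = c(kcat = "kcat", Kpyr = "Km"),
               units = c(kcat = "mmol/mg protein/hr", Kpyr = "mM^4"),
               km = list(Kpyr = list(met = "pyr", power = 4, role = "denominator"))),
  PPC   = list(expr = quote(kcat * c_pep * (1 + c_fdp / Kfdp) / (Kpep + c_pep)),
               irr = TRUE,
               params = c(kcat = "kcat", Kfdp = "Km", Kpep = "Km"),
               units = c(kcat = "mmol/mg protein/hr", Kfdp = "mM", Kpep = "mM"),
               km = list(Kfdp = list(met = "fdp", power = 1, role = "activator"),
                         Kpep = list(met = "pep", power = 1, role = "denominator"))),
  G6PDH = list(expr = quote(kcat * c_nadp * c_g6p), irr = TRUE,
               params = c(kcat = "kcat"),
               units = c(kcat = "mmol/mg protein/mM^2/hr")),
  GND   = list(expr = quote(kcat * (c_nadp * c_6pg) /
                              (c_nadph * c_atp * (K6pg + c_6pg))), irr = TRUE,
               params = c(kcat = "kcat", K6pg = "Km"),
               units = c(kcat = "mmol*mM/mg protein/hr", K6pg = "mM"),
               km = list(K6pg = list(met = "6pg", power = 1, role = "denominator"))),
  RPE   = list(expr = quote(kcat * (c_ru5pD - c_xu5pD / Keq)), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM/hr", Keq = "dimensionless")),
  RPI   = list(expr = quote(kcat * (c_ru5pD - c_r5p / Keq)), irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM/hr", Keq = "dimensionless")),
  TKT1  = list(expr = quote(kcat * (c_r5p * c_xu5pD - c_s7p * c_gap / Keq)),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM^2/hr", Keq = "dimensionless")),
  TKT2  = list(expr = quote(kcat * (c_xu5pD * c_e4p - c_f6p * c_gap / Keq)),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM^2/hr", Keq = "dimensionless")),
  TALA  = list(expr = quote(kcat * (c_gap * c_s7p - c_e4p * c_f6p / Keq)),
               irr = FALSE,
               params = c(kcat = "kcat", Keq = "Keq"),
               units = c(kcat = "mmol/mg protein/mM^2/hr", Keq = "dimensionless"))
)

# fitted value, 95% half-width per parameter of the simplified model
# (shipped fixture parameter set; provenance: in vivo multi-omic fit)
.fitted_params <- list(
  PTS   = list(kcat = c(20.7, 9.1)),
  PGI   = list(kcat = c(40.2, 9.5),    Keq = c(1.23, 0.29)),
  PFK   = list(kcat = c(26, 35)),
  ALDO  = list(kcat = c(3.965, 0.010), Keq = c(0.18, 0.17), Kfdp = c(0.0074, 0.0036)),
  TPI   = list(kcat = c(10000, 14000), Keq = c(0.11400, 0.00031)),
  GAPD  = list(kcat = c(10000, 4100),  Keq = c(1.21, 0.14)),
  PGM   = list(kcat = c(9995, 40),     Keq = c(0.53570, 0.00063)),
  PGK   = list(kcat = c(54.3, 2.9),    Keq = c(5512.1, 1.2)),
  ENO   = list(kcat = c(2, 45),        Keq = c(1.4, 4.1)),
  PYK   = list(kcat = c(40, 49)),
  PDH   = list(kcat = c(10.4, 4.6),    Kpyr = c(0.000020, 0.000029)),
  PPC   = list(kcat = c(2.15, 1.80),   Kfdp = c(2.5, 6.5), Kpep = c(0.10, 0.16)),
  G6PDH = list(kcat = c(859.6, 1.1)),
  GND   = list(kcat = c(18.5, 10.8),   K6pg = c(0.021, 0.012)),
  RPI   = list(kcat = c(549.46, 0.69), Keq = c(1.40000, 0.00019)),
  RPE   = list(kcat = c(10000, 13000), Keq = c(0.4900, 0.0044)),
  TKT1  = list(kcat = c(10000, 7800),  Keq = c(1.99, 0.012)),
  TKT2  = list(kcat = c(10000, 5800),  Keq = c(3.500, 0.013)),
  TALA  = list(kcat = c(10000, 2300),  Keq = c(0.3675, 0.0021))
)

#' Global parameter-name convention
#'
#' Parameters are registered as `<local>_<reaction>`, e.g. `kcat_PGI`,
#' `Keq_PGI`, `Kfdp_ALDO`.
#'
#' @param reaction_id Reaction abbreviation (e.g. `"PGI"`).
#' @param local Local parameter name within the law (e.g. `"Keq"`).
#' @return The registry name.
#' @export
param_name <- function(reaction_id, local) paste0(local, "_", reaction_id)

#' Build the simplified 19-reaction kinetic model
#'
#' Constructs the rate-law registry: one `rate_law` per reaction with its
#' expression, required metabolites, parameter specifications (kind, units,
#' global bounds) and an analytic gradient generated by [stats::deriv()].
#' Parameters other than equilibrium constants carry global bounds
#' `[1e-6, 1e4]` in their own units; equilibrium constants are bounded to
#' `[0.35, 2.85]` times their reference value (`keq_ref`), by default the
#' shipped fitted value.
#'
#' @param keq_ref Optional named vector of reference equilibrium constants
#'   (names as in [param_name()]); defaults to the shipped fitted values.
#' @return A `kinetic_model`: list with `laws`, `specs` (data.frame) and
#'   `metabolite_ids`.
#' @export
build_simplified_model <- function(keq_ref = NULL) {
  fitted <- load_fitted_values_raw()
  laws <- list()
  specs <- list()
  for (rid in names(.law_defs)) {
    d <- .law_defs[[rid]]
    vars <- all.vars(d$expr)
    cvars <- grep("^c_", vars, value = TRUE)
    pvars <- setdiff(vars, cvars)
    stopifnot(setequal(pvars, names(d$params)))
    pnames <- param_name(rid, names(d$params))
    for (j in seq_along(pvars)) {
      lp <- names(d$params)[j]
      kind <- unname(d$params[[lp]])
      nm <- param_name(rid, lp)
      if (kind == "Keq") {
        ref <- if (!is.null(keq_ref) && nm %in% names(keq_ref))
          keq_ref[[nm]] else fitted$value[[nm]]
        lo <- 0.35 * ref; hi <- 2.85 * ref; kref <- ref
      } else {
        lo <- 1e-6; hi <- 1e4; kref <- NA_real_
      }
      kmi <- if (!is.null(d$km)) d$km[[lp]] else NULL
      specs[[nm]] <- data.frame(
        name = nm, reaction = rid, local = lp, kind = kind,
        units = unname(d$units[[lp]]), global_lb = lo, global_ub = hi,
        keq_ref = kref,
        km_met = if (is.null(kmi)) NA_character_ else kmi$met,
        km_power = if (is.null(kmi)) NA_real_ else kmi$power,
        km_role = if (is.null(kmi)) NA_character_ else kmi$role,
        stringsAsFactors = FALSE)
    }
    grad <- stats::deriv(d$expr, c(cvars, names(d$params)),
                         function.arg = c(cvars, names(d$params)))
    laws[[rid]] <- structure(list(
      reaction_id = rid, expr = d$expr,
      required_metabolites = sub("^c_", "", cvars),
      parameters = pnames, local_params = names(d$params),
      irreversible = d$irr, grad = grad), class = "rate_law")
  }
  specs <- do.call(rbind, specs)
  rownames(specs) <- specs$name
  mets <- sort(unique(unlist(lapply(laws, `[[`, "required_metabolites"))))
  structure(list(laws = laws, specs = specs,
                 metabolite_ids = union(mets, c("glc", "amp"))),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model:", length(x$laws), "rate laws,", nrow(x$specs),
      "parameters,", length(x$metabolite_ids), "metabolites\n")
  invisible(x)
}

load_fitted_values_raw <- function() {
  value <- list(); hw <- list()
  for (rid in names(.fitted_params)) {
    for (lp in names(.fitted_params[[rid]])) {
      nm <- param_name(rid, lp)
      value[[nm]] <- .fitted_params[[rid]][[lp]][1]
      hw[[nm]] <- .fitted_params[[rid]][[lp]][2]
    }
  }
  list(value = unlist(value), half_width = unlist(hw))
}

#' Load the shipped fitted parameter set
#'
#' Returns the 36 fitted parameter values of the simplified kinetic model
#' together with their 95% confidence half-widths, in the units recorded in
#' the parameter registry.
#'
#' @return List with `theta` (named numeric vector, a valid parameter set for
#'   [build_simplified_model()]) and `half_width` (named numeric vector).
#' @export
load_fitted_parameters <- function() {
  raw <- load_fitted_values_raw()
  structure(list(theta = raw$value, half_width = raw$half_width,
                 provenance = "shipped fitted values, in vivo multi-omic fit"),
            class = "param_table")
}

#' Evaluate a rate law
#'
#' Computes `v = e * f(c; theta)` in mmol/gDW/h.
#'
#' @param law A `rate_law` from [build_simplified_model()].
#' @param e Enzyme concentration, mg protein/gDCW; must be `>= 0`.
#' @param conc Named vector/list of metabolite concentrations in mM; must
#'   contain every required metabolite of the law.
#' @param theta Named parameter vector (registry names, see [param_name()]).
#' @return Flux in mmol/gDW/h (vectorized over conditions if `conc` entries
#'   are vectors).
#' @export
evaluate_rate <- function(law, e, conc, theta) {
  stopifnot(inherits(law, "rate_law"))
  if (any(e < 0)) stop("enzyme concentration must be nonnegative")
  conc <- as.list(conc)
  missing_mets <- setdiff(law$required_metabolites, names(conc))
  if (length(missing_mets))
    stop("missing required metabolite(s) for ", law$reaction_id, ": ",
         paste(missing_mets, collapse = ", "))
  cm <- conc[law$required_metabolites]
  if (any(!vapply(cm, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite concentration for ", law$reaction_id)
  f <- rate_factor(law, cm, theta)
  if (any(!is.finite(f)))
    stop("rate law ", law$reaction_id,
         " evaluated to a non-finite value (zero denominator concentration?)")
  e * f
}

# f(c; theta) without the enzyme factor; internal fast path (no checks)
rate_factor <- function(law, conc, theta) {
  args <- c(unname(as.list(conc)[law$required_metabolites]),
            unname(as.list(theta[law$parameters])))
  as.numeric(do.call(law$grad, args))
}

# f and its gradient wrt (concentrations, parameters); columns named
rate_factor_grad <- function(law, conc, theta) {
  args <- c(unname(as.list(conc)[law$required_metabolites]),
            unname(as.list(theta[law$parameters])))
  r <- do.call(law$grad, args)
  list(f = as.numeric(r), grad = attr(r, "gradient"))
}

#' Adenylate energy charge
#'
#' `AEC = (ATP + 0.5 ADP) / (ATP + ADP + AMP)`, a dimensionless number in
#' `[0, 1]` that the estimation problem constrains to be at least 0.8, tying
#' the unmeasured ATP concentration to measured ADP and AMP.
#'
#' @param c_atp,c_adp,c_amp Concentrations in mM, all `>= 0`, not all zero.
#' @return The energy charge (vectorized).
#' @export
adenylate_energy_charge <- function(c_atp, c_adp, c_amp) {
  if (any(c_atp < 0 | c_adp < 0 | c_amp < 0))
    stop("adenylate concentrations must be nonnegative")
  tot <- c_atp + c_adp + c_amp
  if (any(tot == 0)) stop("all adenylate concentrations are zero")
  (c_atp + 0.5 * c_adp) / tot
}

#' Validate a parameter set against the registry
#'
#' @param model A `kinetic_model`.
#' @param theta Named parameter vector.
#' @param tol Relative slack on the bounds.
#' @return `TRUE` invisibly; errors listing out-of-bound parameters.
#' @export
validate_parameters <- function(model, theta, tol = 1e-8) {
  sp <- model$specs
  miss <- setdiff(sp$name, names(theta))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  v <- theta[sp$name]
  bad <- v < sp$global_lb * (1 - tol) - tol | v > sp$global_ub * (1 + tol)
  if (any(bad)) stop("parameter(s) outside global bounds: ",
                     paste(sp$name[bad], collapse = ", "))
  invisible(TRUE)
}

#' Serialize a kinetic model to JSON
#'
#' The schema holds, per law: the reaction id, the rate expression in R
#' arithmetic syntax (`+ - * / ^` and parentheses over `c_<met>` and local
#' parameter names), the irreversibility flag, and the parameter specs with
#' kind, units, bounds and Keq reference.
#'
#' @param model A `kinetic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_json <- function(model, path) {
  laws <- lapply(model$laws, function(l) list(
    reaction_id = l$reaction_id,
    expression = paste(deparse(l$expr), collapse = " "),
    irreversible = l$irreversible))
  jsonlite::write_json(list(laws = unname(laws), specs = model$specs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kinetic model from JSON
#'
#' Counterpart of [write_kinetic_json()]; new rate laws can be registered by
#' adding entries to the JSON (expression grammar: R arithmetic over
#' `c_<met>` and parameter names).
#'
#' @param path JSON path.
#' @return A `kinetic_model`.
#' @export
read_kinetic_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- as.data.frame(j$specs)
  rownames(specs) <- specs$name
  laws <- list()
  for (i in seq_len(nrow(j$laws))) {
    rid <- j$laws$reaction_id[i]
    expr <- str2lang(j$laws$expression[i])
    vars <- all.vars(expr)
    cvars <- grep("^c_", vars, value = TRUE)
    pvars <- setdiff(vars, cvars)
    sp <- specs[specs$reaction == rid, ]
    stopifnot(setequal(pvars, sp$local))
    grad <- stats::deriv(expr, c(cvars, sp$local[match(pvars, sp$local)]),
                         function.arg = c(cvars, pvars))
    laws[[rid]] <- structure(list(
      reaction_id = rid, expr = expr,
      required_metabolites = sub("^c_", "", cvars),
      parameters = param_name(rid, pvars), local_params = pvars,
      irreversible = isTRUE(j$laws$irreversible[i]), grad = grad),
      class = "rate_law")
  }
  mets <- sort(unique(unlist(lapply(laws, `[[`, "required_metabolites"))))
  structure(list(laws = laws, specs = specs,
                 metabolite_ids = union(mets, c("glc", "amp"))),
            class = "kinetic_model")
}
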