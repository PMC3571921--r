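#' Thermodynamic distance-from-equilibrium analysis
#'
#' With equilibrium constants estimated in vivo, the standard Gibbs free
#' energy change of each reversible reaction follows as
#' `dG = -R T ln(Keq)`, and the condition-specific value as
#' `dG* = dG + R T sum_i S_ij ln(c_i)` with concentrations in mM (the same
#' convention the equilibrium constants were fitted under; the choice of
#' concentration standard state cancels between conditions for balanced
#' reactions).  Reactions whose mean `dG*` across conditions falls below
#' -10 kJ/mol are operating far from equilibrium and are the natural flux
#' control points; values near zero indicate proximity to equilibrium.
#'
#' @name thermo
NULL

.R_GAS <- 8.314e-3  # kJ/mol/K

#' Standard Gibbs free energy change from an equilibrium constant
#'
#' @param keq Equilibrium constant (must be positive); concentration
#'   convention mM.
#' @param temperature Temperature in K (default 298.15).
#' @return `-R T ln(keq)` in kJ/mol (vectorized).
#' @export
delta_g_standard <- function(keq, temperature = 298.15) {
  if (any(keq <= 0)) stop("keq must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  -.R_GAS * temperature * log(keq)
}

#' Condition-specific Gibbs free energy change
#'
#' @param stoich Named stoichiometric coefficients of the reaction
#'   (negative substrates, positive products).
#' @param dG_standard Standard Gibbs free energy change, kJ/mol.
#' @param conc Named metabolite concentrations in mM.
#' @param temperature Temperature in K.
#' @param exclude Metabolite ids excluded from the concentration term
#'   (protons, water).
#' @return `dG_standard + R T sum S ln c` in kJ/mol, or `NA` when any
#'   participating concentration is missing or non-positive (never a silent
#'   default).
#' @export
delta_g_condition <- function(stoich, dG_standard, conc,
                              temperature = 298.15,
                              exclude = c("h", "h2o")) {
  stoich <- stoich[setdiff(names(stoich), exclude)]
  stoich <- stoich[stoich != 0]
  cc <- unlist(conc)[names(stoich)]
  if (length(cc) < length(stoich) || any(is.na(cc)) || any(cc <= 0))
    return(NA_real_)
  dG_standard + .R_GAS * temperature * sum(stoich * log(cc))
}

#' Per-reaction Gibbs free energy changes across conditions
#'
#' Computes `dG` (standard, from the fitted equilibrium constant) and `dG*`
#' per condition for every reversible rate law of the kinetic model, using
#' the stoichiometry of the matching reaction in the network.  Irreversible
#' laws carry no equilibrium constant and are excluded, matching the
#' convention that no equilibrium distance is reported for them.
#'
#' @param model A `stoich_model` supplying reaction stoichiometries.
#' @param kin A `kinetic_model`.
#' @param theta Named parameter vector with the `Keq_*` entries.
#' @param conc Metabolite x condition concentration matrix in mM (`NA` =
#'   missing; such conditions yield non-computable `dG*`).
#' @param temperature Temperature in K.
#' @return A `thermo_result`: data.frame with `reaction`, `dG_standard`,
#'   `mean`, `sd`, `n_computable`, plus the `dG_star` matrix as an
#'   attribute.
#' @export
thermo_analysis <- function(model, kin, theta, conc, temperature = 298.15) {
  S <- as.matrix(model$S)
  rev_laws <- names(kin$laws)[!vapply(kin$laws, `[[`, TRUE, "irreversible")]
  L <- ncol(conc)
  dG_star <- matrix(NA_real_, length(rev_laws), L,
                    dimnames = list(rev_laws, colnames(conc)))
  rows <- lapply(rev_laws, function(k) {
    keq <- theta[[param_name(k, "Keq")]]
    dg0 <- delta_g_standard(keq, temperature)
    st <- S[, k]
    st <- st[st != 0]
    for (l in seq_len(L))
      dG_star[k, l] <<- delta_g_condition(st, dg0, conc[, l], temperature)
    ok <- !is.na(dG_star[k, ])
    data.frame(reaction = k, dG_standard = dg0,
               mean = if (any(ok)) mean(dG_star[k, ok]) else NA_real_,
               sd = if (sum(ok) > 1) stats::sd(dG_star[k, ok]) else NA_real_,
               n_computable = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$reaction
  attr(out, "dG_star") <- dG_star
  class(out) <- c("thermo_result", "data.frame")
  out
}

#' Classify reactions by distance from equilibrium
#'
#' @param thermo A `thermo_result` from [thermo_analysis()].
#' @param threshold Far-from-equilibrium threshold in kJ/mol (default -10).
#' @param near_range Interval of mean `dG*` called near-equilibrium
#'   (default `[-2, 0]`).
#' @return The input data.frame with a `classification` column:
#'   `"far"`, `"near"`, `"intermediate"`, or `"unclassified"` when no
#'   condition was computable.
#' @export
classify_equilibrium <- function(thermo, threshold = -10,
                                 near_range = c(-2, 0)) {
  cls <- ifelse(thermo$n_computable == 0 | is.na(thermo$mean), "unclassified",
                ifelse(thermo$mean < threshold, "far",
                       ifelse(thermo$mean >= near_range[1] &
                                thermo$mean <= near_range[2],
                              "near", "intermediate")))
  thermo$classification <- cls
  thermo
}

#' Classify metabolite effects on enzyme activities
#'
#' Compares each retained binding coefficient with the (power-matched)
#' concentrations of its metabolite across conditions.  Binding terms in a
#' denominator represent saturation/inhibition; multiplier terms like the
#' fructose-1,6-bisphosphate activation of PEP carboxylase represent
#' activation.  An effect is strong when the median concentration-to-
#' binding-coefficient ratio lies outside `[0.1, 10]` (metabolite far from
#' the binding transition), intermediate when the two are within an order
#' of magnitude.
#'
#' @param kin A `kinetic_model`.
#' @param theta Named parameter vector.
#' @param conc Metabolite x condition concentration matrix (mM).
#' @return data.frame with `enzyme`, `metabolite`, `mode`
#'   (inhibition/activation), `strength` (strong/intermediate) and the
#'   median ratio; one row per (enzyme, metabolite, Km) triple with
#'   observed concentrations.
#' @export
classify_metabolite_effects <- function(kin, theta, conc) {
  sp <- kin$specs[kin$specs$kind == "Km" & !is.na(kin$specs$km_met), ]
  rows <- list()
  for (j in seq_len(nrow(sp))) {
    met <- sp$km_met[j]
    if (!met %in% rownames(conc)) next
    cc <- conc[met, ]
    cc <- cc[!is.na(cc)]
    if (!length(cc)) next
    ratio <- stats::median(cc^sp$km_power[j]) / theta[[sp$name[j]]]
    rows[[length(rows) + 1]] <- data.frame(
      enzyme = sp$reaction[j], metabolite = met,
      parameter = sp$name[j],
      mode = if (identical(sp$km_role[j], "activator")) "activation"
      else "inhibition",
      strength = if (ratio < 0.1 || ratio > 10) "strong" else "intermediate",
      median_ratio = ratio, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(enzyme = character(), metabolite = character(),
                      parameter = character(), mode = character(),
                      strength = character(), median_ratio = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
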