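#' Stoichiometric model objects
#'
#' A `stoich_model` bundles a sparse stoichiometric matrix `S` (metabolites x
#' reactions) with per-reaction reversibility flags, default flux bounds in
#' mmol/gDW/h, and the designations used downstream: the biomass reaction
#' (fixed to the chemostat dilution rate), the glucose uptake (PTS) reaction
#' (the KFBA objective), the subset of reactions carrying kinetic rate laws,
#' and the fermentative reactions that are blocked under aerobic
#' glucose-limited growth.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `reversible`,
#'   `lb`, `ub`.
#' @param S numeric matrix or Matrix, metabolites x reactions.
#' @param biomass_rxn,glucose_uptake_rxn reaction identifiers.
#' @param kinetic_rxns character vector, subset of reaction ids with rate laws.
#' @param fermentative_rxns character vector of fermentative reaction ids.
#' @param notes free-text provenance.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, S,
                         biomass_rxn = NULL, glucose_uptake_rxn = NULL,
                         kinetic_rxns = character(), fermentative_rxns = character(),
                         notes = "") {
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(list(
    metabolites = metabolites, reactions = reactions, S = S,
    biomass_rxn = biomass_rxn, glucose_uptake_rxn = glucose_uptake_rxn,
    kinetic_rxns = kinetic_rxns, fermentative_rxns = fermentative_rxns,
    notes = notes), class = "stoich_model")
  validate_stoich_model(m)
  m
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: dimension agreement between `S` and the
#' metabolite/reaction tables, `lb <= ub` with nonnegative lower bounds on
#' irreversible reactions, and membership of the biomass, glucose-uptake and
#' kinetic reaction designations in the reaction list.
#'
#' @param m A `stoich_model`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_stoich_model <- function(m) {
  stopifnot(inherits(m, "stoich_model"))
  r <- m$reactions
  if (nrow(m$S) != nrow(m$metabolites) || ncol(m$S) != nrow(r))
    stop("S dimensions do not match metabolite/reaction tables")
  if (anyDuplicated(m$metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(r$id)) stop("duplicate reaction ids")
  if (nrow(r) == 0) stop("model has zero reactions")
  if (any(r$lb > r$ub)) stop("lb > ub for reaction(s): ",
                             paste(r$id[r$lb > r$ub], collapse = ", "))
  bad <- !r$reversible & r$lb < 0
  if (any(bad)) stop("irreversible reaction(s) with negative lb: ",
                     paste(r$id[bad], collapse = ", "))
  for (d in c(m$biomass_rxn, m$glucose_uptake_rxn))
    if (!is.null(d) && !d %in% r$id) stop("designated reaction not in model: ", d)
  if (!all(m$kinetic_rxns %in% r$id))
    stop("kinetic_rxns not in model: ",
         paste(setdiff(m$kinetic_rxns, r$id), collapse = ", "))
  invisible(m)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions (", length(x$kinetic_rxns),
      "with kinetic rate laws )\n")
  if (!is.null(x$biomass_rxn))
    cat("  biomass:", x$biomass_rxn, " glucose uptake:", x$glucose_uptake_rxn, "\n")
  invisible(x)
}

#' Load a shipped stoichiometric network fixture
#'
#' The `"ecoli_central"` fixture is a curated central E. coli network
#' (glycolysis, pentose phosphate pathway, TCA cycle, lumped oxidative
#' phosphorylation, anaplerosis, fermentative secretion, exchanges, and a
#' lumped biomass drain) that contains all 19 reactions of the simplified
#' kinetic model.  Composition notes are embedded in the JSON file itself.
#'
#' @param name Fixture identifier; currently `"ecoli_central"`.
#' @return A `stoich_model`.
#' @export
load_fixture <- function(name = "ecoli_central") {
  if (!identical(name, "ecoli_central"))
    stop("unknown fixture: ", name)
  path <- system.file("extdata", "ecoli_central.json", package = "kfba",
                      mustWork = TRUE)
  read_model_json(path)
}

#' Read a stoichiometric model from the package JSON schema
#'
#' The schema is documented in `inst/extdata/ecoli_central.json`: a top-level
#' object with `metabolites` (id/name/compartment), `reactions` (id, name,
#' stoichiometry map, reversible, lb, ub), reaction designations and notes.
#'
#' @param path Path to a JSON model file.
#' @return A `stoich_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(j$metabolites, function(x)
    data.frame(id = x$id, name = x$name %||% x$id,
               compartment = x$compartment %||% "c",
               stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(j$reactions, function(x)
    data.frame(id = x$id, name = x$name %||% x$id,
               reversible = isTRUE(x$reversible),
               lb = as.numeric(x$lb), ub = as.numeric(x$ub),
               stringsAsFactors = FALSE)))
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (x in j$reactions) {
    for (met in names(x$stoichiometry)) {
      if (!met %in% mets$id)
        stop("reaction ", x$id, " references undeclared metabolite ", met)
      S[met, x$id] <- as.numeric(x$stoichiometry[[met]])
    }
  }
  stoich_model(mets, rxns, S,
               biomass_rxn = j$biomass_rxn,
               glucose_uptake_rxn = j$glucose_uptake_rxn,
               kinetic_rxns = unlist(j$kinetic_rxns),
               fermentative_rxns = unlist(j$fermentative_rxns),
               notes = paste(unlist(j$notes), collapse = " "))
}

#' Write a stoichiometric model to the package JSON schema
#'
#' @param m A `stoich_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  S <- as.matrix(m$S)
  rx <- lapply(seq_len(nrow(m$reactions)), function(i) {
    r <- m$reactions[i, ]
    nz <- which(S[, i] != 0)
    st <- as.list(S[nz, i])
    names(st) <- rownames(S)[nz]
    list(id = r$id, name = r$name, stoichiometry = st,
         reversible = r$reversible, lb = r$lb, ub = r$ub)
  })
  mets <- lapply(seq_len(nrow(m$metabolites)), function(i) {
    as.list(m$metabolites[i, c("id", "name", "compartment")])
  })
  jsonlite::write_json(
    list(notes = m$notes, metabolites = mets, reactions = rx,
         biomass_rxn = m$biomass_rxn,
         glucose_uptake_rxn = m$glucose_uptake_rxn,
         kinetic_rxns = m$kinetic_rxns,
         fermentative_rxns = m$fermentative_rxns),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Block reactions (fix their flux to zero)
#'
#' Sets `lb = ub = 0` for the listed reactions, as done for the fermentative
#' pathways under aerobic glucose-limited growth where only carbon dioxide is
#' secreted.
#'
#' @param m A `stoich_model`.
#' @param rxn_ids Character vector of reaction ids to block; all must exist.
#' @return The modified model.
#' @export
block_reactions <- function(m, rxn_ids) {
  unknown <- setdiff(rxn_ids, m$reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  i <- m$reactions$id %in% rxn_ids
  m$reactions$lb[i] <- 0
  m$reactions$ub[i] <- 0
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
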