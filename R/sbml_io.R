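#' SBML import and export
#'
#' A self-contained SBML dialect handler covering what constraint-based
#' central-metabolism models need: species with compartments, reactions
#' with stoichiometries and reversibility, and flux bounds from either the
#' fbc package (Level 3) or legacy COBRA-style kinetic-law parameters
#' named `LOWER_BOUND`/`UPPER_BOUND` (Level 2); fbc wins when both are
#' present.  Defaults are -1000/1000 (reversible) and 0/1000
#' (irreversible) mmol/gDW/h.  Rate laws are exported as MathML
#' `kineticLaw` elements and read back for the arithmetic operator set
#' `+ - * / ^`.  Model-level designations (biomass, glucose uptake,
#' kinetic and fermentative reaction sets) travel in a model annotation.
#'
#' @name sbml_io
NULL

.sbml_ops <- c(plus = "+", minus = "-", times = "*", divide = "/",
               power = "^")

expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn>", format(e, digits = 17), "</cn>"))
  if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_to_mathml(e[[2]]))
    tag <- names(.sbml_ops)[match(op, .sbml_ops)]
    if (is.na(tag)) stop("unsupported operator in rate expression: ", op)
    args <- vapply(as.list(e)[-1], expr_to_mathml, "")
    return(paste0("<apply><", tag, "/>", paste(args, collapse = ""),
                  "</apply>"))
  }
  stop("unsupported expression element")
}

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "math") return(mathml_to_expr(xml2::xml_child(node)))
  if (nm == "apply") {
    ch <- xml2::xml_children(node)
    op <- .sbml_ops[[xml2::xml_name(ch[[1]])]]
    if (is.null(op)) stop("unsupported MathML operator: ",
                          xml2::xml_name(ch[[1]]))
    args <- lapply(ch[-1], mathml_to_expr)
    if (length(args) == 1 && op == "-")
      return(call("-", args[[1]]))
    out <- args[[1]]
    for (a in args[-1]) out <- call(op, out, a)
    return(out)
  }
  stop("unsupported MathML node: ", nm)
}

#' Write a stoichiometric model (optionally with rate laws) to SBML
#'
#' @param model A `stoich_model`.
#' @param path Output path.
#' @param kin Optional `kinetic_model`; its laws are embedded as MathML
#'   kinetic laws on the matching reactions.
#' @param level `3` (fbc-style bound attributes) or `2` (legacy
#'   kinetic-law bound parameters).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, kin = NULL, level = 3) {
  S <- as.matrix(model$S)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  buf <- c('<?xml version="1.0" encoding="UTF-8"?>')
  if (level == 3) {
    buf <- c(buf, paste0(
      '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">'))
  } else {
    buf <- c(buf, '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">')
  }
  buf <- c(buf, '<model id="model">')
  buf <- c(buf, "<annotation><designations xmlns=\"https://kfba.r/designations\">",
           sprintf('<biomass>%s</biomass><glucoseUptake>%s</glucoseUptake>',
                   model$biomass_rxn %||% "", model$glucose_uptake_rxn %||% ""),
           sprintf('<kinetic>%s</kinetic>',
                   paste(model$kinetic_rxns, collapse = " ")),
           sprintf('<fermentative>%s</fermentative>',
                   paste(model$fermentative_rxns, collapse = " ")),
           "</designations></annotation>")
  comps <- unique(model$metabolites$compartment)
  buf <- c(buf, "<listOfCompartments>",
           sprintf('<compartment id="%s" constant="true"/>', comps),
           "</listOfCompartments>")
  buf <- c(buf, "<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    buf <- c(buf, sprintf(
      '<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      mt$id, esc(mt$name), mt$compartment))
  }
  buf <- c(buf, "</listOfSpecies>")
  if (level == 3) {
    ub_ids <- unique(c(model$reactions$lb, model$reactions$ub))
    buf <- c(buf, "<listOfParameters>",
             sprintf('<parameter id="B_%d" value="%s" constant="true"/>',
                     seq_along(ub_ids), format(ub_ids, digits = 17)),
             "</listOfParameters>")
    bid <- function(x) sprintf("B_%d", match(x, ub_ids))
  }
  buf <- c(buf, "<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    attr_extra <- if (level == 3)
      sprintf(' fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s"',
              bid(r$lb), bid(r$ub)) else ""
    buf <- c(buf, sprintf(
      '<reaction id="R_%s" name="%s" reversible="%s"%s>',
      r$id, esc(r$name), tolower(as.character(r$reversible)), attr_extra))
    subs <- which(S[, i] < 0); prods <- which(S[, i] > 0)
    if (length(subs)) {
      buf <- c(buf, "<listOfReactants>",
               sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                       rownames(S)[subs], format(-S[subs, i], digits = 17)),
               "</listOfReactants>")
    }
    if (length(prods)) {
      buf <- c(buf, "<listOfProducts>",
               sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                       rownames(S)[prods], format(S[prods, i], digits = 17)),
               "</listOfProducts>")
    }
    has_law <- !is.null(kin) && r$id %in% names(kin$laws)
    if (has_law || level == 2) {
      buf <- c(buf, "<kineticLaw>")
      if (has_law) {
        law <- kin$laws[[r$id]]
        ml <- expr_to_mathml(call("*", as.name("e"), law$expr))
        buf <- c(buf, paste0(
          '<math xmlns="http://www.w3.org/1998/Math/MathML">', ml, "</math>"))
      }
      if (level == 2) {
        buf <- c(buf, "<listOfParameters>",
                 sprintf('<parameter id="LOWER_BOUND" value="%s"/>',
                         format(r$lb, digits = 17)),
                 sprintf('<parameter id="UPPER_BOUND" value="%s"/>',
                         format(r$ub, digits = 17)),
                 "</listOfParameters>")
      }
      buf <- c(buf, "</kineticLaw>")
    }
    buf <- c(buf, "</reaction>")
  }
  buf <- c(buf, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(buf, path)
  invisible(path)
}

#' Read an SBML model (Level 2 or 3)
#'
#' @param path SBML file path.
#' @return A `stoich_model`; rate-law MathML, when present, is attached as
#'   attribute `"kinetic_exprs"` (named list of R expressions including the
#'   enzyme factor `e`).
#' @export
load_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("malformed SBML: no <model> element")
  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  strip_id <- function(x) sub("^(M_|R_)", "", x)
  mets <- data.frame(
    id = strip_id(xml2::xml_attr(sp, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_id(xml2::xml_attr(sp, "id")),
                  xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rx)) stop("SBML model has zero reactions")
  n <- length(rx)
  ids <- strip_id(xml2::xml_attr(rx, "id"))
  rev <- !(xml2::xml_attr(rx, "reversible") %in% "false")
  lb <- ifelse(rev, -1000, 0); ub <- rep(1000, n)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  kexpr <- list()
  for (i in seq_len(n)) {
    for (sref in xml2::xml_find_all(rx[[i]], "./listOfReactants/speciesReference")) {
      met <- strip_id(xml2::xml_attr(sref, "species"))
      if (!met %in% mets$id)
        stop("malformed SBML: reaction ", ids[i],
             " references undeclared species ", met)
      st <- xml2::xml_attr(sref, "stoichiometry")
      S[met, i] <- S[met, i] - as.numeric(ifelse(is.na(st), 1, st))
    }
    for (sref in xml2::xml_find_all(rx[[i]], "./listOfProducts/speciesReference")) {
      met <- strip_id(xml2::xml_attr(sref, "species"))
      if (!met %in% mets$id)
        stop("malformed SBML: reaction ", ids[i],
             " references undeclared species ", met)
      st <- xml2::xml_attr(sref, "stoichiometry")
      S[met, i] <- S[met, i] + as.numeric(ifelse(is.na(st), 1, st))
    }
    # legacy kinetic-law bound parameters
    for (p in xml2::xml_find_all(rx[[i]], "./kineticLaw/listOfParameters/parameter")) {
      pid <- xml2::xml_attr(p, "id")
      pv <- as.numeric(xml2::xml_attr(p, "value"))
      if (identical(pid, "LOWER_BOUND")) lb[i] <- pv
      if (identical(pid, "UPPER_BOUND")) ub[i] <- pv
    }
    # fbc bounds override when present
    flb <- xml2::xml_attr(rx[[i]], "lowerFluxBound")
    fub <- xml2::xml_attr(rx[[i]], "upperFluxBound")
    if (!is.na(flb) && flb %in% names(parval)) lb[i] <- parval[[flb]]
    if (!is.na(fub) && fub %in% names(parval)) ub[i] <- parval[[fub]]
    math <- xml2::xml_find_first(rx[[i]], "./kineticLaw/math")
    if (!inherits(math, "xml_missing"))
      kexpr[[ids[i]]] <- mathml_to_expr(math)
  }
  des <- xml2::xml_find_first(mdl, "./annotation/designations")
  getdes <- function(tag) {
    nd <- xml2::xml_find_first(des, paste0("./", tag))
    if (inherits(nd, "xml_missing")) return(character(0))
    txt <- trimws(xml2::xml_text(nd))
    if (!nzchar(txt)) character(0) else strsplit(txt, "\\s+")[[1]]
  }
  biomass <- NULL; pts <- NULL; kin_ids <- character(); ferm <- character()
  if (!inherits(des, "xml_missing")) {
    biomass <- getdes("biomass"); if (!length(biomass)) biomass <- NULL
    pts <- getdes("glucoseUptake"); if (!length(pts)) pts <- NULL
    kin_ids <- getdes("kinetic")
    ferm <- getdes("fermentative")
  } else if (length(kexpr)) {
    kin_ids <- names(kexpr)
  }
  m <- stoich_model(mets,
                    data.frame(id = ids, name = xml2::xml_attr(rx, "name"),
                               reversible = rev, lb = lb, ub = ub,
                               stringsAsFactors = FALSE),
                    S, biomass_rxn = biomass, glucose_uptake_rxn = pts,
                    kinetic_rxns = intersect(kin_ids, ids),
                    fermentative_rxns = intersect(ferm, ids))
  if (length(kexpr)) attr(m, "kinetic_exprs") <- kexpr
  m
}
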