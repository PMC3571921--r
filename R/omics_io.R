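#' Multi-omic chemostat datasets
#'
#' An `omics_dataset` holds, per experimental condition: the chemostat
#' dilution rate (1/h), an optional knockout annotation, measured fluxes
#' (mmol/gDW/h), and metabolite (mM) and enzyme (mg protein/gDCW)
#' concentration means and standard deviations.  Missing measurements are
#' flagged, never imputed; they simply drop out of the weighted
#' least-squares objective through a zero weight.
#'
#' @param conditions data.frame with columns `condition_id`, `dilution_rate`,
#'   `knockout` (NA when none).
#' @param fluxes numeric matrix, reactions x conditions; `NA` = unmeasured.
#' @param met_mean,met_sd numeric matrices, metabolites x conditions
#'   (`NA` = missing).
#' @param enz_mean,enz_sd numeric matrices, enzymes x conditions.
#' @return An `omics_dataset`.
#' @export
omics_dataset <- function(conditions, fluxes, met_mean, met_sd,
                          enz_mean, enz_sd) {
  ids <- conditions$condition_id
  if (anyDuplicated(ids)) stop("duplicate condition ids")
  if (any(conditions$dilution_rate <= 0)) stop("dilution_rate must be > 0")
  for (nm in c("fluxes", "met_mean", "met_sd", "enz_mean", "enz_sd")) {
    m <- get(nm)
    if (!identical(colnames(m), ids))
      stop(nm, " columns must match condition ids")
  }
  if (!identical(dim(met_mean), dim(met_sd)) ||
      !identical(dim(enz_mean), dim(enz_sd)))
    stop("mean and sd matrices must have identical shape")
  if (any(met_mean < 0, na.rm = TRUE) || any(enz_mean < 0, na.rm = TRUE))
    stop("negative concentration mean")
  if (any(met_sd < 0, na.rm = TRUE) || any(enz_sd < 0, na.rm = TRUE))
    stop("negative standard deviation")
  structure(list(conditions = conditions, fluxes = fluxes,
                 met_mean = met_mean, met_sd = met_sd,
                 enz_mean = enz_mean, enz_sd = enz_sd,
                 metabolite_ids = rownames(met_mean),
                 enzyme_ids = rownames(enz_mean)),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("Omics dataset:", nrow(x$conditions), "conditions,",
      length(x$metabolite_ids), "metabolites,",
      length(x$enzyme_ids), "enzymes\n")
  nmiss <- sum(is.na(x$met_mean)) + sum(is.na(x$enz_mean))
  cat("  missing concentration cells:", nmiss, "\n")
  invisible(x)
}

#' Subset an omics dataset by condition
#'
#' @param ds An `omics_dataset`.
#' @param condition_ids Conditions to keep, in order.
#' @return The subsetted dataset.
#' @export
subset_conditions <- function(ds, condition_ids) {
  stopifnot(all(condition_ids %in% ds$conditions$condition_id))
  i <- match(condition_ids, ds$conditions$condition_id)
  omics_dataset(ds$conditions[i, , drop = FALSE],
                ds$fluxes[, i, drop = FALSE],
                ds$met_mean[, i, drop = FALSE], ds$met_sd[, i, drop = FALSE],
                ds$enz_mean[, i, drop = FALSE], ds$enz_sd[, i, drop = FALSE])
}

#' Read per-condition omics tables
#'
#' Expects four UTF-8 CSV files (schemas also written by
#' [write_omics_tables()]):
#' \describe{
#'   \item{condition_path}{columns `condition`, `dilution_rate`, `knockout`
#'     (blank when none).}
#'   \item{flux_path}{column `condition` plus one column per reaction;
#'     blank cells mean unmeasured.}
#'   \item{metabolite_path}{column `condition` plus `<met>_mean`, `<met>_sd`
#'     column pairs; blank cells are flagged missing, never imputed.}
#'   \item{enzyme_path}{same layout as the metabolite table.}
#' }
#'
#' @param flux_path,metabolite_path,enzyme_path,condition_path CSV paths.
#' @param model Optional `stoich_model`; when given, flux columns must name
#'   reactions of the model.
#' @return An `omics_dataset`.
#' @export
read_omics_tables <- function(flux_path, metabolite_path, enzyme_path,
                              condition_path, model = NULL) {
  cond <- utils::read.csv(condition_path, stringsAsFactors = FALSE)
  need <- c("condition", "dilution_rate")
  if (!all(need %in% names(cond)))
    stop("condition table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cond$condition))
    stop("duplicate condition ids in ", condition_path)
  conditions <- data.frame(condition_id = as.character(cond$condition),
                           dilution_rate = cond$dilution_rate,
                           knockout = if ("knockout" %in% names(cond))
                             ifelse(is.na(cond$knockout) | cond$knockout == "",
                                    NA_character_, cond$knockout)
                           else NA_character_,
                           stringsAsFactors = FALSE)

  read_wide <- function(path, what) {
    x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"condition" %in% names(x)) stop(what, " table lacks 'condition' column")
    if (!setequal(x$condition, conditions$condition_id))
      stop(what, " table conditions do not match condition table")
    x[match(conditions$condition_id, x$condition), , drop = FALSE]
  }
  fx <- read_wide(flux_path, "flux")
  rxns <- setdiff(names(fx), "condition")
  if (!is.null(model)) {
    unknown <- setdiff(rxns, model$reactions$id)
    if (length(unknown))
      stop("flux table references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
  }
  fluxes <- t(as.matrix(fx[, rxns, drop = FALSE]))
  colnames(fluxes) <- conditions$condition_id

  read_meansd <- function(path, what) {
    x <- read_wide(path, what)
    cols <- setdiff(names(x), "condition")
    mcols <- grep("_mean$", cols, value = TRUE)
    species <- sub("_mean$", "", mcols)
    scols <- paste0(species, "_sd")
    if (!all(scols %in% cols))
      stop(what, " table: every <id>_mean column needs a matching <id>_sd")
    mean <- t(as.matrix(x[, mcols, drop = FALSE]))
    sd <- t(as.matrix(x[, scols, drop = FALSE]))
    rownames(mean) <- rownames(sd) <- species
    colnames(mean) <- colnames(sd) <- conditions$condition_id
    if (any(mean < 0, na.rm = TRUE))
      stop(what, " table: negative mean in ", path)
    if (any(sd < 0, na.rm = TRUE))
      stop(what, " table: negative sd in ", path)
    list(mean = mean, sd = sd)
  }
  met <- read_meansd(metabolite_path, "metabolite")
  enz <- read_meansd(enzyme_path, "enzyme")
  omics_dataset(conditions, fluxes, met$mean, met$sd, enz$mean, enz$sd)
}

#' Write an omics dataset to the CSV schemas of [read_omics_tables()]
#'
#' @param ds An `omics_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_omics_tables <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(conditions = file.path(dir, "conditions.csv"),
             fluxes = file.path(dir, "fluxes.csv"),
             metabolites = file.path(dir, "metabolites.csv"),
             enzymes = file.path(dir, "enzymes.csv"))
  cond <- data.frame(condition = ds$conditions$condition_id,
                     dilution_rate = ds$conditions$dilution_rate,
                     knockout = ds$conditions$knockout)
  utils::write.csv(cond, paths["conditions"], row.names = FALSE, na = "")
  utils::write.csv(cbind(condition = colnames(ds$fluxes),
                         as.data.frame(t(ds$fluxes))),
                   paths["fluxes"], row.names = FALSE, na = "")
  wide <- function(mean, sd) {
    out <- data.frame(condition = colnames(mean))
    for (sp in rownames(mean)) {
      out[[paste0(sp, "_mean")]] <- mean[sp, ]
      out[[paste0(sp, "_sd")]] <- sd[sp, ]
    }
    out
  }
  utils::write.csv(wide(ds$met_mean, ds$met_sd), paths["metabolites"],
                   row.names = FALSE, na = "")
  utils::write.csv(wide(ds$enz_mean, ds$enz_sd), paths["enzymes"],
                   row.names = FALSE, na = "")
  invisible(paths)
}

#' Inverse-variance weights for the WSLS objective
#'
#' Weights are the inverse of the experimental variance, with a coefficient-
#' of-variation floor guarding degenerate (zero or missing) standard
#' deviations: `W = 1 / max(sd^2, (variance_floor * mean)^2)`.  Missing
#' measurements get weight zero and thereby drop out of the objective.  When
#' a species has no per-condition standard deviations at all but a shared
#' replicate-derived value is available for some conditions, that species-
#' level standard deviation is reused across conditions.
#'
#' @param ds An `omics_dataset`.
#' @param variance_floor Minimum coefficient of variation (default 0.05).
#' @return List of matrices `W_c` (1/mM^2) and `W_e` ((gDCW/mg protein)^2),
#'   shaped like the mean matrices.
#' @export
compute_weights <- function(ds, variance_floor = 0.05) {
  one <- function(mean, sd) {
    # share a species-level sd into conditions whose own sd is absent
    # (replicate-derived variance reuse); zero sds are handled by the floor
    for (i in seq_len(nrow(sd))) {
      have <- !is.na(sd[i, ]) & sd[i, ] > 0
      need <- !is.na(mean[i, ]) & is.na(sd[i, ])
      if (any(have) && any(need)) sd[i, need] <- mean(sd[i, have])
    }
    if (variance_floor <= 0 && any(!is.na(mean) & (is.na(sd) | sd == 0)))
      stop("zero/missing sds present; a positive variance_floor is required")
    sd[is.na(sd)] <- 0
    v <- pmax(sd^2, (variance_floor * mean)^2)
    W <- 1 / v
    W[is.na(mean) | !is.finite(W)] <- 0
    W
  }
  list(W_c = one(ds$met_mean, ds$met_sd), W_e = one(ds$enz_mean, ds$enz_sd))
}
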