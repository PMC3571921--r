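#' Run the full estimation-to-prediction pipeline
#'
#' Orchestrates the stages end to end: load the network, obtain a dataset
#' (synthetic study or CSV tables), project measured fluxes onto steady
#' state, fit the kinetic parameters by weighted least squares, profile
#' confidence intervals, run the thermodynamic analysis, derive kinetic
#' flux bounds for held-out conditions, and solve FBA/KFBA for each of
#' them.  Every artifact is written to the output directory with an md5
#' checksum recorded in a manifest, so a run is reproducible from its
#' configuration and seed alone.
#'
#' @param config Configuration list (or path to a YAML file with the same
#'   structure).  Recognized entries, all optional:
#'   \describe{
#'     \item{seed}{integer, default 1.}
#'     \item{output_dir}{artifact directory, default `"kfba_run"`.}
#'     \item{model}{fixture name (default `"ecoli_central"`) or path to an
#'       SBML/JSON model.}
#'     \item{data}{either `list(simulate = list(n_train, n_test, noise_cv))`
#'       (default: 20 + 5 conditions at 5% noise) or
#'       `list(tables = list(fluxes=, metabolites=, enzymes=, conditions=),
#'       test_conditions = ...)`.}
#'     \item{estimation}{`n_starts`, `aec_min`, `variance_floor`.}
#'     \item{thermo}{`temperature`, `threshold`.}
#'     \item{kfba}{`n_star` override.}
#'   }
#' @return The run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out <- config$output_dir %||% "kfba_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  est <- config$estimation %||% list()
  th_cfg <- config$thermo %||% list()
  manifest <- list(seed = seed, started = format(Sys.time()),
                   stages = list())
  artifacts <- character()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(status = "complete", ...)
  }

  model_spec <- config$model %||% "ecoli_central"
  model <- if (identical(model_spec, "ecoli_central")) load_fixture()
  else if (grepl("\\.json$", model_spec)) read_model_json(model_spec)
  else load_sbml(model_spec)
  kin <- build_simplified_model()
  note("model", reactions = nrow(model$reactions),
       kinetic = length(model$kinetic_rxns))

  data_cfg <- config$data %||% list(simulate = list())
  if (!is.null(data_cfg$tables)) {
    tb <- data_cfg$tables
    ds <- read_omics_tables(tb$fluxes, tb$metabolites, tb$enzymes,
                            tb$conditions, model = model)
    test_ids <- data_cfg$test_conditions %||% character(0)
    train_ids <- setdiff(ds$conditions$condition_id, test_ids)
    theta_true <- NULL
    study <- NULL
  } else {
    sim <- data_cfg$simulate %||% list()
    study <- generate_study(model, kin,
                            n_train = sim$n_train %||% 20,
                            n_test = sim$n_test %||% 5,
                            noise_cv = sim$noise_cv %||% 0.05,
                            seed = seed)
    ds <- study$dataset
    train_ids <- study$split$train
    test_ids <- study$split$test
    theta_true <- study$theta_true
    write_omics_tables(ds, file.path(out, "omics"))
  }
  note("data", n_train = length(train_ids), n_test = length(test_ids))

  train <- subset_conditions(ds, train_ids)
  adj <- adjust_dataset(model, train)
  utils::write.csv(data.frame(condition = names(adj$distance),
                              distance = adj$distance),
                   file.path(out, "adjustment.csv"), row.names = FALSE)
  note("adjust", max_distance = max(adj$distance))

  W <- compute_weights(train, variance_floor = est$variance_floor %||% 0.05)
  pb <- wsls_problem(kin, train, W, adj,
                     aec_min = est$aec_min %||% 0.8)
  fit <- solve_wsls(pb, n_starts = est$n_starts %||% 24, seed = seed)
  theta_df <- data.frame(name = names(fit$theta), value = unname(fit$theta))
  utils::write.csv(theta_df, file.path(out, "parameters.csv"),
                   row.names = FALSE)
  cov <- fit_coverage(fit)
  note("fit", wsls = fit$wsls, coverage_pooled = cov$pooled)

  ci <- estimate_confidence_intervals(fit)
  utils::write.csv(as.data.frame(ci), file.path(out, "confidence_intervals.csv"),
                   row.names = FALSE)
  note("ci", n_identifiable = sum(ci$relative_width < 10))

  thr <- thermo_analysis(model, kin, fit$theta, fit$c_hat,
                         temperature = th_cfg$temperature %||% 298.15)
  thr <- classify_equilibrium(thr, threshold = th_cfg$threshold %||% -10)
  utils::write.csv(as.data.frame(thr), file.path(out, "thermo.csv"),
                   row.names = FALSE)
  eff <- classify_metabolite_effects(kin, fit$theta, fit$c_hat)
  utils::write.csv(eff, file.path(out, "metabolite_effects.csv"),
                   row.names = FALSE)
  note("thermo", far = sum(thr$classification == "far"))

  kfba_rows <- list(); bound_rows <- list()
  for (cid in test_ids) {
    bounds <- compute_kinetic_bounds(kin, ds, cid, ci,
                                     aec_min = est$aec_min %||% 0.8)
    bound_rows[[cid]] <- bounds
    D <- ds$conditions$dilution_rate[ds$conditions$condition_id == cid]
    meas <- ds$fluxes[, cid]
    meas <- meas[!is.na(meas)]
    adj_t <- adjust_fluxes(model, meas, D)
    fba <- solve_fba(model, D)
    kf <- solve_kfba(model, bounds, D, n_star = config$kfba$n_star %||% NULL)
    ev_f <- evaluate_predictions(fba$v, adj_t$v[names(meas)], model, D)
    ev_k <- evaluate_predictions(kf$v, adj_t$v[names(meas)], model, D)
    kfba_rows[[cid]] <- data.frame(
      condition = cid, dilution_rate = D, n_star = kf$n_star,
      n_bounds = nrow(bounds),
      fba_uptake = fba$objective, kfba_uptake = kf$objective,
      fba_residual = ev_f$mean_residual, kfba_residual = ev_k$mean_residual,
      fba_yield = ev_f$yield, kfba_yield = ev_k$yield,
      stringsAsFactors = FALSE)
  }
  if (length(bound_rows))
    utils::write.csv(do.call(rbind, bound_rows),
                     file.path(out, "kinetic_bounds.csv"), row.names = FALSE)
  kdf <- if (length(kfba_rows)) do.call(rbind, kfba_rows) else NULL
  if (!is.null(kdf)) {
    utils::write.csv(kdf, file.path(out, "kfba_evaluation.csv"),
                     row.names = FALSE)
    p <- tryCatch(sign_test(kdf$kfba_residual, kdf$fba_residual),
                  warning = function(w) NA_real_)
    note("kfba", median_n_star = stats::median(kdf$n_star),
         residual_sign_test_p = as.numeric(p))
  } else note("kfba", skipped = "no test conditions")

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest$artifacts <- data.frame(
    file = basename(files), md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
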