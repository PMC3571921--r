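# Shared fixtures, built lazily and cached for the whole test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

fixture_model <- function() cached("model", function() load_fixture())
fixture_kin <- function() cached("kin", function() build_simplified_model())
fitted_theta <- function() cached("theta", function()
  load_fitted_parameters()$theta)

# small noiseless synthetic study shared across module tests
small_study <- function() cached("small_study", function()
  generate_study(fixture_model(), fixture_kin(), n_train = 5, n_test = 2,
                 noise_cv = 0, seed = 101))

# a dataset whose measurements equal the hidden truth of a study
noiseless_dataset <- function(study) {
  tr <- study$truth
  ds <- study$dataset
  met_mean <- tr$conc
  met_sd <- tr$conc * 0
  met_mean["atp", ] <- NA
  met_sd["atp", ] <- NA
  omics_dataset(ds$conditions, tr$v[rownames(ds$fluxes), , drop = FALSE],
                met_mean, met_sd, tr$enz, tr$enz * 0)
}

# tiny linear-chain model  A_e -> A -> B -> biomass-ish drain
chain_model <- function() {
  mets <- data.frame(id = c("A_e", "A", "B"), name = c("A_e", "A", "B"),
                     compartment = c("e", "c", "c"))
  rxns <- data.frame(id = c("EX_A", "UP", "R1", "R2"),
                     name = c("A exchange", "uptake", "step 1", "step 2"),
                     reversible = c(TRUE, FALSE, FALSE, FALSE),
                     lb = c(-1000, 0, 0, 0), ub = c(1000, 1000, 1000, 1000))
  S <- matrix(0, 3, 4, dimnames = list(mets$id, rxns$id))
  S["A_e", "EX_A"] <- -1
  S["A_e", "UP"] <- -1; S["A", "UP"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1
  stoich_model(mets, rxns, S, biomass_rxn = "R2", glucose_uptake_rxn = "UP")
}

# scipy LP oracle (pre-installed python); returns the optimal objective
scipy_lp_objective <- function(f, Aeq, lb, ub) {
  dir <- tempfile("lp")
  dir.create(dir)
  utils::write.csv(as.data.frame(as.matrix(Aeq)), file.path(dir, "A.csv"),
                   row.names = FALSE)
  writeLines(as.character(f), file.path(dir, "f.txt"))
  writeLines(as.character(lb), file.path(dir, "lb.txt"))
  writeLines(as.character(ub), file.path(dir, "ub.txt"))
  script <- sprintf("
import numpy as np, pandas as pd
from scipy.optimize import linprog
d = %s
A = pd.read_csv(d + '/A.csv').values
f = np.loadtxt(d + '/f.txt'); lb = np.loadtxt(d + '/lb.txt'); ub = np.loadtxt(d + '/ub.txt')
r = linprog(f, A_eq=A, b_eq=np.zeros(A.shape[0]), bounds=list(zip(lb, ub)), method='highs')
print(repr(r.fun))
", deparse(dir))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  as.numeric(out[length(out)])
}
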