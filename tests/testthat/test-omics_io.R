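toy_dataset <- function() {
  cond <- data.frame(condition_id = c("c1", "c2", "c3"),
                     dilution_rate = c(0.1, 0.2, 0.2),
                     knockout = c(NA, NA, "PGI"))
  fx <- matrix(c(1, 2, NA, 1.5, 2.5, 3), 2, 3,
               dimnames = list(c("PTS", "PGI"), cond$condition_id))
  mm <- matrix(c(1, 0.5, 2, NA, 1.5, 0.6), 2, 3,
               dimnames = list(c("g6p", "f6p"), cond$condition_id))
  ms <- matrix(c(0.5, 0.1, 0.2, NA, 0.3, 0.1), 2, 3, dimnames = dimnames(mm))
  em <- matrix(c(0.1, 0.2, 0.3), 1, 3,
               dimnames = list("PTS", cond$condition_id))
  es <- em * 0.1
  omics_dataset(cond, fx, mm, ms, em, es)
}

test_that("CSV tables round trip through read_omics_tables", {
  ds <- toy_dataset()
  dir <- tempfile("omics")
  paths <- write_omics_tables(ds, dir)
  ds2 <- read_omics_tables(paths["fluxes"], paths["metabolites"],
                           paths["enzymes"], paths["conditions"])
  expect_equal(nrow(ds2$conditions), 3)
  expect_equal(ds2$met_mean, ds$met_mean)
  expect_equal(ds2$enz_sd, ds$enz_sd)
  expect_equal(ds2$fluxes, ds$fluxes)
  # blank cell stayed missing, not imputed
  expect_true(is.na(ds2$met_mean["f6p", "c2"]))
  expect_true(is.na(ds2$fluxes["PTS", "c2"]))
  expect_identical(ds2$conditions$knockout, c(NA, NA, "PGI"))
})

test_that("schema violations are rejected with informative errors", {
  ds <- toy_dataset()
  dir <- tempfile("omics")
  paths <- write_omics_tables(ds, dir)
  # negative sd
  x <- utils::read.csv(paths["metabolites"], check.names = FALSE)
  x$g6p_sd[1] <- -0.1
  utils::write.csv(x, paths["metabolites"], row.names = FALSE, na = "")
  expect_error(read_omics_tables(paths["fluxes"], paths["metabolites"],
                                 paths["enzymes"], paths["conditions"]),
               "negative sd")
  # duplicate condition ids
  paths <- write_omics_tables(ds, dir)
  y <- utils::read.csv(paths["conditions"])
  y$condition[2] <- y$condition[1]
  utils::write.csv(y, paths["conditions"], row.names = FALSE, na = "")
  expect_error(read_omics_tables(paths["fluxes"], paths["metabolites"],
                                 paths["enzymes"], paths["conditions"]),
               "duplicate")
  # unknown reaction against a model
  paths <- write_omics_tables(ds, dir)
  fx <- utils::read.csv(paths["fluxes"], check.names = FALSE)
  names(fx)[2] <- "NOT_A_REACTION"
  utils::write.csv(fx, paths["fluxes"], row.names = FALSE, na = "")
  expect_error(read_omics_tables(paths["fluxes"], paths["metabolites"],
                                 paths["enzymes"], paths["conditions"],
                                 model = fixture_model()),
               "unknown reaction")
})

test_that("weights are inverse variances with a floor and zero for missing", {
  ds <- toy_dataset()
  W <- compute_weights(ds, variance_floor = 0.05)
  expect_equal(W$W_c["g6p", "c1"], 1 / 0.5^2)   # sd 0.5 -> 4.0 per mM^2
  expect_equal(W$W_c["f6p", "c2"], 0)           # missing -> zero weight
  # floor rule: sd 0 with floor 0.05 and mean 2 -> 1 / 0.1^2 = 100
  ds$met_sd["g6p", "c2"] <- 0
  ds$met_mean["g6p", "c2"] <- 2
  W2 <- compute_weights(ds, variance_floor = 0.05)
  expect_equal(W2$W_c["g6p", "c2"], 100)
  # a species-level sd is shared into conditions lacking one
  ds$met_sd["f6p", "c1"] <- NA
  W3 <- compute_weights(ds, variance_floor = 1e-6)
  shared <- mean(ds$met_sd["f6p", 3])
  expect_equal(W3$W_c["f6p", "c1"], 1 / shared^2)
  expect_error(compute_weights(ds, variance_floor = 0), "variance_floor")
})

test_that("weights are invariant under condition reordering", {
  ds <- toy_dataset()
  W <- compute_weights(ds)
  dsr <- subset_conditions(ds, c("c3", "c1", "c2"))
  Wr <- compute_weights(dsr)
  expect_equal(Wr$W_c[, c("c1", "c2", "c3")], W$W_c)
  expect_equal(sum(Wr$W_c > 0), sum(!is.na(ds$met_mean)))
})
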