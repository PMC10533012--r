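test_that("toy CSV triple loads with a single-cell missingness mask", {
  dir <- write_toy_triple()
  tri <- load_dataset(file.path(dir, "observations.csv"),
                      file.path(dir, "variables.csv"),
                      file.path(dir, "bounds.csv"))
  miss <- missing_cells(tri$dataset)
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$observation, "b")
  expect_equal(miss$variable, "x1")
  expect_equal(nrow(tri$bounds), 1L)
})

test_that("invalid inputs are rejected with informative errors", {
  dir <- write_toy_triple(lower = 3, upper = 2)
  expect_error(load_dataset(file.path(dir, "observations.csv"),
                            file.path(dir, "variables.csv"),
                            file.path(dir, "bounds.csv")),
               "lower > upper.*b, x1")

  # blocking dummy with a fractional value
  dir2 <- write_toy_triple()
  obs <- read.csv(file.path(dir2, "observations.csv"))
  obs$blkB[1] <- 0.5
  write.csv(obs, file.path(dir2, "observations.csv"), row.names = FALSE,
            na = "NA")
  expect_error(load_dataset(file.path(dir2, "observations.csv"),
                            file.path(dir2, "variables.csv"),
                            file.path(dir2, "bounds.csv")),
               "binary column 'blkB'")

  # unknown role string
  dir3 <- write_toy_triple()
  meta <- read.csv(file.path(dir3, "variables.csv"))
  meta$role[1] <- "covariate"
  write.csv(meta, file.path(dir3, "variables.csv"), row.names = FALSE)
  expect_error(load_dataset(file.path(dir3, "observations.csv"),
                            file.path(dir3, "variables.csv"),
                            file.path(dir3, "bounds.csv")),
               "unknown role")

  # missing predictor cell without a bound
  dir4 <- write_toy_triple()
  writeLines("observation,variable,day,lower,upper",
             file.path(dir4, "bounds.csv"))
  expect_error(load_dataset(file.path(dir4, "observations.csv"),
                            file.path(dir4, "variables.csv"),
                            file.path(dir4, "bounds.csv")),
               "without bounds.*b, x1")
})

test_that("bound entries for observed cells are dropped with a warning", {
  stale <- data.frame(observation = "a", variable = "x2",
                      day = NA_integer_, lower = 0, upper = 1)
  dir <- write_toy_triple(extra_bounds = stale)
  expect_warning(
    tri <- load_dataset(file.path(dir, "observations.csv"),
                        file.path(dir, "variables.csv"),
                        file.path(dir, "bounds.csv")),
    "non-missing cells.*a, x2")
  expect_equal(nrow(tri$bounds), 1L)
})

test_that("write then load round-trips values bit-exactly with the mask", {
  g <- generate_study(simulation_design(
    n_obs = 15, n_numeric_predictors = 6, n_temporal = 2,
    missing_prob = 0.2, seed = 3))
  dir <- tempfile("rt")
  write_dataset(g$dataset, g$bounds, dir)
  tri <- load_dataset(file.path(dir, "observations.csv"),
                      file.path(dir, "variables.csv"),
                      file.path(dir, "bounds.csv"),
                      file.path(dir, "series.csv"))
  for (v in names(g$dataset$values)) {
    expect_identical(tri$dataset$values[[v]], g$dataset$values[[v]],
                     label = v)
  }
  expect_identical(tri$dataset$series$value, g$dataset$series$value)
  expect_identical(as.data.frame(tri$bounds)$lower, g$bounds$lower)
  expect_identical(missing_cells(tri$dataset), missing_cells(g$dataset))
})

test_that("every missing predictor cell maps to exactly one bound entry", {
  g <- generate_study(simulation_design(n_obs = 40, seed = 11))
  miss <- missing_cells(g$dataset, roles = "predictor")
  mkey <- milasso:::bounds_key(miss)
  bkey <- milasso:::bounds_key(as.data.frame(g$bounds))
  expect_setequal(mkey, bkey)
  expect_false(anyDuplicated(bkey) > 0)
})

test_that("validation report tallies roles, missingness and variance", {
  sm <- make_small_dataset()
  rep1 <- validate_dataset(sm$dataset)
  expect_equal(unname(rep1$missing_counts["x1"]), 1)
  expect_length(rep1$issues, 0)

  # zero-variance predictor flagged
  vals <- data.frame(observation = c("a", "b", "c"), x1 = c(1, 1, 1),
                     FA_pctFA = c(1, 2, 3))
  meta <- data.frame(name = c("x1", "FA_pctFA"),
                     role = c("predictor", "response"), kind = "numeric",
                     units = "", temporal = FALSE)
  rep2 <- validate_dataset(mi_dataset(vals, meta))
  expect_equal(rep2$zero_variance, "x1")
  expect_match(rep2$issues, "zero-variance")

  # study-scale fixture: 115 predictors including the N-source dummies
  g <- generate_study(simulation_design(n_obs = 121,
                                        n_numeric_predictors = 113,
                                        seed = 5))
  rep3 <- validate_dataset(g$dataset)
  expect_equal(unname(rep3$role_tally["predictor"]), 115)
})
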