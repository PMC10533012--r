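make_cat_dataset <- function(levels_vec) {
  n <- length(levels_vec)
  vals <- data.frame(observation = sprintf("o%d", seq_len(n)),
                     Nsource = levels_vec,
                     FA_pctFA = seq_len(n))
  meta <- data.frame(name = c("Nsource", "FA_pctFA"),
                     role = c("categorical_raw", "response"),
                     kind = c("categorical", "numeric"),
                     units = "", temporal = FALSE)
  mi_dataset(vals, meta)
}

test_that("one-hot encoding assigns zeros to the reference level", {
  ds <- make_cat_dataset(c("NO3", "Urea", "NH4", "NO3"))
  enc <- one_hot_encode(ds, "Nsource", reference_level = "NH4")
  expect_true(all(c("NsourceNO3", "NsourceUrea") %in% names(enc$values)))
  # the reference-level row is all zeros
  nh4 <- which(ds$values$Nsource == "NH4")
  expect_equal(enc$values$NsourceNO3[nh4], 0)
  expect_equal(enc$values$NsourceUrea[nh4], 0)
  expect_equal(enc$values$NsourceNO3, c(1, 0, 0, 1))
  expect_equal(enc$values$NsourceUrea, c(0, 1, 0, 0))
  expect_equal(enc$meta$role[enc$meta$name == "Nsource"], "auxiliary")
})

test_that("binary categoricals give a single dummy, c levels give c-1", {
  ds2 <- make_cat_dataset(c("A", "B", "B", "A"))
  enc2 <- one_hot_encode(ds2, "Nsource", reference_level = "B")
  expect_equal(sum(grepl("^Nsource.", names(enc2$values))), 1L)
  expect_equal(enc2$values$NsourceA, c(1, 0, 0, 1))

  set.seed(1)
  g <- generate_study(simulation_design(n_obs = 60, n_origin_groups = 4,
                                        missing_prob = 0, seed = 13))
  dummies <- g$meta$name[g$meta$role == "blocking_dummy"]
  expect_length(dummies, 3L)
  sums <- rowSums(g$dataset$values[, dummies])
  expect_true(all(sums %in% c(0, 1)))
})

test_that("encoding errors and missingness propagation behave", {
  ds <- make_cat_dataset(c("A", "A", "A", "A"))
  expect_error(one_hot_encode(ds, "Nsource"), "fewer than 2")
  ds2 <- make_cat_dataset(c("A", "B", NA, "A"))
  enc <- one_hot_encode(ds2, "Nsource", reference_level = "B")
  expect_true(is.na(enc$values$NsourceA[3]))
})

test_that("dummies reconstruct the original categorical exactly", {
  lv <- c("NO3", "Urea", "NH4", "NO3", "Urea", "NH4", "NO3")
  ds <- make_cat_dataset(lv)
  enc <- one_hot_encode(ds, "Nsource", reference_level = "auto")
  map <- attr(enc, "derived_map")
  ref <- attr(enc, "reference_level")[["Nsource"]]
  rebuilt <- rep(ref, length(lv))
  for (k in seq_len(nrow(map))) {
    rebuilt[enc$values[[map$derived[k]]] == 1] <- map$level[k]
  }
  expect_identical(rebuilt, lv)
})

test_that("temporal averages take the trailing k-day mean", {
  expect_equal(as.numeric(temporal_average(c(`6` = 2, `7` = 4), 7, 2)), 3.0)
  expect_equal(as.numeric(temporal_average(
    c(`4` = 1, `5` = 2, `6` = 3, `7` = 6), 7, 4)), 3.0)
  s <- setNames(rep(5.5, 8), 0:7)
  for (k in 2:4) expect_equal(as.numeric(temporal_average(s, 7, k)), 5.5)
  # k = 1 degenerates to the day-of-harvest value
  expect_equal(as.numeric(temporal_average(s, 7, 1)), 5.5)
  # short culture: flagged partial average over available days
  short <- temporal_average(c(`0` = 1, `1` = 3), 1, 4)
  expect_equal(as.numeric(short), 2.0)
  expect_true(attr(short, "partial"))
  expect_false(attr(temporal_average(s, 7, 2), "partial"))
  expect_error(temporal_average(c(`3` = 1), 7, 2), "lacks day")
})

test_that("FA ratios to C16:0 divide percentages and guard the zero case", {
  expect_equal(ratio_to_reference(15, 30), 0.5)
  expect_equal(ratio_to_reference(30, 30), 1.0)
  expect_equal(ratio_to_reference(0, 30), 0.0)
  expect_warning(r <- ratio_to_reference(c(15, 10), c(30, 0)),
                 "non-positive C16:0")
  expect_equal(r, c(0.5, NA))
})

test_that("design matrix carries harvest values, averages and dummies", {
  g <- generate_study(simulation_design(n_obs = 20, n_numeric_predictors = 6,
                                        n_temporal = 2, missing_prob = 0,
                                        seed = 21))
  b <- build_design(g$dataset)
  expect_true(all(c("tv1", "tv1_2DaysAv", "tv1_3DaysAv", "tv1_4DaysAv")
                  %in% colnames(b$X)))
  expect_true(all(b$blocking %in% colnames(b$X)))
  # harvest-day column equals the series value at the collection day
  s <- g$dataset$series
  o <- g$dataset$obs[1]
  cd <- g$dataset$collection_day[o]
  v <- s$value[s$observation == o & s$variable == "tv1" & s$day == cd]
  expect_equal(unname(b$X[o, "tv1"]), v)
  # 2-day average from the raw series
  v2 <- s$value[s$observation == o & s$variable == "tv1" &
                  s$day %in% c(cd - 1, cd)]
  expect_equal(unname(b$X[o, "tv1_2DaysAv"]), mean(v2))
})
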