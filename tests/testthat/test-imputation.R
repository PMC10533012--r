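test_that("degenerate intervals pin the imputed value", {
  sm <- make_small_dataset()
  b <- as.data.frame(sm$bounds)
  b$lower <- 2; b$upper <- 2
  stack <- draw_imputations(sm$dataset, bounds_table(b), m = 5, seed = 1)
  for (d in stack$datasets) expect_equal(d$values$x1[2], 2)
})

test_that("uniform draws fill bounds with the right mean and coverage", {
  sm <- make_small_dataset()
  # interval (0, 1) on the single missing cell, many imputations
  b <- as.data.frame(sm$bounds)
  b$lower <- 0; b$upper <- 1
  stack <- draw_imputations(sm$dataset, bounds_table(b), m = 2000, seed = 42)
  draws <- vapply(stack$datasets, function(d) d$values$x1[2], numeric(1))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("a complete dataset yields identical copies and zero B", {
  g <- generate_study(simulation_design(n_obs = 25, n_numeric_predictors = 6,
                                        n_temporal = 0, missing_prob = 0,
                                        seed = 9))
  stack <- draw_imputations(g$dataset, g$bounds, m = 4, seed = 3)
  for (i in 2:4) {
    expect_identical(stack$datasets[[i]]$values, stack$datasets[[1]]$values)
  }
  fits <- lapply(1:4, function(i) {
    stepwise_fit(as.data.frame(build_design(stack$datasets[[i]])$X),
                 stack$datasets[[i]]$values$EPA_pctFA,
                 build_terms(c("x01", "x02")))
  })
  pooled <- pool_fits(fits, 4)
  expect_true(all(pooled$terms$B == 0))
})

test_that("imputed values respect bounds; observed cells never change", {
  g <- generate_study(simulation_design(n_obs = 40, missing_prob = 0.25,
                                        seed = 14))
  stack <- draw_imputations(g$dataset, g$bounds, m = 6, seed = 5)
  bdf <- as.data.frame(g$bounds)
  key_b <- milasso:::bounds_key(bdf)
  for (d in stack$datasets) {
    expect_equal(nrow(missing_cells(d, roles = "predictor")), 0L)
    miss <- missing_cells(g$dataset, roles = "predictor")
    hit <- match(milasso:::bounds_key(miss), key_b)
    for (k in seq_len(nrow(miss))) {
      v <- if (is.na(miss$day[k])) {
        d$values[[miss$variable[k]]][match(miss$observation[k], d$obs)]
      } else {
        with(d$series, value[observation == miss$observation[k] &
                               variable == miss$variable[k] &
                               day == miss$day[k]])
      }
      expect_gte(v, bdf$lower[hit[k]])
      expect_lte(v, bdf$upper[hit[k]])
    }
    # observed cells identical to the source
    obs_mask <- !is.na(g$dataset$values$x01)
    expect_identical(d$values$x01[obs_mask],
                     g$dataset$values$x01[obs_mask])
  }
})

test_that("stacks are seed-deterministic and differ only at imputed cells", {
  g <- generate_study(simulation_design(n_obs = 30, missing_prob = 0.2,
                                        seed = 16))
  s1 <- draw_imputations(g$dataset, g$bounds, m = 3, seed = 11)
  s2 <- draw_imputations(g$dataset, g$bounds, m = 3, seed = 11)
  for (i in 1:3) {
    expect_identical(s1$datasets[[i]]$values, s2$datasets[[i]]$values)
    expect_identical(s1$datasets[[i]]$series, s2$datasets[[i]]$series)
  }
  s3 <- draw_imputations(g$dataset, g$bounds, m = 3, seed = 12)
  miss <- missing_cells(g$dataset, roles = "predictor")
  for (v in setdiff(names(g$dataset$values), miss$variable)) {
    expect_identical(s1$datasets[[1]]$values[[v]],
                     s3$datasets[[1]]$values[[v]])
  }
})

test_that("imputation preconditions are enforced", {
  sm <- make_small_dataset()
  expect_error(draw_imputations(sm$dataset, sm$bounds, m = 1, seed = 1),
               "m >= 2")
  empty <- bounds_table(data.frame(observation = character(),
                                   variable = character(), day = integer(),
                                   lower = numeric(), upper = numeric()))
  expect_error(draw_imputations(sm$dataset, empty, m = 3, seed = 1),
               "without bounds")
})
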