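# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except what a test itself writes to a tempdir.

# A 3-observation toy dataset with one missing predictor cell and a
# matching bound entry, written as the four CSVs; returns the directory.
write_toy_triple <- function(dir = tempfile("toy"),
                             lower = 1.5, upper = 2.5,
                             extra_bounds = NULL,
                             x2_vals = c(0.5, 0.1, 0.9)) {
  dir.create(dir, recursive = TRUE)
  obs <- data.frame(observation = c("a", "b", "c"),
                    collection_day = c(5L, 5L, 6L),
                    x1 = c(1.0, NA, 3.0),
                    x2 = x2_vals,
                    blkB = c(0, 1, 0),
                    FA_pctFA = c(10, 12, 14))
  meta <- data.frame(name = c("x1", "x2", "blkB", "FA_pctFA"),
                     role = c("predictor", "predictor", "blocking_dummy",
                              "response"),
                     kind = c("numeric", "numeric", "binary", "numeric"),
                     units = "", temporal = FALSE)
  bnd <- data.frame(observation = "b", variable = "x1", day = NA_integer_,
                    lower = lower, upper = upper)
  if (!is.null(extra_bounds)) bnd <- rbind(bnd, extra_bounds)
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE,
            na = "NA")
  write.csv(meta, file.path(dir, "variables.csv"), row.names = FALSE)
  write.csv(bnd, file.path(dir, "bounds.csv"), row.names = FALSE, na = "NA")
  dir
}

# Small in-memory dataset with controllable missingness, no temporal vars.
make_small_dataset <- function(n = 8, missing = c(2L), seed = 99) {
  set.seed(seed)
  obs <- sprintf("o%02d", seq_len(n))
  vals <- data.frame(observation = obs,
                     x1 = rnorm(n, 5), x2 = runif(n),
                     FA_pctFA = rnorm(n))
  truth <- vals$x1[missing]
  vals$x1[missing] <- NA
  meta <- data.frame(name = c("x1", "x2", "FA_pctFA"),
                     role = c("predictor", "predictor", "response"),
                     kind = "numeric", units = "", temporal = FALSE)
  ds <- mi_dataset(vals, meta)
  bnd <- bounds_table(data.frame(observation = obs[missing], variable = "x1",
                                 day = NA_integer_,
                                 lower = truth - 1, upper = truth + 1))
  list(dataset = ds, bounds = bnd, truth = truth)
}

# A compact pipeline design that runs in seconds: strong signal, few
# predictors, small m.
fast_design <- function(seed, n_obs = 60, missing_prob = 0.1,
                        noise_sd = 0.25, block_offsets = NULL) {
  simulation_design(
    n_obs = n_obs, n_numeric_predictors = 10, n_temporal = 0,
    n_origin_groups = 3, true_terms = list(
      list(term = "x01", coef = 2.0),
      list(term = "x05", coef = -1.5),
      list(term = c("x01", "x05"), coef = 1.0)),
    block_offsets = block_offsets,
    noise_sd = noise_sd, missing_prob = missing_prob, seed = seed)
}

fast_config <- function(m = 3) {
  cfg <- default_config()
  cfg$imputation$m <- m
  cfg
}

# Fabricate a stepwise_fit-shaped object for pooling tests.
fake_fit <- function(terms, estimates, ses, ps, adj_r2 = 0.9, n = 50) {
  structure(list(
    terms = setdiff(terms, "(Intercept)"),
    coefficients = data.frame(term = terms, estimate = estimates,
                              se = ses, t = estimates / pmax(ses, 1e-12),
                              p = ps, stringsAsFactors = FALSE),
    adj_r2 = adj_r2, sigma2 = 1, n = n, steps = 0L,
    screen_dropped = character()), class = "stepwise_fit")
}

# Independent bisection oracle for the carbonate proton condition, written
# against the solver's returned constants but with its own arithmetic.
oracle_carbonate_ph <- function(medium, temperature_C, pCO2_atm) {
  S <- if (is.null(medium$salinity)) 0 else medium$salinity
  k <- carbonate_constants(temperature_C, S)
  g <- function(nm) if (is.null(medium[[nm]])) 0 else medium[[nm]]
  Z <- g("Na") + g("K") + 2 * g("Mg") + 2 * g("Ca") + g("NH4") -
    g("Cl") - 2 * g("SO4") - g("NO3") - g("PO4")
  co2 <- k$KH * pCO2_atm
  bal <- function(pH) {
    H <- 10^(-pH)
    H + Z - k$Kw / H - k$K1 * co2 / H - 2 * k$K1 * k$K2 * co2 / H^2
  }
  lo <- 2; hi <- 12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (bal(lo) * bal(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# L-BFGS-B oracle for the LASSO objective via the positive/negative split:
# minimize (1/2n)||y - X(u - v)||^2 + lambda * sum(u + v), u, v >= 0.
oracle_lasso <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  fn <- function(w) {
    b <- w[1:p] - w[(p + 1):(2 * p)]
    sum((y - X %*% b)^2) / (2 * n) + lambda * sum(w)
  }
  gr <- function(w) {
    b <- w[1:p] - w[(p + 1):(2 * p)]
    g <- -crossprod(X, y - X %*% b) / n
    c(g + lambda, -g + lambda)
  }
  fit <- optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 5000, factr = 10))
  list(beta = fit$par[1:p] - fit$par[(p + 1):(2 * p)],
       objective = fit$value)
}
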