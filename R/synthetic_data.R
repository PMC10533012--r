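# run expr under a local RNG state so generators are seeded but callers'
# RNG streams are untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation design for study-shaped synthetic data
#'
#' Describes a synthetic study mimicking the structure of the compiled
#' growth dataset: ~121 observations, dozens of numeric predictors (log-normal
#' concentration-like variables plus uniform temperature-like temporal
#' variables carrying AR(1) daily series), a data-origin categorical encoded
#' as blocking dummies, a nitrogen-source categorical, sparse linear signal
#' with pairwise interactions, per-origin block offsets, and bounded
#' missingness applied completely at random.
#'
#' @param n_obs Number of observations (default 121).
#' @param n_numeric_predictors Total numeric predictors (default 40),
#'   `n_temporal` of which carry daily series.
#' @param n_temporal Temporal predictors (default 4); each contributes its
#'   day-of-harvest value plus 2/3/4-day averages to the design.
#' @param n_origin_groups Data-origin categories (default 4, >= 2).
#' @param n_source_levels Nitrogen-source categories (default 3).
#' @param true_terms List of `list(term = <name or pair>, coef = <numeric>)`.
#'   Defaults to 5 mains (4 concentration-like, 1 temporal) and 2 pairwise
#'   interactions among true mains.
#' @param block_offsets Additive response shift per origin group.
#' @param noise_sd Gaussian response noise SD (default 0.25).
#' @param missing_prob Per-cell missingness probability for predictors
#'   (default 0.15, MCAR).
#' @param bound_halfwidth Relative half-width of the bound interval around
#'   the true value behind each missing cell (default 0.2, absolute floor
#'   0.05).
#' @param response_name Response variable name (must end in `_pctFA`,
#'   `_ratioC16` or `_pctAFDW`).
#' @param seed Integer seed.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_obs = 121,
                              n_numeric_predictors = 40,
                              n_temporal = 4,
                              n_origin_groups = 4,
                              n_source_levels = 3,
                              true_terms = NULL,
                              block_offsets = NULL,
                              noise_sd = 0.25,
                              missing_prob = 0.15,
                              bound_halfwidth = 0.2,
                              response_name = "EPA_pctFA",
                              seed = 1L) {
  stopifnot(n_obs >= 2, n_numeric_predictors > n_temporal, n_temporal >= 0,
            n_origin_groups >= 2, n_source_levels >= 2,
            missing_prob >= 0, missing_prob < 1, noise_sd > 0,
            bound_halfwidth >= 0)
  n_plain <- n_numeric_predictors - n_temporal
  plain <- sprintf("x%02d", seq_len(n_plain))
  tvars <- if (n_temporal > 0) sprintf("tv%d", seq_len(n_temporal)) else character()
  if (is.null(true_terms)) {
    true_terms <- list(
      list(term = "x01", coef = 1.5),
      list(term = "x02", coef = -1.2),
      list(term = "x03", coef = 1.0),
      list(term = "x04", coef = 0.8),
      list(term = if (n_temporal > 0) "tv1" else "x05",
           coef = if (n_temporal > 0) 0.12 else 1.0),
      list(term = c("x01", "x03"), coef = 0.8),
      list(term = c("x02", "x04"), coef = -0.8)
    )
  }
  known <- c(plain, tvars)
  for (tt in true_terms) {
    bad <- setdiff(tt$term, known)
    if (length(bad)) {
      stop("true term references absent predictor(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(block_offsets)) {
    block_offsets <- c(0, 0.8, -0.5, 0.4, rep(0, max(0, n_origin_groups - 4)))
  }
  block_offsets <- rep_len(block_offsets, n_origin_groups)
  structure(list(n_obs = n_obs, n_plain = n_plain, n_temporal = n_temporal,
                 plain = plain, tvars = tvars,
                 n_origin_groups = n_origin_groups,
                 n_source_levels = n_source_levels,
                 true_terms = true_terms, block_offsets = block_offsets,
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 bound_halfwidth = bound_halfwidth,
                 response_name = response_name, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate a synthetic study with known ground truth
#'
#' Draws a complete dataset from the design, computes the response as the sum
#' of true-term contributions plus the origin block offset and Gaussian
#' noise, then masks predictor cells completely at random and builds a bound
#' interval around every masked true value
#' (`true value +/- max(bound_halfwidth * |true|, 0.05)`), so the truth is
#' guaranteed to lie inside every bound.
#'
#' @param design A [simulation_design()].
#' @return List: `dataset` ([mi_dataset()] with missingness applied), `meta`,
#'   `bounds` ([bounds_table()]), `truth` (true term list with coefficients,
#'   the pre-missingness value and series tables, per-masked-cell true
#'   values, origin assignment and block offsets).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_local_seed(design$seed, generate_study_impl(design))
}

generate_study_impl <- function(design) {
  n <- design$n_obs
  obs <- sprintf("obs%03d", seq_len(n))
  collection_day <- sample(7:12, n, replace = TRUE)

  vals <- data.frame(row.names = obs)
  for (v in design$plain) vals[[v]] <- rlnorm(n, meanlog = 0, sdlog = 0.5)

  # temporal variables: AR(1) (rho = 0.8) daily wander around a
  # per-observation level, so harvest-day values and k-day averages are
  # strongly collinear as in the real data
  rho <- 0.8; sigma_d <- 1.5
  series <- list(); harvest <- list()
  for (v in design$tvars) {
    level <- runif(n, 10, 30)
    hvals <- numeric(n)
    for (i in seq_len(n)) {
      nd <- collection_day[i] + 1L
      e <- rnorm(nd, 0, sigma_d)
      x <- numeric(nd)
      x[1] <- level[i] + e[1]
      for (t in 2:nd) {
        x[t] <- level[i] + rho * (x[t - 1] - level[i]) + sqrt(1 - rho^2) * e[t]
      }
      series[[length(series) + 1L]] <- data.frame(
        observation = obs[i], variable = v, day = 0:(nd - 1L), value = x)
      hvals[i] <- x[nd]
    }
    harvest[[v]] <- hvals
  }
  series <- if (length(series)) do.call(rbind, series) else NULL

  origin <- sample(sprintf("G%d", seq_len(design$n_origin_groups)), n,
                   replace = TRUE)
  nsource <- sample(c("NO3", "Urea", "NH4")[seq_len(min(3, design$n_source_levels))],
                    n, replace = TRUE)

  term_value <- function(nm) {
    if (nm %in% design$plain) vals[[nm]] else harvest[[nm]]
  }
  signal <- rep(0, n)
  for (tt in design$true_terms) {
    contrib <- Reduce(`*`, lapply(tt$term, term_value))
    signal <- signal + tt$coef * contrib
  }
  offsets <- design$block_offsets[match(origin, sprintf("G%d", seq_len(design$n_origin_groups)))]
  y <- signal + offsets + rnorm(n, 0, design$noise_sd)
  vals[[design$response_name]] <- y
  vals$Origin <- origin
  vals$Nsource <- nsource

  meta <- data.frame(
    name = c(design$plain, design$tvars, design$response_name,
             "Origin", "Nsource"),
    role = c(rep("predictor", design$n_plain + design$n_temporal),
             "response", "categorical_raw", "categorical_raw"),
    kind = c(rep("numeric", design$n_plain + design$n_temporal + 1),
             "categorical", "categorical"),
    units = "", temporal = c(rep(FALSE, design$n_plain),
                             rep(TRUE, design$n_temporal), FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  ds <- mi_dataset(cbind(data.frame(observation = obs), vals), meta,
                   series = series, collection_day = setNames(collection_day, obs))
  ds <- one_hot_encode(ds, "Origin", reference_level = "G1",
                       role = "blocking_dummy")
  ds <- one_hot_encode(ds, "Nsource", reference_level = "auto",
                       role = "predictor")

  truth_values <- ds$values
  truth_series <- ds$series

  # MCAR masking of predictor cells; bounds around the masked truth
  bnd <- list(); cells <- list()
  hw <- design$bound_halfwidth
  interval <- function(v) {
    h <- max(hw * abs(v), 0.05)
    c(v - h, v + h)
  }
  if (design$missing_prob > 0) {
    for (v in design$plain) {
      hit <- which(runif(n) < design$missing_prob)
      for (i in hit) {
        tv <- ds$values[[v]][i]
        iv <- interval(tv)
        bnd[[length(bnd) + 1L]] <- data.frame(
          observation = obs[i], variable = v, day = NA_integer_,
          lower = iv[1], upper = iv[2])
        cells[[length(cells) + 1L]] <- data.frame(
          observation = obs[i], variable = v, day = NA_integer_, value = tv)
        ds$values[[v]][i] <- NA_real_
      }
    }
    if (!is.null(ds$series) && nrow(ds$series)) {
      hit <- which(runif(nrow(ds$series)) < design$missing_prob)
      for (r in hit) {
        tv <- ds$series$value[r]
        iv <- interval(tv)
        bnd[[length(bnd) + 1L]] <- data.frame(
          observation = ds$series$observation[r],
          variable = ds$series$variable[r],
          day = ds$series$day[r], lower = iv[1], upper = iv[2])
        cells[[length(cells) + 1L]] <- data.frame(
          observation = ds$series$observation[r],
          variable = ds$series$variable[r],
          day = ds$series$day[r], value = tv)
        ds$series$value[r] <- NA_real_
      }
    }
  }
  bounds <- bounds_table(if (length(bnd)) do.call(rbind, bnd) else
    data.frame(observation = character(), variable = character(),
               day = integer(), lower = numeric(), upper = numeric()))
  masked <- if (length(cells)) do.call(rbind, cells) else
    data.frame(observation = character(), variable = character(),
               day = integer(), value = numeric())

  truth <- list(true_terms = design$true_terms,
                truth_values = truth_values,
                truth_series = truth_series,
                masked_cells = masked,
                origin = origin,
                block_offsets = design$block_offsets,
                response = design$response_name)
  list(dataset = ds, meta = ds$meta, bounds = bounds, truth = truth)
}

#' Ion composition of an f/2-style seawater growth medium
#'
#' Returns a medium composition record accepted by
#' [carbonate_equilibrium()]: the six major sea-salt ions of standard
#' seawater scaled linearly to the requested salinity, plus f/2 nutrient
#' loads (nitrate and phosphate) that do not scale with salinity.
#'
#' @param temperature_C Temperature, degrees Celsius (0-45 exclusive).
#' @param salinity_ppt Salinity in parts per thousand (>= 0; 0 gives pure
#'   water plus nutrients).
#' @param pCO2_atm CO2 partial pressure, atm (>= 0).
#' @return List of molar concentrations (`Na`, `Cl`, `Mg`, `Ca`, `K`,
#'   `SO4`, `NO3`, `PO4`) plus `salinity`, `temperature_C`, `pCO2_atm`.
#' @export
generate_chem_fixture <- function(temperature_C, salinity_ppt, pCO2_atm) {
  stopifnot(temperature_C > 0, temperature_C < 45, salinity_ppt >= 0,
            pCO2_atm >= 0)
  s <- salinity_ppt / 35
  # standard seawater major ions at S = 35, mol/L
  ref <- c(Na = 0.46906, Cl = 0.54586, Mg = 0.05282, Ca = 0.01028,
           K = 0.01021, SO4 = 0.02824)
  out <- as.list(ref * s)
  out$NO3 <- 8.82e-4   # f/2 nitrate
  out$PO4 <- 3.62e-5   # f/2 phosphate
  out$salinity <- salinity_ppt
  out$temperature_C <- temperature_C
  out$pCO2_atm <- pCO2_atm
  out
}
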