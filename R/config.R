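#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters used across the pipeline as a
#' nested list. Every entry can be overridden either programmatically
#' (`modifyList`) or through a YAML file read with [read_config()].
#'
#' Blocks:
#' \describe{
#'   \item{lasso}{`tol` (coordinate-descent convergence on max coefficient
#'     change, default `1e-7`), `max_iter` (default `1e5`), `n_lambda`
#'     (path length, default 100), `lambda_min_ratio` (smallest/largest
#'     penalty, default `1e-3`), `folds` (cross-validation folds, default 10).}
#'   \item{stepwise}{`penter` (p-value to add a term, default 0.05),
#'     `premove` (p-value to drop a term, default 0.10), `max_steps`
#'     (default 500).}
#'   \item{imputation}{`m` (number of imputations, default 10).}
#'   \item{pooling}{`retain` (trimmed-mean retained fraction, default 0.8).}
#'   \item{chem}{`nitrate_poly` (coefficients `c0`, `c1`, `c2`, `c11` of the
#'     nitrate-consumption model in mg N per litre; see [nitrate_bounds()]),
#'     `ph_residual` (intercept and dN/dP/vvm coefficients of the pH residual
#'     model on the proton-activity scale), `proton_floor` (lower clamp on
#'     corrected proton activity, default `1e-12`).}
#' }
#'
#' @return Nested named list of defaults.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$lasso$folds
default_config <- function() {
  list(
    lasso = list(
      tol = 1e-7,
      max_iter = 1e5,
      n_lambda = 100L,
      lambda_min_ratio = 1e-3,
      folds = 10L
    ),
    stepwise = list(
      penter = 0.05,
      premove = 0.10,
      max_steps = 500L
    ),
    imputation = list(m = 10L),
    pooling = list(retain = 0.8),
    chem = list(
      # default nitrate model: consumption = c1 * dX (+ c2 * N0 + c11 * dX^2)
      # with dX in g AFDW / L and N0 in mg N / L; c1 ~ biomass N quota of
      # ~6% w/w => 60 mg N per g biomass.
      nitrate_poly = list(c0 = 0, c1 = 60, c2 = 0, c11 = 0),
      ph_residual = list(intercept = 0, dN = 0, dP = 0, vvm = 0),
      proton_floor = 1e-12
    )
  )
}

#' Read a configuration file
#'
#' Reads a YAML key-value file and merges it over [default_config()], so a
#' file needs to state only the values it changes.
#'
#' @param path Path to a YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}
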