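#' AFDW bounds from a dry-weight measurement
#'
#' Dry weight (DW) overstates ash-free dry weight (AFDW) by the ash fraction.
#' Assuming between 1% and 20% ash content gives
#' `lower = 0.80 * dw`, `upper = 0.99 * dw`.
#'
#' @param dw Dry weight, g L^-1 (strictly positive).
#' @return Named vector `c(lower, upper)` in g AFDW L^-1.
#' @export
#' @examples
#' afdw_bounds_from_dw(1.0) # 0.80, 0.99
afdw_bounds_from_dw <- function(dw) {
  if (any(!is.finite(dw)) || any(dw <= 0)) {
    stop("dry weight must be positive", call. = FALSE)
  }
  c(lower = 0.80 * dw, upper = 0.99 * dw)
}

# average weight of a single cell used for the lower biomass ramp, grams
.cell_weight_floor <- 10e-12 # 10 pg

#' Per-day biomass bounds from a cell-density series
#'
#' When only a cell-count profile plus the final biomass concentration are
#' known, the biomass trajectory is bracketed by two per-cell-weight
#' assumptions: the lower series ramps the single-cell weight linearly from
#' 10 pg at the start to the final per-cell weight (final biomass / final
#' count); the upper series holds the final per-cell weight constant.
#'
#' @param cell_density_series Numeric vector, cells L^-1 per day.
#' @param final_biomass Final biomass concentration, g AFDW L^-1.
#' @return List `lower`, `upper`: numeric vectors (g AFDW L^-1) aligned with
#'   the input series. If the final per-cell weight falls below 10 pg the two
#'   assumptions cross; bounds are swapped day-wise with a warning.
#' @export
biomass_bounds_from_cells <- function(cell_density_series, final_biomass) {
  n <- length(cell_density_series)
  stopifnot(n >= 1, all(cell_density_series > 0), final_biomass > 0)
  w_final <- final_biomass / cell_density_series[n]
  frac <- if (n == 1) 1 else (seq_len(n) - 1) / (n - 1)
  w_ramp <- .cell_weight_floor + (w_final - .cell_weight_floor) * frac
  w_ramp[n] <- w_final # exact endpoint, immune to rounding in the ramp
  lower <- cell_density_series * w_ramp
  upper <- cell_density_series * w_final
  if (w_final < .cell_weight_floor) {
    warning("final per-cell weight below 10 pg; swapping bounds",
            call. = FALSE)
  }
  list(lower = pmin(lower, upper), upper = pmax(lower, upper))
}

eval_nitrate_poly <- function(coefs, dX, n0) {
  coefs$c0 + coefs$c1 * dX + coefs$c2 * n0 + coefs$c11 * dX^2
}

#' Per-day nitrate concentration bounds from biomass trajectories
#'
#' Nitrate consumption is predicted by a second-order polynomial in the
#' biomass concentration change and the initial nitrate concentration
#' (`consumption = c0 + c1 * dX + c2 * N0 + c11 * dX^2`, coefficients
#' supplied through the configuration; see [default_config()]). The lower
#' nitrate bound uses the upper biomass trajectory and vice versa; values
#' are clamped to `[0, initial_no3]` and negative predicted consumption is
#' clamped to zero.
#'
#' @param initial_no3 Initial nitrate, mg N L^-1.
#' @param biomass_bounds List `lower`, `upper`: biomass concentration
#'   (g AFDW L^-1) per day; the change is taken from the first element.
#' @param consumption_model Coefficient list `c0`, `c1`, `c2`, `c11`.
#' @return List `lower`, `upper`: nitrate (mg N L^-1) per day.
#' @export
nitrate_bounds <- function(initial_no3, biomass_bounds,
                           consumption_model = default_config()$chem$nitrate_poly) {
  stopifnot(initial_no3 >= 0)
  dX_up <- biomass_bounds$upper - biomass_bounds$upper[1]
  dX_lo <- biomass_bounds$lower - biomass_bounds$lower[1]
  cons_up <- pmax(0, eval_nitrate_poly(consumption_model, dX_up, initial_no3))
  cons_lo <- pmax(0, eval_nitrate_poly(consumption_model, dX_lo, initial_no3))
  lower <- pmin(pmax(initial_no3 - cons_up, 0), initial_no3)
  upper <- pmin(pmax(initial_no3 - cons_lo, 0), initial_no3)
  swap <- lower > upper
  if (any(swap)) { tmp <- lower[swap]; lower[swap] <- upper[swap]; upper[swap] <- tmp }
  list(lower = lower, upper = upper)
}

#' Phosphate concentration bounds from biomass change
#'
#' Bracketed by two biomass phosphorus contents: 2.5% (luxury uptake) with
#' the upper biomass change for the lower phosphate limit, 0.5% with the
#' lower biomass change for the upper limit.
#'
#' @param initial_p Initial phosphate, mg P L^-1.
#' @param biomass_change_bounds Named vector or list with `lower`, `upper`
#'   biomass concentration change, g AFDW L^-1.
#' @return Named vector `c(lower, upper)`, mg P L^-1 (clamped at 0,
#'   `lower <= upper` enforced).
#' @export
#' @examples
#' phosphate_bounds(20, list(lower = 0.2, upper = 0.4)) # 10, 19
phosphate_bounds <- function(initial_p, biomass_change_bounds) {
  stopifnot(initial_p >= 0, biomass_change_bounds$lower >= 0,
            biomass_change_bounds$upper >= 0)
  lower <- max(0, initial_p - 0.025 * biomass_change_bounds$upper * 1000)
  upper <- max(0, initial_p - 0.005 * biomass_change_bounds$lower * 1000)
  if (lower > upper) lower <- upper
  c(lower = lower, upper = upper)
}

#' Temperature- and salinity-dependent carbonate equilibrium constants
#'
#' Henry's constant for CO2 after Weiss (1974); first and second carbonic
#' acid dissociation constants after Millero et al. (2006), whose fits cover
#' salinity 0-50 and reduce to the freshwater limits at S = 0; water
#' ionization after Millero's seawater formulation.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param salinity Practical salinity (~ g salt per kg).
#' @return List `KH` (mol L^-1 atm^-1), `K1`, `K2`, `Kw`.
#' @export
carbonate_constants <- function(temperature_C, salinity = 0) {
  stopifnot(temperature_C > 0, temperature_C < 45, salinity >= 0)
  TK <- temperature_C + 273.15
  S <- salinity
  lnKH <- -58.0931 + 90.5069 * (100 / TK) + 22.2940 * log(TK / 100) +
    S * (0.027766 - 0.025888 * (TK / 100) + 0.0050578 * (TK / 100)^2)
  pK1_0 <- -126.34048 + 6320.813 / TK + 19.568224 * log(TK)
  pK1 <- pK1_0 + (13.4191 * sqrt(S) + 0.0331 * S - 5.33e-5 * S^2) +
    (-530.123 * sqrt(S) - 6.103 * S) / TK + (-2.06950 * sqrt(S)) * log(TK)
  pK2_0 <- -90.18333 + 5143.692 / TK + 14.613358 * log(TK)
  pK2 <- pK2_0 + (21.0894 * sqrt(S) + 0.1248 * S - 3.687e-4 * S^2) +
    (-772.483 * sqrt(S) - 20.051 * S) / TK + (-3.3336 * sqrt(S)) * log(TK)
  lnKw <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
    (-5.977 + 118.67 / TK + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S
  list(KH = exp(lnKH), K1 = 10^-pK1, K2 = 10^-pK2, Kw = exp(lnKw))
}

medium_charge <- function(medium) {
  g <- function(nm) if (is.null(medium[[nm]])) 0 else medium[[nm]]
  g("Na") + g("K") + 2 * g("Mg") + 2 * g("Ca") + g("NH4") -
    g("Cl") - 2 * g("SO4") - g("NO3") - g("PO4")
}

#' Equilibrium carbonate speciation and pH of a growth medium
#'
#' Solves the proton condition / charge balance of the open carbonate system
#' at a fixed CO2 partial pressure:
#' `[H+] + Z - [OH-] - [HCO3-] - 2[CO3^2-] = 0`, with
#' `[CO2(aq)] = KH * pCO2`, `[HCO3-] = K1 [CO2(aq)] / [H+]`,
#' `[CO3^2-] = K2 [HCO3-] / [H+]`, and `Z` the net strong-ion charge of the
#' medium (Na + K + 2 Mg + 2 Ca + NH4 - Cl - 2 SO4 - NO3 - PO4, eq L^-1).
#' The left side is strictly increasing in `[H+]`, so the root is unique; a
#' bracketing root-find on pH in [2, 12] is polished by Newton steps on
#' `[H+]` down to machine-level charge-balance residual.
#'
#' @param medium Composition record: list with molar ion concentrations
#'   (`Na`, `K`, `Mg`, `Ca`, `Cl`, `SO4`, `NO3`, `PO4`, `NH4`; absent ions
#'   count as zero) and `salinity`. See [generate_chem_fixture()].
#' @param temperature_C Temperature, degrees Celsius (0-45 exclusive).
#' @param pCO2_atm CO2 partial pressure in the gas feed, atm.
#' @return Object of class `carbonate_state`: `pH`, `CO2aq`, `HCO3`, `CO3`,
#'   `DIC` (all mol L^-1), `constants`, `charge_residual` (eq L^-1).
#' @export
#' @examples
#' pure <- generate_chem_fixture(25, 0, 10^-3.5)
#' carbonate_equilibrium(pure, 25, 10^-3.5)$pH # about 5.6
carbonate_equilibrium <- function(medium, temperature_C, pCO2_atm) {
  stopifnot(pCO2_atm >= 0)
  S <- if (is.null(medium$salinity)) 0 else medium$salinity
  k <- carbonate_constants(temperature_C, S)
  co2 <- k$KH * pCO2_atm
  Z <- medium_charge(medium)
  a <- k$K1 * co2          # HCO3 * H
  b <- k$K1 * k$K2 * co2   # CO3 * H^2
  f <- function(H) H + Z - k$Kw / H - a / H - 2 * b / H^2
  fH <- function(pH) f(10^(-pH))
  lo <- 2; hi <- 12
  if (fH(lo) * fH(hi) > 0) {
    stop(sprintf(paste0("no charge-balance root in pH [2, 12]: ",
                        "f(2) = %.3e, f(12) = %.3e, Z = %.3e eq/L"),
                 fH(lo), fH(hi), Z), call. = FALSE)
  }
  root <- uniroot(fH, c(lo, hi), tol = 1e-12)
  H <- 10^(-root$root)
  # Newton polish on [H+]: f is smooth and strictly increasing
  for (it in 1:50) {
    fv <- f(H)
    if (abs(fv) < 1e-15) break
    fp <- 1 + k$Kw / H^2 + a / H^2 + 4 * b / H^3
    H <- H - fv / fp
  }
  hco3 <- a / H
  co3 <- b / H^2
  structure(list(pH = -log10(H), CO2aq = co2, HCO3 = hco3, CO3 = co3,
                 DIC = co2 + hco3 + co3, constants = k,
                 charge_residual = f(H)),
            class = "carbonate_state")
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf("carbonate_state: pH %.3f, DIC %.4g mol/L (CO2aq %.3g, HCO3 %.3g, CO3 %.3g)\n",
              x$pH, x$DIC, x$CO2aq, x$HCO3, x$CO3))
  invisible(x)
}

#' Correct an equilibrium pH with the residual model
#'
#' The equilibrium solver ignores biological proton fluxes; the correction
#' adds a modelled residual on the proton-activity scale
#' (`r = 10^(-real pH) - 10^(-equilibrium pH)` during fitting):
#' `corrected pH = -log10(10^(-equilibrium_ph) + r)`.
#'
#' @param equilibrium_ph Equilibrium pH (0-14 exclusive).
#' @param dN Nitrate consumed to date, mol L^-1.
#' @param dP Phosphate consumed to date, mol L^-1.
#' @param vvm Aeration rate, volumes per volume per minute.
#' @param model Coefficient list `intercept`, `dN`, `dP`, `vvm` (see
#'   [fit_ph_residual_model()] / [default_config()]).
#' @param proton_floor Lower clamp on the corrected proton activity; a
#'   non-positive corrected activity is clamped here with a warning.
#' @return Corrected pH.
#' @export
estimate_ph_with_residual <- function(equilibrium_ph, dN, dP, vvm, model,
                                      proton_floor = 1e-12) {
  stopifnot(equilibrium_ph > 0, equilibrium_ph < 14)
  r <- model$intercept + model$dN * dN + model$dP * dP + model$vvm * vvm
  if (!is.finite(r)) stop("non-finite residual prediction", call. = FALSE)
  act <- 10^(-equilibrium_ph) + r
  if (act <= 0) {
    warning("corrected proton activity non-positive; clamped at floor",
            call. = FALSE)
    act <- proton_floor
  }
  -log10(act)
}

#' Fit the pH residual model
#'
#' Least-squares fit of proton-activity residuals
#' (`10^(-real pH) - 10^(-equilibrium pH)`) on nitrate consumption, phosphate
#' consumption and aeration rate. Intended for observations aerated with
#' ambient air, where the equilibrium assumption is closest.
#'
#' @param observations Data frame with columns `real_ph`, `equilibrium_ph`,
#'   `dN`, `dP`, `vvm`; at least 5 complete rows.
#' @return List `model` (coefficients `intercept`, `dN`, `dP`, `vvm`) and
#'   `r_squared`.
#' @export
fit_ph_residual_model <- function(observations) {
  req <- c("real_ph", "equilibrium_ph", "dN", "dP", "vvm")
  stopifnot(all(req %in% names(observations)))
  obs <- observations[complete.cases(observations[, req]), , drop = FALSE]
  if (nrow(obs) < 5) stop("need at least 5 observations with known real pH",
                          call. = FALSE)
  resid <- 10^(-obs$real_ph) - 10^(-obs$equilibrium_ph)
  fit <- lm(resid ~ dN + dP + vvm, data = obs)
  if (anyNA(coef(fit))) stop("rank-deficient residual-model design",
                             call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((resid - mean(resid))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  cf <- coef(fit)
  list(model = list(intercept = unname(cf[1]), dN = unname(cf["dN"]),
                    dP = unname(cf["dP"]), vvm = unname(cf["vvm"])),
       r_squared = r2)
}

#' Light-availability bounds from an assumed vessel geometry
#'
#' For a cylindrical vessel of unknown diameter illuminated from one side,
#' the light availability (surface intensity times illuminated surface over
#' working volume) reduces to `2 * I0 / d`, so a diameter range `[d_lo,
#' d_hi]` brackets it. No ray tracing: surface intensity and the
#' illuminated-surface-to-volume ratio are the only geometry inputs.
#'
#' @param surface_intensity Incident intensity, umol photons m^-2 s^-1.
#' @param diameter_range Assumed diameter range in metres (default 5-10 cm).
#' @param working_volume Working volume, L (validated positive; cancels in
#'   the cylindrical one-side formula).
#' @return Named vector `c(lower, upper)`, umol photons m^-3 s^-1.
#' @export
illumination_bounds <- function(surface_intensity,
                                diameter_range = c(0.05, 0.10),
                                working_volume = 1) {
  stopifnot(surface_intensity >= 0, all(diameter_range > 0),
            working_volume > 0)
  d <- sort(diameter_range)
  c(lower = 2 * surface_intensity / d[2],
    upper = 2 * surface_intensity / d[1])
}
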