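#' First-order irreversible inactivation rate from a time course
#'
#' Fits `ln(Act_t / Act_0) = -k_in * t` by zero-intercept least squares
#' (the model forces the log fraction through the origin), giving the
#' closed form `k_in = -sum(t * ln f) / sum(t^2)`.  A free-intercept
#' diagnostic fit is reported alongside.  Non-positive residual
#' fractions cannot be log-transformed and are dropped with a warning.
#'
#' @param time_min numeric vector of incubation times (min), including 0.
#' @param fraction numeric vector of residual activity fractions
#'   (activity at time t over activity at time 0).
#' @return An object of class `inactivation_fit`: `k_in_per_min`,
#'   `r_squared` (about the forced-origin line), `free_fit` (intercept
#'   and slope of the diagnostic fit), `n_used`, `data`, `activation`
#'   (TRUE when the estimated rate is negative, i.e. activity rose).
#' @examples
#' t <- c(0, 60, 120, 240, 360)
#' fit_inactivation_rate(t, exp(-0.05 * t))$k_in_per_min  # 0.05
#' @export
fit_inactivation_rate <- function(time_min, fraction) {
  stopifnot(is.numeric(time_min), is.numeric(fraction),
            length(time_min) == length(fraction))
  keep <- fraction > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive fraction(s) dropped before the log fit")
    time_min <- time_min[keep]; fraction <- fraction[keep]
  }
  if (length(time_min) == 0L) stop("no decay data: all fractions non-positive")
  if (length(time_min) < 3L) stop("no decay data: need at least 3 usable time points")
  y <- log(fraction)
  k <- -sum(time_min * y) / sum(time_min^2)
  ss_tot <- sum(y^2)  # about the model's forced origin
  r2 <- if (ss_tot > 0) 1 - sum((y + k * time_min)^2) / ss_tot else 1
  free <- stats::lm(y ~ time_min)
  out <- list(k_in_per_min = k, r_squared = r2,
              free_fit = c(intercept = unname(stats::coef(free)[1L]),
                           slope = unname(stats::coef(free)[2L])),
              n_used = length(time_min),
              data = data.frame(time_min = time_min, fraction = fraction),
              activation = k < 0)
  if (out$activation)
    warning("activation, not inactivation: residual activity increases with time")
  class(out) <- "inactivation_fit"
  out
}

#' @export
print.inactivation_fit <- function(x, digits = 4, ...) {
  cat("First-order inactivation fit (", x$n_used, " points)\n", sep = "")
  cat("  k_in = ", format(x$k_in_per_min, digits = digits),
      " min-1,  r2 = ", format(x$r_squared, digits = digits), "\n", sep = "")
  if (x$activation) cat("  (negative rate: activity rises with time)\n")
  invisible(x)
}

#' Half-life and decimal reduction time of a first-order decay
#'
#' `t_half = ln 2 / k_in` and `D = ln 10 / k_in` (the time for a 10-fold
#' activity drop).  Their ratio `D / t_half = ln 10 / ln 2 ~ 3.32` is a
#' fixed property of first-order kinetics and is used by the consistency
#' checker to vet published tables.
#'
#' @param k_in_per_min first-order inactivation rate constant (min-1).
#' @return list with `t_half_min` and `D_min`.
#' @examples
#' half_life_and_D(log(2))   # t_half = 1 min
#' half_life_and_D(0.0162)   # t_half ~ 42.79, D ~ 142.13
#' @export
half_life_and_D <- function(k_in_per_min) {
  if (any(k_in_per_min <= 0)) stop("no decay: k_in must be positive")
  list(t_half_min = log(2) / k_in_per_min, D_min = log(10) / k_in_per_min)
}

#' Thermodynamic state functions of irreversible inactivation
#'
#' `dG = -R T ln(k_in * h / (kB * T))` (Eyring form, see
#' [eyring_free_energy()] for the `rate_unit_mode` convention),
#' `dH = Ea - R T`, `dS = (dH - dG) / T` (signed, with magnitude).
#'
#' @param k_in_per_min inactivation rate constant (min-1).
#' @param Ea_kJ_mol inactivation energy barrier (kJ/mol).
#' @param temperature_K absolute temperature (K).
#' @param rate_unit_mode `"per_second"` (k_in converted to s-1 before
#'   the Eyring expression) or `"per_minute"` (per-minute numeral used
#'   as-is; reproduces tables computed that way).
#' @return list with `dG_kJ_mol`, `dH_kJ_mol`, `dS_J_mol_K`,
#'   `dS_abs_J_mol_K`.
#' @examples
#' inactivation_state_functions(0.0162, 59.29, 313.15,
#'                              rate_unit_mode = "per_minute")
#' @export
inactivation_state_functions <- function(k_in_per_min, Ea_kJ_mol, temperature_K,
                                         rate_unit_mode = c("per_second", "per_minute")) {
  rate_unit_mode <- match.arg(rate_unit_mode)
  if (any(k_in_per_min <= 0)) stop("invalid rate: k_in must be positive")
  rate <- switch(rate_unit_mode,
                 per_second = k_in_per_min / 60,
                 per_minute = k_in_per_min)
  dG <- eyring_free_energy(rate, temperature_K, rate_unit_mode)$dG_kJ_mol
  sf <- activation_state_functions(Ea_kJ_mol, dG, temperature_K)
  list(dG_kJ_mol = dG, dH_kJ_mol = sf$dH_kJ_mol,
       dS_J_mol_K = sf$dS_J_mol_K, dS_abs_J_mol_K = sf$dS_abs_J_mol_K)
}

#' End-to-end irreversible thermal-inactivation profile
#'
#' Consolidates a panel of residual-activity time courses at several
#' temperatures into one record: per-temperature `k_in`, half-life and
#' D-value, the Arrhenius inactivation energy `Ea#` across temperatures,
#' and the per-temperature state functions `dG#`, `dH#`, `dS#`.
#' Temperatures whose time course cannot be fitted are dropped with a
#' warning and the rest are still analysed.
#'
#' @param panel a list of time courses, each a list/data frame with
#'   elements `temperature_C` (scalar), `time_min`, `fraction`;
#'   or a long data frame with those three columns.
#' @inheritParams inactivation_state_functions
#' @return An object of class `inactivation_thermo`: `table` (one row
#'   per temperature with `temperature_C`, `k_in_per_min`, `t_half_min`,
#'   `D_min`, `dG_kJ_mol`, `dH_kJ_mol`, `dS_J_mol_K`, `dS_abs_J_mol_K`,
#'   `r_squared`), `Ea_kJ_mol`, `arrhenius` (the underlying
#'   [fit_arrhenius()] object), `rate_unit_mode`, `dropped`.
#' @examples
#' panel <- simulate_inactivation_panel(sd = 0, seed = 1)
#' inactivation_profile(panel)
#' @export
inactivation_profile <- function(panel,
                                 rate_unit_mode = c("per_second", "per_minute")) {
  rate_unit_mode <- match.arg(rate_unit_mode)
  if (is.data.frame(panel)) {
    stopifnot(all(c("temperature_C", "time_min", "fraction") %in% names(panel)))
    panel <- lapply(split(panel, panel$temperature_C), function(d)
      list(temperature_C = d$temperature_C[1L], time_min = d$time_min,
           fraction = d$fraction))
  }
  temps <- vapply(panel, function(p) p$temperature_C, numeric(1))
  fits <- lapply(panel, function(p)
    tryCatch(fit_inactivation_rate(p$time_min, p$fraction),
             error = function(e) NULL))
  usable <- !vapply(fits, is.null, logical(1))
  dropped <- temps[!usable]
  if (length(dropped))
    warning("unusable time course(s) at ", paste(dropped, collapse = ", "),
            " degC dropped from the profile")
  temps <- temps[usable]; fits <- fits[usable]
  if (length(temps) < 3L) stop("insufficient data: need at least 3 usable temperatures")
  k <- unname(vapply(fits, `[[`, numeric(1), "k_in_per_min"))
  Tk <- celsius_to_kelvin(unname(temps))
  arr <- fit_arrhenius(Tk, k)
  hd <- half_life_and_D(k)
  sf <- inactivation_state_functions(k, arr$Ea_kJ_mol, Tk, rate_unit_mode)
  tab <- data.frame(row.names = NULL, temperature_C = unname(temps),
                    k_in_per_min = k,
                    t_half_min = hd$t_half_min,
                    D_min = hd$D_min,
                    dG_kJ_mol = sf$dG_kJ_mol,
                    dH_kJ_mol = sf$dH_kJ_mol,
                    dS_J_mol_K = sf$dS_J_mol_K,
                    dS_abs_J_mol_K = sf$dS_abs_J_mol_K,
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  out <- list(table = tab, Ea_kJ_mol = arr$Ea_kJ_mol, arrhenius = arr,
              rate_unit_mode = rate_unit_mode, dropped = dropped)
  class(out) <- "inactivation_thermo"
  out
}

#' @export
print.inactivation_thermo <- function(x, digits = 4, ...) {
  cat("Irreversible thermal inactivation (",
      nrow(x$table), " temperatures, Eyring rate unit: ",
      x$rate_unit_mode, ")\n", sep = "")
  cat("  Ea# = ", format(x$Ea_kJ_mol, digits = digits), " kJ/mol\n", sep = "")
  print(format(x$table, digits = digits))
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "degC\n")
  invisible(x)
}
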