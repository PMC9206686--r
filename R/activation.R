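#' Arrhenius fit: activation energy from rate constants
#'
#' Ordinary least squares of `ln k` on `1/T`.  The slope `alpha` equals
#' `-Ea/R`, so `Ea = -alpha * R`; the pre-exponential factor is
#' `A = exp(intercept)` in the unit of the supplied rates.  Used both
#' for the catalytic activation energy (ascending limb of the
#' temperature-activity profile) and, with inactivation rate constants,
#' for the inactivation energy barrier.
#'
#' @param temperature_K numeric vector of absolute temperatures (K);
#'   at least 3 (exactly 2 gives the two-point closed form, flagged by
#'   `r_squared = 1`).
#' @param rate numeric vector of positive rate constants.
#' @return An object of class `arrhenius_fit`: `Ea_kJ_mol`, `A`,
#'   `slope_K` (alpha, in Kelvin), `intercept`, `r_squared`, `n`,
#'   `data`.
#' @examples
#' Tk <- seq(300, 320, 5)
#' k <- 1e8 * exp(-50e3 / (8.314 * Tk))
#' fit_arrhenius(Tk, k)$Ea_kJ_mol  # 50
#' @export
fit_arrhenius <- function(temperature_K, rate) {
  stopifnot(is.numeric(temperature_K), is.numeric(rate),
            length(temperature_K) == length(rate))
  if (any(rate <= 0)) stop("log undefined: all rates must be positive")
  if (length(temperature_K) < 2L) stop("insufficient data: need at least 2 temperatures")
  if (length(temperature_K) < 3L)
    warning("only 2 temperatures: slope is the exact two-point form, no error estimate")
  x <- 1 / temperature_K
  y <- log(rate)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((y - mean(y))^2)
  out <- list(Ea_kJ_mol = -slope * physical_constants$R / 1000,
              A = exp(intercept),
              slope_K = slope, intercept = intercept,
              r_squared = if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1,
              n = length(rate),
              data = data.frame(temperature_K = temperature_K, rate = rate))
  class(out) <- "arrhenius_fit"
  out
}

#' @export
print.arrhenius_fit <- function(x, digits = 4, ...) {
  cat("Arrhenius fit (", x$n, " temperatures)\n", sep = "")
  cat("  Ea = ", format(x$Ea_kJ_mol, digits = digits), " kJ/mol,  A = ",
      format(x$A, digits = digits), ",  r2 = ",
      format(x$r_squared, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...)
  c(Ea_kJ_mol = object$Ea_kJ_mol, A = object$A)

#' @export
predict.arrhenius_fit <- function(object, newdata = NULL, ...) {
  Tk <- if (is.null(newdata)) object$data$temperature_K else
    if (is.data.frame(newdata)) newdata$temperature_K else newdata
  object$A * exp(-object$Ea_kJ_mol * 1000 / (physical_constants$R * Tk))
}

#' Eyring reduced rate and free energy of activation
#'
#' Computes the dimensionless reduced rate `k' = k * h / (kB * T)` and
#' the Gibbs free energy of activation `dG = -R T ln k'` (kJ/mol) from a
#' first-order rate constant.
#'
#' `rate_unit_mode` declares the unit the numeric rate is expressed in.
#' In the standard `"per_second"` mode a rate given per minute should be
#' divided by 60 by the caller (or see `rate_per_minute`); the
#' `"per_minute"` mode feeds the per-minute numeral directly to the
#' reduced-rate expression, a published-table compatibility convention
#' (it reproduces tabulated inactivation dG values computed that way).
#'
#' @param rate rate constant (kcat or k_in), in the declared unit.
#' @param temperature_K absolute temperature (K).
#' @param rate_unit_mode `"per_second"` (standard) or `"per_minute"`
#'   (compatibility; uses the numeral as-is).
#' @return list with `reduced_rate` (dimensionless) and `dG_kJ_mol`.
#' @examples
#' with(physical_constants, eyring_free_energy(kB * 313.15 / h, 313.15))$dG_kJ_mol # 0
#' eyring_free_energy(0.10430, 313.15)$dG_kJ_mol  # ~82.7
#' @export
eyring_free_energy <- function(rate, temperature_K,
                               rate_unit_mode = c("per_second", "per_minute")) {
  rate_unit_mode <- match.arg(rate_unit_mode)
  if (any(rate <= 0)) stop("invalid rate: must be positive")
  stopifnot(all(temperature_K > 0))
  kr <- rate * physical_constants$h / (physical_constants$kB * temperature_K)
  dG <- -physical_constants$R * temperature_K * log(kr) / 1000
  list(reduced_rate = kr, dG_kJ_mol = dG, rate_unit_mode = rate_unit_mode)
}

#' Activation enthalpy and entropy from Ea and dG
#'
#' `dH = Ea - R T` and `dS = (dH - dG) / T`.  The entropy is returned
#' signed together with its magnitude (`dS_abs`), since published tables
#' sometimes print the magnitude only.  The identity
#' `dG = dH - T dS` holds exactly by construction.
#'
#' @param Ea_kJ_mol Arrhenius activation energy (kJ/mol).
#' @param dG_kJ_mol Gibbs free energy of activation (kJ/mol).
#' @param temperature_K absolute temperature (K).
#' @return list with `dH_kJ_mol`, `dS_J_mol_K` (signed),
#'   `dS_abs_J_mol_K`.
#' @examples
#' activation_state_functions(25.36, 58.60, 313.15)
#' @export
activation_state_functions <- function(Ea_kJ_mol, dG_kJ_mol, temperature_K) {
  stopifnot(all(temperature_K > 0))
  dH <- Ea_kJ_mol - physical_constants$R * temperature_K / 1000
  dS <- (dH - dG_kJ_mol) * 1000 / temperature_K
  list(dH_kJ_mol = dH, dS_J_mol_K = dS, dS_abs_J_mol_K = abs(dS))
}

#' Free energies of substrate binding and transition-state formation
#'
#' `dG(E-S) = -R T ln Ka` with `Ka = 1/Km`, and
#' `dG(E-T) = -R T ln(kcat/Km)`.  The thermodynamically standard choice
#' expresses Km in molar units; `km_unit_mode = "mM"` keeps Km in mM, a
#' compatibility convention under which some published tables report the
#' enzyme-substrate term (the two differ by `R T ln 1000`).
#'
#' @param Km Michaelis constant, in the declared unit mode.
#' @param kcat_over_Km catalytic efficiency (M-1 s-1).
#' @param temperature_K absolute temperature (K).
#' @param km_unit_mode `"M"` (standard) or `"mM"` (compatibility).
#' @return list with `Ka` (1/Km in the declared unit), `dG_ES_kJ_mol`
#'   (signed), `dG_ES_abs_kJ_mol`, `dG_ET_kJ_mol`.
#' @examples
#' substrate_binding_energies(0.46, 226.73, 313.15, km_unit_mode = "mM")
#' @export
substrate_binding_energies <- function(Km, kcat_over_Km, temperature_K,
                                       km_unit_mode = c("M", "mM")) {
  km_unit_mode <- match.arg(km_unit_mode)
  if (Km <= 0 || kcat_over_Km <= 0) stop("log undefined: inputs must be positive")
  RT <- physical_constants$R * temperature_K / 1000
  Ka <- 1 / Km
  dG_ES <- -RT * log(Ka)
  dG_ET <- -RT * log(kcat_over_Km)
  list(Ka = Ka, dG_ES_kJ_mol = dG_ES, dG_ES_abs_kJ_mol = abs(dG_ES),
       dG_ET_kJ_mol = dG_ET, km_unit_mode = km_unit_mode)
}

#' Full activation-thermodynamics record for a catalytic rate
#'
#' Chains the Arrhenius activation energy, Eyring free energy, state
#' functions and binding energies into one record at a reference
#' temperature.  When a published `dG_override_kJ_mol` is supplied the
#' entropy is computed from it instead of the Eyring-derived value
#' (useful when a tabulated dG is not reproducible from the tabulated
#' rate; both values are kept in the record).
#'
#' @param Ea_kJ_mol catalytic activation energy (kJ/mol), e.g. from
#'   [fit_arrhenius()] on the ascending limb of the activity profile.
#' @param kcat turnover number, in the declared rate unit.
#' @param Km Michaelis constant (declared unit mode).
#' @param kcat_over_Km catalytic efficiency (M-1 s-1).
#' @param temperature_K reference temperature (K).
#' @param dG_override_kJ_mol optional externally supplied dG (kJ/mol).
#' @inheritParams eyring_free_energy
#' @inheritParams substrate_binding_energies
#' @return An object of class `activation_thermo` collecting every
#'   parameter: `Ea`, `reduced_rate`, `dG`, `dG_eyring`, `dH`, `dS`
#'   (signed and `dS_abs`), `dG_ES`, `dG_ET`, `Ka`, `temperature_K`.
#' @examples
#' activation_thermo(Ea_kJ_mol = 25.36, kcat = 0.10430, Km = 0.46,
#'                   kcat_over_Km = 226.73, temperature_K = 313.15,
#'                   km_unit_mode = "mM", dG_override_kJ_mol = 58.60)
#' @export
activation_thermo <- function(Ea_kJ_mol, kcat, Km, kcat_over_Km,
                              temperature_K,
                              rate_unit_mode = c("per_second", "per_minute"),
                              km_unit_mode = c("M", "mM"),
                              dG_override_kJ_mol = NULL) {
  rate_unit_mode <- match.arg(rate_unit_mode)
  km_unit_mode <- match.arg(km_unit_mode)
  ey <- eyring_free_energy(kcat, temperature_K, rate_unit_mode)
  dG <- if (is.null(dG_override_kJ_mol)) ey$dG_kJ_mol else dG_override_kJ_mol
  sf <- activation_state_functions(Ea_kJ_mol, dG, temperature_K)
  be <- substrate_binding_energies(Km, kcat_over_Km, temperature_K, km_unit_mode)
  out <- list(Ea_kJ_mol = Ea_kJ_mol, kcat = kcat,
              reduced_rate = ey$reduced_rate,
              dG_kJ_mol = dG, dG_eyring_kJ_mol = ey$dG_kJ_mol,
              dG_overridden = !is.null(dG_override_kJ_mol),
              dH_kJ_mol = sf$dH_kJ_mol,
              dS_J_mol_K = sf$dS_J_mol_K, dS_abs_J_mol_K = sf$dS_abs_J_mol_K,
              Ka = be$Ka, dG_ES_kJ_mol = be$dG_ES_kJ_mol,
              dG_ES_abs_kJ_mol = be$dG_ES_abs_kJ_mol,
              dG_ET_kJ_mol = be$dG_ET_kJ_mol,
              temperature_K = temperature_K,
              rate_unit_mode = rate_unit_mode, km_unit_mode = km_unit_mode)
  class(out) <- "activation_thermo"
  out
}

#' @export
print.activation_thermo <- function(x, digits = 4, ...) {
  cat("Activation thermodynamics at ", x$temperature_K, " K\n", sep = "")
  cat("  Ea      = ", format(x$Ea_kJ_mol, digits = digits), " kJ/mol\n", sep = "")
  cat("  dG      = ", format(x$dG_kJ_mol, digits = digits), " kJ/mol",
      if (x$dG_overridden) paste0(" (override; Eyring value ",
                                  format(x$dG_eyring_kJ_mol, digits = digits), ")"),
      "\n", sep = "")
  cat("  dH      = ", format(x$dH_kJ_mol, digits = digits), " kJ/mol\n", sep = "")
  cat("  dS      = ", format(x$dS_J_mol_K, digits = digits), " J/mol/K (|dS| = ",
      format(x$dS_abs_J_mol_K, digits = digits), ")\n", sep = "")
  cat("  dG(E-S) = ", format(x$dG_ES_kJ_mol, digits = digits),
      " kJ/mol (Km in ", x$km_unit_mode, ", Ka = ",
      format(x$Ka, digits = digits), ")\n", sep = "")
  cat("  dG(E-T) = ", format(x$dG_ET_kJ_mol, digits = digits), " kJ/mol\n", sep = "")
  invisible(x)
}
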