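# Published CelC307 reference values (endoglucanase from Cohnella sp.
# A01, GH5).  These are the printed characterization tables that the
# package's estimators reproduce or, where a printed value is not
# reproducible from its own printed inputs, that the consistency
# checker flags.

#' Published CelC307 Michaelis-Menten parameters
#'
#' Km 0.46 mM, Vmax 62.58 U/mg, kcat 0.10430 s-1, kcat/Km 226.73
#' M-1 s-1, assayed on 1% CMC at 40 degC, pH 7.
#'
#' @return a one-row data frame.
#' @examples celc307_kinetics()
#' @export
celc307_kinetics <- function() {
  data.frame(Km_mM = 0.46, Vmax_U_mg = 62.58, kcat_per_s = 0.10430,
             kcat_over_Km_M_s = 226.73, temperature_C = 40, pH = 7)
}

#' Published CelC307 activation-thermodynamics table
#'
#' The tabulated transition-state parameters at 40 degC: Ea 25.36,
#' dG 58.60, dH 22.75 kJ/mol, |dS| 114.51 J/mol/K, dG(E-T) -14.11,
#' dG(E-S) 2.01 kJ/mol, Ka 2.17 (1/Km, mM-1).
#'
#' @return a named list.
#' @examples celc307_activation_table()
#' @export
celc307_activation_table <- function() {
  list(Ea_kJ_mol = 25.36, dG_kJ_mol = 58.60, dH_kJ_mol = 22.75,
       dS_abs_J_mol_K = 114.51, dG_ET_kJ_mol = -14.11,
       dG_ES_kJ_mol = 2.01, Ka_per_mM = 2.17, temperature_C = 40)
}

#' Published CelC307 irreversible thermal-inactivation table
#'
#' Per-temperature inactivation rate constants and the tabulated
#' half-life, D-value, Ea#, dH#, dG# and |dS#| columns.  Note that the
#' printed t_half and D columns are not internally consistent with the
#' printed k_in (see [celc307_consistency()]).
#'
#' @return a data frame, one row per temperature.
#' @examples celc307_inactivation_table()
#' @export
celc307_inactivation_table <- function() {
  data.frame(
    temperature_C = c(40, 60, 70, 80, 90),
    k_in_per_min  = c(1.62e-2, 14.60e-2, 29.70e-2, 41.68e-2, 56.67e-2),
    t_half_min    = c(427.86, 47.47, 25.76, 16.63, 12.23),
    D_min         = c(1606.34, 189.62, 96.01, 70.41, 53.25),
    Ea_kJ_mol     = c(59.29, NA, NA, NA, NA),
    dH_kJ_mol     = c(56.69, 56.52, 56.44, 56.43, 56.27),
    dG_kJ_mol     = c(87.58, 87.08, 87.67, 89.24, 90.83),
    dS_abs_J_mol_K = c(98.72, 91.76, 91.05, 93.05, 95.20))
}

#' The 20-run response-surface design and measured activities
#'
#' The printed expression-optimization experiment for CelC307: a
#' rotatable central composite in pH (A), temperature (B, degC) and
#' inoculum concentration (C, OD600), with the measured and the
#' originally reported predicted cellulase activities (U/ml).  The
#' block split (factorial runs with center runs 3, 5, 9, 12; axial runs
#' with center runs 16, 17) is inferred from the two distinct
#' center-point predicted values.
#'
#' @return a data frame with columns `run`, `pH`, `temperature`,
#'   `inoculum_od`, `activity`, `predicted`, `block`.
#' @examples celc307_rsm_runs()
#' @export
celc307_rsm_runs <- function() {
  d <- data.frame(
    run = 1:20,
    pH = c(5, 8, 6.5, 5, 6.5, 5, 8, 8, 6.5, 5, 8, 6.5,
           6.5, 9.02, 3.97, 6.5, 6.5, 6.5, 6.5, 6.5),
    temperature = c(20, 40, 30, 40, 30, 40, 20, 20, 30, 20, 40, 30,
                    13.18, 30, 30, 30, 30, 30, 46.81, 30),
    inoculum_od = c(0.3, 1, 0.65, 0.3, 0.65, 1, 0.3, 1, 0.65, 1, 0.3, 0.65,
                    0.65, 0.65, 0.65, 0.65, 0.65, 0.06, 0.65, 1.23),
    activity = c(47, 49.3, 49, 46.2, 51.4, 47.6, 48.5, 56.1, 51.9, 52.1,
                 46.4, 50.6, 52.86, 49, 48.7, 51.7, 52.4, 45.1, 47.5, 53),
    predicted = c(46.9, 49.10, 51.01, 46.51, 51.01, 47.84, 47.96, 55.50,
                  51.01, 52.44, 45.76, 51.01, 53.23, 50.02, 48.07, 51.44,
                  51.44, 45.52, 47.52, 52.98))
  d$block <- factor(ifelse(d$run %in% 13:20, 2L, 1L))
  d
}

#' Factor specifications of the CelC307 response-surface design
#'
#' pH 6.5 +/- 1.5, temperature 30 +/- 10 degC, inoculum OD600
#' 0.65 +/- 0.35; the coded axial levels at +/- 1.682 reproduce the
#' printed extreme runs (pH 3.97/9.02, 13.18/46.81 degC, OD 0.06/1.23).
#'
#' @return list of three [factor_spec()] objects.
#' @examples celc307_rsm_factors()
#' @export
celc307_rsm_factors <- function() {
  list(factor_spec("pH", 6.5, 1.5, "A"),
       factor_spec("temperature", 30, 10, "B"),
       factor_spec("inoculum_od", 0.65, 0.35, "C"))
}

#' Published CelC307 second-order polynomial coefficients
#'
#' The reported natural-unit regression for cellulase activity (U/ml)
#' as a function of pH (A), temperature (B, degC) and inoculum OD600
#' (C).
#'
#' @return named numeric vector in [fit_response_surface()] layout.
#' @examples celc307_quadratic_coefficients()
#' @export
celc307_quadratic_coefficients <- function() {
  c(intercept = 20.04144, A = 5.56251, B = 0.44628, C = 17.38737,
    AB = -0.030000, AC = 0.95238, BC = -0.30000,
    A2 = -0.37659, B2 = -3.77106e-3, C2 = -6.33976)
}

#' Published CelC307 Plackett-Burman screening factors
#'
#' The seven culture-condition factors screened at two levels each.
#'
#' @return a data frame with columns `factor`, `low`, `high`.
#' @examples celc307_pb_factors()
#' @export
celc307_pb_factors <- function() {
  data.frame(
    factor = c("pH", "temperature", "rotation_rpm", "inoculum_od",
               "induction_time_h", "yeast_extract_g_l", "tryptone_g_l"),
    low  = c(3, 20, 70, 0.3, 4, 2.5, 7.5),
    high = c(8, 40, 200, 1, 18, 7.5, 12.5))
}

#' Published CelC307 substrate-specificity panel
#'
#' Relative activities (percent of the CMC maximum) on the assayed
#' polysaccharide substrates, mean +/- sd of triplicates.
#'
#' @return a data frame with columns `substrate`, `relative_percent`, `sd`.
#' @examples celc307_substrate_panel()
#' @export
celc307_substrate_panel <- function() {
  data.frame(substrate = c("CMC", "laminarin", "chitin", "pectic acid", "pustulan"),
             relative_percent = c(100, 21.6, 8.4, 1.9, NA),
             sd = c(3.3, 2.4, 1.3, 0.6, NA))
}
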