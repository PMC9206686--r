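# Shared table readers with schema validation, plus the end-to-end
# characterization report.

.dialects <- list(
  calibration  = c("concentration_umol", "absorbance"),
  profile      = c("condition", "activity"),
  kinetics     = c("substrate", "velocity"),
  inhibition   = c("inhibitor_conc", "substrate", "velocity"),
  inactivation = c("temperature_C", "time_min", "residual_fraction"),
  doe          = c("response")
)

#' Read a validated assay table
#'
#' Reads one of the package's CSV dialects with schema checking:
#' missing required columns raise a schema error naming the column, and
#' non-numeric cells in required numeric columns raise a parse error
#' with the offending row.  UTF-8 byte-order marks and CRLF line
#' endings are handled transparently.
#'
#' Dialects and their required columns:
#' `calibration` (concentration_umol, absorbance), `profile`
#' (condition, activity), `kinetics` (substrate, velocity),
#' `inhibition` (inhibitor_conc, substrate, velocity), `inactivation`
#' (temperature_C, time_min, residual_fraction), `doe` (one column per
#' factor plus `response`, optional `block`).
#'
#' @param path path to a CSV file.
#' @param dialect one of the dialect names above.
#' @return a data frame with the validated columns coerced to numeric
#'   (except `condition`, which may be character, and `block`).
#' @export
read_assay_table <- function(path, dialect = names(.dialects)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, fileEncoding = "UTF-8-BOM",
                       stringsAsFactors = FALSE, strip.white = TRUE)
  required <- .dialects[[dialect]]
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("schema error: missing column '", missing[1L], "' for dialect '",
         dialect, "'")
  numeric_cols <- setdiff(required, "condition")
  for (col in numeric_cols) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "")
      if (length(bad))
        stop("parse error: non-numeric value '", v[bad[1L]], "' in column '",
             col, "', row ", bad[1L])
      d[[col]] <- coerced
    }
  }
  d
}

#' Run the characterization pipeline on a set of inputs
#'
#' Executes the requested stages independently and collects their
#' results, warnings and errors into a single report: one stage's
#' failure never aborts the others.  Recognized stage names and their
#' expected inputs:
#'
#' * `mm`: a kinetics data frame (`substrate`, `velocity`);
#' * `inhibition`: an inhibition-series data frame;
#' * `inactivation`: a panel accepted by [inactivation_profile()];
#' * `rsm`: list with `design` (3 natural factor columns), `response`,
#'   optional `block`;
#' * `seqprops`: a protein string, or a named list with `dna`
#'   (translated first);
#' * `activation`: list of arguments for [activation_thermo()].
#'
#' @param config named list of stage inputs; names select the stages.
#' @return An object of class `characterization_report`: `results`
#'   (named list of stage outputs), `errors`, `warnings`, `stages`.
#' @examples
#' rep <- run_characterization(list(
#'   mm = simulate_mm_dataset(sd_frac = 0, reps = 1, seed = 1)))
#' names(rep$results)
#' @export
run_characterization <- function(config) {
  stopifnot(is.list(config))
  if (length(config) == 0L) stop("nothing to do: empty configuration")
  known <- c("mm", "inhibition", "inactivation", "rsm", "seqprops", "activation")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  results <- list(); errors <- list(); warns <- character(0)
  run_stage <- function(name, fun) {
    withCallingHandlers(
      tryCatch(results[[name]] <<- fun(),
               error = function(e) errors[[name]] <<- conditionMessage(e)),
      warning = function(w) {
        warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  for (name in names(config)) {
    input <- config[[name]]
    run_stage(name, switch(name,
      mm = function() fit_michaelis_menten(input),
      inhibition = function() classify_inhibition_mode(fit_inhibition_series(input)),
      inactivation = function() inactivation_profile(input),
      rsm = function() fit_response_surface(input$design, input$response,
                                            block = input$block),
      seqprops = function() {
        prot <- if (is.list(input) && !is.null(input$dna))
          translate_dna(input$dna) else input
        protein_properties(prot)
      },
      activation = function() do.call(activation_thermo, input)))
  }
  out <- list(results = results, errors = errors, warnings = warns,
              stages = names(config))
  class(out) <- "characterization_report"
  out
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Characterization report: ", length(x$stages), " stage(s)\n", sep = "")
  for (s in x$stages) {
    status <- if (!is.null(x$results[[s]])) "ok"
    else paste("FAILED:", x$errors[[s]])
    cat("  ", s, ": ", status, "\n", sep = "")
  }
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a characterization report to JSON
#'
#' Losslessly round-trips the report's numeric content (full double
#' precision); reports can be compared with
#' [report_from_json()] after a disk round trip.
#'
#' @param report a `characterization_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "characterization_report"))
  strip <- function(x) {
    if (inherits(x, "lm")) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  payload <- list(stages = report$stages,
                  results = lapply(report$results, function(r) strip(unclass(r))),
                  errors = report$errors, warnings = report$warnings)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @param json a JSON string or path produced by [report_to_json()].
#' @export
report_from_json <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE)
}

#' Consistency check of a published parameter table
#'
#' Recomputes derivable quantities from their own printed inputs and
#' flags rows whose printed value disagrees beyond `rel_tol`:
#'
#' * half-life vs `ln 2 / k_in` and D-value vs `ln 10 / k_in`
#'   (first-order identities);
#' * the `D / t_half` ratio vs `ln 10 / ln 2`;
#' * the Arrhenius activation energy vs an OLS refit of the printed
#'   per-temperature rate constants;
#' * the Eyring free energy vs the printed rate constant;
#' * `dH = Ea - R T` and `dS = (dH - dG)/T`.
#'
#' @param kinetics one-row data frame as [celc307_kinetics()].
#' @param activation named list as [celc307_activation_table()].
#' @param inactivation data frame as [celc307_inactivation_table()].
#' @param rel_tol relative tolerance above which a row is flagged.
#' @return An object of class `consistency_report`: a data frame with
#'   columns `quantity`, `printed`, `recomputed`, `rel_diff`,
#'   `consistent`.
#' @examples
#' celc307_consistency()
#' @export
celc307_consistency <- function(kinetics = celc307_kinetics(),
                                activation = celc307_activation_table(),
                                inactivation = celc307_inactivation_table(),
                                rel_tol = 0.02) {
  Tk <- celsius_to_kelvin(activation$temperature_C)
  rows <- list()
  add <- function(quantity, printed, recomputed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, printed = printed, recomputed = recomputed,
      rel_diff = abs(recomputed - printed) / max(abs(printed), .Machine$double.eps),
      stringsAsFactors = FALSE)
  }

  # catalytic efficiency and binding energies from printed kcat, Km
  add("kcat/Km (M-1 s-1)", kinetics$kcat_over_Km_M_s,
      kinetics$kcat_per_s / (kinetics$Km_mM * 1e-3))
  add("Ka = 1/Km (mM-1)", activation$Ka_per_mM, 1 / kinetics$Km_mM)
  add("dG (kJ/mol) from printed kcat", activation$dG_kJ_mol,
      eyring_free_energy(kinetics$kcat_per_s, Tk)$dG_kJ_mol)
  add("dH (kJ/mol) from printed Ea", activation$dH_kJ_mol,
      activation$Ea_kJ_mol - physical_constants$R * Tk / 1000)
  add("dG(E-T) (kJ/mol) from printed kcat/Km", activation$dG_ET_kJ_mol,
      -physical_constants$R * Tk * log(kinetics$kcat_over_Km_M_s) / 1000)

  # first-order identities on the inactivation table
  hd <- half_life_and_D(inactivation$k_in_per_min)
  for (i in seq_len(nrow(inactivation))) {
    add(sprintf("t_half at %g degC (min)", inactivation$temperature_C[i]),
        inactivation$t_half_min[i], hd$t_half_min[i])
    add(sprintf("D at %g degC (min)", inactivation$temperature_C[i]),
        inactivation$D_min[i], hd$D_min[i])
  }
  add("D / t_half ratio", inactivation$D_min[1] / inactivation$t_half_min[1],
      log(10) / log(2))

  # Arrhenius refit of the printed rate constants
  arr <- fit_arrhenius(celsius_to_kelvin(inactivation$temperature_C),
                       inactivation$k_in_per_min)
  add("Ea# (kJ/mol) from printed k_in", inactivation$Ea_kJ_mol[1], arr$Ea_kJ_mol)

  # inactivation state functions at the reference temperature
  sf <- inactivation_state_functions(inactivation$k_in_per_min[1],
                                     inactivation$Ea_kJ_mol[1],
                                     celsius_to_kelvin(inactivation$temperature_C[1]),
                                     rate_unit_mode = "per_minute")
  add("dG# at 40 degC (kJ/mol, per-minute mode)", inactivation$dG_kJ_mol[1],
      sf$dG_kJ_mol)
  add("dH# at 40 degC (kJ/mol)", inactivation$dH_kJ_mol[1], sf$dH_kJ_mol)

  tab <- do.call(rbind, rows)
  tab$consistent <- tab$rel_diff <= rel_tol
  out <- list(table = tab, rel_tol = rel_tol)
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, digits = 4, ...) {
  cat("Consistency check (relative tolerance ", x$rel_tol, ")\n", sep = "")
  tab <- x$table
  tab$printed <- signif(tab$printed, digits)
  tab$recomputed <- signif(tab$recomputed, digits)
  tab$rel_diff <- signif(tab$rel_diff, 3)
  print(tab, row.names = FALSE)
  n_bad <- sum(!x$table$consistent)
  cat(if (n_bad) paste0(n_bad, " inconsistent quantit",
                        if (n_bad > 1) "ies" else "y", " flagged\n")
      else "all quantities consistent\n")
  invisible(x)
}
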