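#' Fit a linear reducing-sugar calibration curve
#'
#' Ordinary least-squares fit of blank-corrected absorbance against the
#' amount of reducing sugar (micromoles) in a dinitrosalicylic-acid (DNS)
#' standard series.  The fitted line converts assay absorbances into
#' product amounts and hence enzyme activity units.
#'
#' @param concentration numeric vector of standard amounts (umol reducing
#'   sugar); at least 3 values, not all equal.
#' @param absorbance numeric vector of measured absorbances, same length.
#' @return An object of class `linear_calibration` with components
#'   `slope` (absorbance per umol), `intercept` (absorbance),
#'   `r_squared`, `n`, and the underlying `lm` fit (`model`).
#' @examples
#' cal <- fit_linear_calibration(0:5, 2 * (0:5) + 0.1)
#' cal$slope
#' @seealso [activity_units()]
#' @export
fit_linear_calibration <- function(concentration, absorbance) {
  stopifnot(is.numeric(concentration), is.numeric(absorbance),
            length(concentration) == length(absorbance))
  if (length(concentration) < 3L)
    stop("insufficient calibration: need at least 3 standard points")
  if (isTRUE(all.equal(stats::var(concentration), 0)) ||
      stats::var(concentration) == 0)
    stop("degenerate calibration: zero variance in concentration")
  fit <- stats::lm(absorbance ~ concentration)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = r2, n = length(concentration), model = fit)
  if (out$slope <= 0)
    warning("calibration slope is non-positive; check the standard series")
  class(out) <- "linear_calibration"
  out
}

#' @export
print.linear_calibration <- function(x, digits = 4, ...) {
  cat("Linear calibration (", x$n, " standards)\n", sep = "")
  cat("  absorbance = ", format(x$slope, digits = digits),
      " * umol + ", format(x$intercept, digits = digits), "\n", sep = "")
  cat("  r-squared  = ", format(x$r_squared, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Enzyme activity units from an assay absorbance
#'
#' Converts an endpoint absorbance into liberated reducing sugar via a
#' [fit_linear_calibration()] line and expresses the result as enzyme
#' units.  One unit (U) liberates one umol of reducing sugar per minute.
#' Specific activity (U/mg) and volumetric activity (U/ml) are derived
#' when the enzyme mass or reaction volume is supplied.
#'
#' Absorbances that fall below the calibration intercept would imply a
#' negative product amount; those are clamped to zero and flagged
#' (`clamped = TRUE`) with a warning, since a blank cannot consume sugar.
#'
#' @param absorbance measured absorbance (blank corrected).
#' @param calibration a `linear_calibration` object.
#' @param time_min reaction time in minutes (> 0).
#' @param enzyme_mg enzyme amount in mg (optional, for U/mg).
#' @param volume_ml reaction volume in ml (optional, for U/ml).
#' @return An object of class `activity_measurement`: `product_umol`,
#'   `time_min`, `units_U`, `specific_activity_U_mg`,
#'   `volumetric_activity_U_ml`, `clamped`.
#' @examples
#' cal <- fit_linear_calibration(0:5, 0:5)     # slope 1, intercept 0
#' activity_units(5, cal, time_min = 5, enzyme_mg = 1)
#' @export
activity_units <- function(absorbance, calibration, time_min,
                           enzyme_mg = NULL, volume_ml = NULL) {
  stopifnot(inherits(calibration, "linear_calibration"))
  if (!is.numeric(time_min) || time_min <= 0)
    stop("invalid duration: reaction time must be positive")
  product <- (absorbance - calibration$intercept) / calibration$slope
  clamped <- FALSE
  if (product < 0) {
    warning("absorbance below calibration intercept; product clamped to 0")
    product <- 0
    clamped <- TRUE
  }
  U <- product / time_min
  out <- list(product_umol = product,
              time_min = time_min,
              units_U = U,
              specific_activity_U_mg = if (!is.null(enzyme_mg)) U / enzyme_mg else NA_real_,
              volumetric_activity_U_ml = if (!is.null(volume_ml)) U / volume_ml else NA_real_,
              clamped = clamped)
  class(out) <- "activity_measurement"
  out
}

#' @export
print.activity_measurement <- function(x, digits = 4, ...) {
  cat("Activity: ", format(x$units_U, digits = digits), " U (",
      format(x$product_umol, digits = digits), " umol / ",
      x$time_min, " min)\n", sep = "")
  if (!is.na(x$specific_activity_U_mg))
    cat("  specific:   ", format(x$specific_activity_U_mg, digits = digits), " U/mg\n", sep = "")
  if (!is.na(x$volumetric_activity_U_ml))
    cat("  volumetric: ", format(x$volumetric_activity_U_ml, digits = digits), " U/ml\n", sep = "")
  if (x$clamped) cat("  (absorbance below blank; clamped)\n")
  invisible(x)
}

#' Normalize an activity profile to percent of maximum
#'
#' Scales a condition-versus-activity profile (temperature, pH or
#' substrate panel) so that the maximum activity maps to 100 percent and
#' every other activity is scaled proportionally.  Replicates of the same
#' condition are averaged first; their standard deviations are kept as
#' metadata (`sd_percent`).  Ties for the maximum resolve to the first
#' occurrence, so exactly one entry equals 100 after normalization.
#'
#' @param condition numeric or character vector of condition values
#'   (degrees C, pH units, substrate names, ...).
#' @param activity numeric vector of activities (any consistent unit).
#' @param profile_kind one of `"activity"`, `"survival"`, `"stability"`.
#' @return An object of class `activity_profile`: a data frame with
#'   columns `condition`, `relative_percent`, `sd_percent`, plus
#'   attributes `profile_kind` and `max_condition`.
#' @examples
#' relative_activity_profile(c(30, 40, 50), c(10, 20, 5))
#' @export
relative_activity_profile <- function(condition, activity,
                                      profile_kind = c("activity", "survival", "stability")) {
  profile_kind <- match.arg(profile_kind)
  stopifnot(length(condition) == length(activity), is.numeric(activity))
  agg_mean <- tapply(activity, factor(condition, levels = unique(condition)), mean)
  agg_sd   <- tapply(activity, factor(condition, levels = unique(condition)), stats::sd)
  if (all(agg_mean == 0)) stop("no activity to normalize: all activities are zero")
  if (any(agg_mean < 0)) warning("negative mean activities present before normalization")
  ref <- agg_mean[[which.max(agg_mean)]]
  out <- data.frame(condition = unique(condition),
                    relative_percent = as.numeric(agg_mean) / ref * 100,
                    sd_percent = as.numeric(agg_sd) / ref * 100,
                    stringsAsFactors = FALSE)
  attr(out, "profile_kind") <- profile_kind
  attr(out, "max_condition") <- out$condition[which.max(out$relative_percent)]
  class(out) <- c("activity_profile", "data.frame")
  out
}
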