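#' Fit Michaelis-Menten kinetics at each inhibitor concentration
#'
#' Independently fits the Michaelis-Menten model to the velocity data
#' collected at each inhibitor concentration (the control, `[I] = 0`,
#' must be present).  Results are ordered by increasing inhibitor
#' concentration.  A failure of any sub-fit does not abort the series:
#' the failing level is recorded and the downstream verdict becomes
#' `"indeterminate"`.
#'
#' @param series a data frame with columns `inhibitor_conc`, `substrate`
#'   and `velocity` (long format, one row per assay point).
#' @param inhibitor optional inhibitor name carried into the result.
#' @param ... passed to [fit_michaelis_menten()].
#' @return An object of class `inhibition_fits`: a list with `fits`
#'   (one `mm_fit` or `NULL` per level), `conc` (sorted inhibitor
#'   concentrations), `failed` (levels whose fit failed), `inhibitor`.
#' @examples
#' ser <- simulate_inhibition_series(mode = "competitive", sd_frac = 0, seed = 1)
#' fits <- fit_inhibition_series(ser)
#' sapply(fits$fits, coef)
#' @export
fit_inhibition_series <- function(series, inhibitor = attr(series, "inhibitor"), ...) {
  stopifnot(is.data.frame(series),
            all(c("inhibitor_conc", "substrate", "velocity") %in% names(series)))
  conc <- sort(unique(series$inhibitor_conc))
  if (!0 %in% conc) stop("no control: series must include inhibitor_conc = 0")
  if (length(conc) < 2L) stop("no inhibitor data: need at least one nonzero level")
  fits <- vector("list", length(conc))
  failed <- numeric(0)
  for (i in seq_along(conc)) {
    d <- series[series$inhibitor_conc == conc[i], ]
    fits[i] <- list(tryCatch(
      fit_michaelis_menten(d$substrate, d$velocity, ...),
      error = function(e) {
        warning("fit failed at [I] = ", conc[i], ": ", conditionMessage(e))
        NULL
      }))
    if (is.null(fits[[i]])) failed <- c(failed, conc[i])
  }
  out <- list(fits = fits, conc = conc, failed = failed,
              inhibitor = if (is.null(inhibitor)) NA_character_ else inhibitor)
  class(out) <- "inhibition_fits"
  out
}

#' @export
print.inhibition_fits <- function(x, digits = 4, ...) {
  cat("Inhibition series", if (!is.na(x$inhibitor)) paste0(" (", x$inhibitor, ")"),
      ": ", length(x$conc), " levels\n", sep = "")
  for (i in seq_along(x$conc)) {
    f <- x$fits[[i]]
    if (is.null(f)) {
      cat("  [I] = ", x$conc[i], ": fit failed\n", sep = "")
    } else {
      cat("  [I] = ", x$conc[i], ": Km = ", format(f$Km, digits = digits),
          ", Vmax = ", format(f$Vmax, digits = digits), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Lineweaver-Burk lines and their pairwise intersections
#'
#' Maps each Michaelis-Menten fit to its double-reciprocal line
#' `y = (Km/Vmax) x + 1/Vmax` and solves every pairwise intersection in
#' closed form.  Each intersection is labelled `"on y-axis"` when its x
#' coordinate is within `tol` of zero relative to the x spread of the
#' intersections/intercepts, `"on x-axis"` analogously for y, and
#' `"parallel"` when the relative slope difference is below `tol`
#' (parallel lines have no finite intersection).
#'
#' @param fits an `inhibition_fits` object or a list of `mm_fit`s.
#' @param tol relative tolerance for the axis/parallel labels.
#' @return An object of class `lb_geometry`: `lines` (data frame of
#'   slope/intercept per level) and `intersections` (data frame with
#'   `x`, `y`, `label` per pair).
#' @examples
#' f1 <- fit_michaelis_menten(c(1, 2, 4, 8), 50 * c(1, 2, 4, 8) / (2 + c(1, 2, 4, 8)))
#' f2 <- fit_michaelis_menten(c(1, 2, 4, 8), 25 * c(1, 2, 4, 8) / (2 + c(1, 2, 4, 8)))
#' lb_intersections(list(f1, f2))  # same Km: lines cross on the x-axis at -1/Km
#' @export
lb_intersections <- function(fits, tol = 0.02) {
  if (inherits(fits, "inhibition_fits")) {
    conc <- fits$conc[!vapply(fits$fits, is.null, logical(1))]
    fits <- Filter(Negate(is.null), fits$fits)
  } else {
    conc <- seq_along(fits)
  }
  if (length(fits) < 2L) stop("need at least 2 fits for intersections")
  slope <- vapply(fits, function(f) f$Km / f$Vmax, numeric(1))
  intercept <- vapply(fits, function(f) 1 / f$Vmax, numeric(1))
  lines <- data.frame(level = conc, slope = slope, intercept = intercept)
  pairs <- utils::combn(length(fits), 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    ds <- slope[i] - slope[j]
    if (abs(ds) < tol * max(abs(slope[i]), abs(slope[j]))) {
      return(c(NA_real_, NA_real_))
    }
    xs <- (intercept[j] - intercept[i]) / ds
    c(xs, slope[i] * xs + intercept[i])
  })
  x <- res[1, ]; y <- res[2, ]
  # scales: where the lines live in reciprocal space
  x_scale <- max(abs(c(x[is.finite(x)], -1 / vapply(fits, `[[`, numeric(1), "Km"))), na.rm = TRUE)
  y_scale <- max(abs(c(y[is.finite(y)], intercept)), na.rm = TRUE)
  label <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    if (!is.finite(x[k])) label[k] <- "parallel"
    else if (abs(x[k]) < tol * x_scale) label[k] <- "on y-axis"
    else if (abs(y[k]) < tol * y_scale) label[k] <- "on x-axis"
    else label[k] <- "off-axis"
  }
  out <- list(lines = lines,
              intersections = data.frame(level_i = conc[pairs[1, ]],
                                         level_j = conc[pairs[2, ]],
                                         x = x, y = y, label = label))
  class(out) <- "lb_geometry"
  out
}

#' @export
print.lb_geometry <- function(x, digits = 4, ...) {
  cat("Lineweaver-Burk geometry (", nrow(x$lines), " lines)\n", sep = "")
  print(format(x$intersections, digits = digits), ...)
  invisible(x)
}

#' Classify the mechanism of inhibition from Km/Vmax shifts
#'
#' Applies the classical rule table to the per-concentration
#' Michaelis-Menten parameters, relative to the uninhibited control:
#'
#' * `Vmax` reduced beyond `rel_tol` while `Km` unchanged: non-competitive;
#' * `Km` increased beyond `rel_tol` while `Vmax` unchanged: competitive;
#' * both reduced proportionally (double-reciprocal lines parallel,
#'   slope difference below `parallel_tol`): uncompetitive;
#' * both shifted beyond `rel_tol` non-proportionally: mixed;
#' * both within `rel_tol`: none.
#'
#' A parameter counts as shifted only when its relative change versus
#' the control exceeds both `rel_tol` (the minimum relevant effect) and
#' `z_se` times the shift's propagated standard error from the two
#' nonlinear fits; likewise the parallelism test widens `parallel_tol`
#' by the propagated uncertainty of the slope ratio (which uses the
#' Km-Vmax covariance of each fit).  Without the statistical guard, fit
#' noise in Km alone would routinely exceed a fixed percentage
#' threshold and masquerade as a mixed mechanism.
#'
#' The call uses the nonlinear-fit parameters (reciprocal-space
#' regression biases the classical plot); the Lineweaver-Burk geometry is
#' attached as corroborating evidence.  Shifts must act in a consistent
#' direction and grow (weakly) with inhibitor concentration; otherwise
#' the verdict is `"indeterminate"` with diagnostics.
#'
#' @param fits an `inhibition_fits` object (or a data frame accepted by
#'   [fit_inhibition_series()]).
#' @param rel_tol relative shift below which a parameter counts as
#'   unchanged (default 0.10).
#' @param parallel_tol relative slope difference below which
#'   double-reciprocal lines count as parallel (default 0.02).
#' @param z_se multiplier on the propagated standard error in the
#'   shifted/parallel decisions (default 2, a roughly 95 percent
#'   criterion).
#' @return An object of class `inhibition_verdict`: `mode`, `parameters`
#'   (data frame of Km/Vmax and shifts per level), `geometry`
#'   (`lb_geometry`), `rel_tol`, `parallel_tol`, `diagnostics`.
#' @examples
#' ser <- simulate_inhibition_series(mode = "noncompetitive", sd_frac = 0, seed = 1)
#' classify_inhibition_mode(ser)$mode  # "noncompetitive"
#' @export
classify_inhibition_mode <- function(fits, rel_tol = 0.10, parallel_tol = 0.02,
                                     z_se = 2) {
  if (is.data.frame(fits)) fits <- fit_inhibition_series(fits)
  stopifnot(inherits(fits, "inhibition_fits"))
  diag_msgs <- character(0)

  if (length(fits$failed)) {
    return(.verdict("indeterminate", fits, NULL, rel_tol, parallel_tol,
                    paste("sub-fit failed at [I] =",
                          paste(fits$failed, collapse = ", "))))
  }
  conc <- fits$conc
  Km <- vapply(fits$fits, `[[`, numeric(1), "Km")
  Vmax <- vapply(fits$fits, `[[`, numeric(1), "Vmax")
  ctrl <- which(conc == 0)
  dKm <- Km / Km[ctrl] - 1
  dV  <- Vmax / Vmax[ctrl] - 1

  # relative parameter uncertainties and the slope (Km/Vmax) cv using
  # the within-fit Km-Vmax covariance (delta method)
  cv <- function(f, par) {
    s <- f$se[[par]] / f[[par]]
    if (is.finite(s)) s else 0
  }
  cv_km <- vapply(fits$fits, cv, numeric(1), "Km")
  cv_v  <- vapply(fits$fits, cv, numeric(1), "Vmax")
  cv_sl <- vapply(fits$fits, function(f) {
    v <- cv(f, "Km")^2 + cv(f, "Vmax")^2 -
      2 * f$cov_Km_Vmax / (f$Km * f$Vmax)
    sqrt(max(v, 0))
  }, numeric(1))
  se_shift_km <- (1 + dKm) * sqrt(cv_km^2 + cv_km[ctrl]^2)
  se_shift_v  <- (1 + dV)  * sqrt(cv_v^2  + cv_v[ctrl]^2)

  params <- data.frame(inhibitor_conc = conc, Km = Km, Vmax = Vmax,
                       Km_shift = dKm, Vmax_shift = dV,
                       Km_shift_se = se_shift_km, Vmax_shift_se = se_shift_v)
  geom <- lb_intersections(fits, tol = parallel_tol)

  nz <- which(conc > 0)
  hi <- nz[which.max(conc[nz])]
  moved <- function(shift, se) abs(shift) > pmax(rel_tol, z_se * se)
  km_moved <- moved(dKm[hi], se_shift_km[hi])
  v_moved  <- moved(dV[hi], se_shift_v[hi])

  # monotone consistency: decisive shifts must keep their sign and not
  # shrink (beyond tolerance slack) as [I] grows
  mono <- function(shift, se, is_moved) {
    if (!is_moved || length(nz) < 2L) return(TRUE)
    o <- order(conc[nz])
    s <- shift[nz][o]; e <- se[nz][o]
    decisive <- abs(s) > pmax(rel_tol, z_se * e)
    all(sign(s[decisive]) == sign(shift[hi])) &&
      all(diff(abs(s)) > -pmax(rel_tol, z_se * e[-1L]))
  }
  if (!mono(dKm, se_shift_km, km_moved) || !mono(dV, se_shift_v, v_moved)) {
    return(.verdict("indeterminate", fits, geom, rel_tol, parallel_tol,
                    "non-monotone Km/Vmax shifts across inhibitor levels",
                    params))
  }

  # parallel double-reciprocal lines (slope = Km/Vmax preserved)
  slope_ratio <- (Km / Vmax) / (Km[ctrl] / Vmax[ctrl])
  se_ratio <- slope_ratio * sqrt(cv_sl^2 + cv_sl[ctrl]^2)
  par_ok <- all(abs(slope_ratio[nz] - 1) <
                  pmax(parallel_tol, z_se * se_ratio[nz]))

  mode <- if (!km_moved && !v_moved) "none"
  else if (v_moved && dV[hi] < 0 && !km_moved) "noncompetitive"
  else if (km_moved && dKm[hi] > 0 && !v_moved) "competitive"
  else if (km_moved && v_moved && dKm[hi] < 0 && dV[hi] < 0 && par_ok) "uncompetitive"
  else if (km_moved && v_moved) "mixed"
  else {
    diag_msgs <- c(diag_msgs, "shift pattern matches no canonical mechanism")
    "indeterminate"
  }
  .verdict(mode, fits, geom, rel_tol, parallel_tol,
           if (length(diag_msgs)) diag_msgs else NULL, params)
}

.verdict <- function(mode, fits, geom, rel_tol, parallel_tol,
                     diagnostics = NULL, params = NULL) {
  out <- list(mode = mode, inhibitor = fits$inhibitor, parameters = params,
              geometry = geom, rel_tol = rel_tol, parallel_tol = parallel_tol,
              diagnostics = diagnostics)
  class(out) <- "inhibition_verdict"
  out
}

#' @export
print.inhibition_verdict <- function(x, digits = 4, ...) {
  cat("Inhibition mode", if (!is.na(x$inhibitor)) paste0(" (", x$inhibitor, ")"),
      ": ", x$mode, "\n", sep = "")
  if (!is.null(x$parameters)) print(format(x$parameters, digits = digits))
  if (!is.null(x$diagnostics)) cat("  note:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}
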