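#' Fit the Michaelis-Menten model by nonlinear least squares
#'
#' Fits `v = Vmax * S / (Km + S)` to substrate-velocity data by
#' Levenberg-Marquardt nonlinear least squares.  Starting values are
#' `Vmax0 = max(v)` and `Km0 =` the substrate concentration at half-max
#' velocity (linearly interpolated), the classical heuristics.
#' Convergence requires a relative parameter change below 1e-8 within
#' 500 iterations.
#'
#' `weighting = "relative"` weights each residual by `1/v` (constant
#' relative error); the default `"uniform"` matches the usual
#' unweighted fit.
#'
#' @param substrate either a numeric vector of substrate concentrations,
#'   or a data frame with columns `substrate` and `velocity`.
#' @param velocity numeric vector of initial velocities (ignored when
#'   `substrate` is a data frame).
#' @param weighting `"uniform"` or `"relative"`.
#' @param substrate_unit,velocity_unit unit tags carried through to
#'   downstream conversions (e.g. `"mM"`, `"U/mg"`).
#' @return An object of class `mm_fit`: `Km`, `Vmax`, their standard
#'   errors (`se`, from the local quadratic approximation of the
#'   objective), `rss`, `fitted`, `residuals`, `data`, `units`,
#'   `convergence`.
#' @examples
#' S <- c(0.625, 1.25, 2.5, 5, 10, 20)
#' fit <- fit_michaelis_menten(S, 50 * S / (2 + S))
#' coef(fit)
#' @seealso [catalytic_constants()], [lineweaver_burk()]
#' @export
fit_michaelis_menten <- function(substrate, velocity = NULL,
                                 weighting = c("uniform", "relative"),
                                 substrate_unit = "mM", velocity_unit = "U/mg") {
  weighting <- match.arg(weighting)
  if (is.data.frame(substrate)) {
    d <- substrate
    stopifnot(all(c("substrate", "velocity") %in% names(d)))
    substrate <- d$substrate
    velocity <- d$velocity
  }
  stopifnot(is.numeric(substrate), is.numeric(velocity),
            length(substrate) == length(velocity))
  if (any(substrate <= 0)) stop("invalid kinetics: substrate concentrations must be positive")
  if (any(velocity < 0)) stop("invalid kinetics: velocities must be non-negative")
  if (length(unique(substrate)) < 4L)
    stop("insufficient data: need at least 4 distinct substrate concentrations")

  start <- .mm_start(substrate, velocity)
  w <- switch(weighting,
              uniform = rep(1, length(velocity)),
              relative = 1 / pmax(velocity, max(velocity) * 1e-6)^2)
  d <- data.frame(S = substrate, v = velocity)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = d,
                      start = start, weights = w,
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-8, ftol = 1e-12)),
    error = function(e) stop("fit failed: ", conditionMessage(e), call. = FALSE))

  est <- stats::coef(fit)
  if (any(!is.finite(est)) || est["Vmax"] <= 0)
    stop("invalid kinetics: non-positive parameter at optimum")
  km_floor <- min(substrate) * 1e-6
  if (est["Km"] <= km_floor)
    stop("invalid kinetics: Km collapsed to the zero boundary (velocity ~ constant in substrate)")

  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("Vmax", "Km"), c("Vmax", "Km"))))
  se <- sqrt(diag(vc))
  out <- list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
              se = c(Km = unname(se["Km"]), Vmax = unname(se["Vmax"])),
              cov_Km_Vmax = unname(vc["Km", "Vmax"]),
              rss = sum(stats::resid(fit)^2),
              fitted = stats::fitted(fit),
              residuals = stats::resid(fit),
              data = d,
              units = c(substrate = substrate_unit, velocity = velocity_unit),
              weighting = weighting,
              convergence = fit$convInfo$isConv,
              kcat = NA_real_, kcat_over_Km = NA_real_,
              Ka = 1 / unname(est["Km"]), Ki = 1 / unname(est["Km"]))
  class(out) <- "mm_fit"
  out
}

# Km start = substrate at half-maximal velocity, interpolated on the
# sorted data; falls back to the median substrate if v never crosses.
.mm_start <- function(S, v) {
  Vmax0 <- max(v)
  o <- order(S)
  Km0 <- tryCatch(stats::approx(v[o], S[o], xout = Vmax0 / 2, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(S)
  list(Vmax = Vmax0, Km = Km0)
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  if (is.null(x$data)) {
    cat("Michaelis-Menten parameters\n")
  } else {
    cat("Michaelis-Menten fit (", nrow(x$data), " points, ",
        x$weighting, " weighting)\n", sep = "")
  }
  se_txt <- function(par) {
    if (is.null(x$se) || !is.finite(x$se[[par]])) ""
    else paste0("  (se ", format(x$se[[par]], digits = 3), ")")
  }
  cat("  Km   = ", format(x$Km, digits = digits), " ", x$units[["substrate"]],
      se_txt("Km"), "\n", sep = "")
  if (is.finite(x$Vmax))
    cat("  Vmax = ", format(x$Vmax, digits = digits), " ", x$units[["velocity"]],
        se_txt("Vmax"), "\n", sep = "")
  if (is.finite(x$kcat))
    cat("  kcat = ", format(x$kcat, digits = digits), " s-1",
        if (is.finite(x$kcat_over_Km))
          paste0(", kcat/Km = ", format(x$kcat_over_Km, digits = digits), " M-1 s-1"),
        "\n", sep = "")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Km = object$Km, Vmax = object$Vmax)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    if (is.data.frame(newdata)) newdata$substrate else newdata
  object$Vmax * S / (object$Km + S)
}

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
summary.mm_fit <- function(object, ...) {
  n <- nrow(object$data)
  out <- list(fit = object, n = n, sigma = sqrt(object$rss / max(n - 2L, 1L)))
  class(out) <- "summary.mm_fit"
  out
}

#' @export
print.summary.mm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  residual sd = ", format(x$sigma, digits = digits),
      " on ", x$n - 2L, " df\n", sep = "")
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, n_curve = 200, ...) {
  S <- x$data$S
  grid <- seq(min(S), max(S), length.out = n_curve)
  plot(S, x$data$v, xlab = paste0("substrate (", x$units[["substrate"]], ")"),
       ylab = paste0("velocity (", x$units[["velocity"]], ")"),
       main = "Michaelis-Menten fit", ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Catalytic constants for a Michaelis-Menten fit
#'
#' Augments an `mm_fit` with the turnover number `kcat` (s-1) and the
#' catalytic efficiency `kcat/Km` (M-1 s-1), plus the association
#' constant `Ka = 1/Km` (and its alias `Ki` used by the
#' enzyme-substrate free-energy expression) in the reciprocal of the
#' substrate unit.
#'
#' `kcat` is taken as given when supplied; alternatively it is derived
#' from `Vmax` (U/mg, i.e. umol min-1 mg-1) and the enzyme molar mass:
#' `kcat = Vmax * MW(kDa) / 60` s-1 (kDa = mg/umol).  `kcat/Km` requires `Km` in
#' a molar-convertible unit (`mM` or `M`); for mass-per-volume units the
#' efficiency is omitted with a warning.
#'
#' @param fit an `mm_fit`, or a single numeric Km (with `km_unit`).
#' @param kcat turnover number in s-1 (optional).
#' @param mw_kDa enzyme molar mass in kDa (optional, to derive kcat).
#' @param km_unit unit of Km when `fit` is numeric (`"mM"` or `"M"`).
#' @return The `mm_fit` (or a minimal list when `fit` was numeric) with
#'   `kcat`, `kcat_over_Km`, `Ka`, `Ki` filled in.
#' @examples
#' cc <- catalytic_constants(0.46, kcat = 0.10430, km_unit = "mM")
#' cc$kcat_over_Km  # ~ 226.7 M-1 s-1
#' cc$Ka            # 2.17 mM-1
#' @export
catalytic_constants <- function(fit, kcat = NULL, mw_kDa = NULL, km_unit = NULL) {
  if (is.numeric(fit) && length(fit) == 1L) {
    fit <- list(Km = fit, Vmax = NA_real_,
                units = c(substrate = if (is.null(km_unit)) "mM" else km_unit,
                          velocity = "U/mg"))
    class(fit) <- "mm_fit"
  }
  stopifnot(inherits(fit, "mm_fit"))
  if (is.null(kcat)) {
    if (is.null(mw_kDa) || !is.finite(fit$Vmax))
      stop("supply kcat, or mw_kDa together with a fitted Vmax in U/mg")
    # U/mg = umol min-1 mg-1; * kDa (= mg/umol) -> min-1; /60 -> s-1
    kcat <- fit$Vmax * mw_kDa / 60
  }
  fit$kcat <- kcat
  fit$Ka <- 1 / fit$Km
  fit$Ki <- 1 / fit$Km
  unit <- fit$units[["substrate"]]
  km_molar <- switch(unit, mM = fit$Km * 1e-3, M = fit$Km, NA_real_)
  if (is.na(km_molar)) {
    warning("Km unit '", unit, "' is not molar-convertible; kcat/Km omitted")
    fit$kcat_over_Km <- NA_real_
  } else {
    fit$kcat_over_Km <- kcat / km_molar
  }
  fit
}

#' Lineweaver-Burk (double-reciprocal) transformation and line
#'
#' Ordinary least squares on `(1/S, 1/v)`.  The regression line has
#' slope `Km/Vmax` and intercept `1/Vmax`; the back-derived `Km` and
#' `Vmax` are reported alongside the transformed points.  Zero
#' velocities cannot be reciprocated and are excluded with a warning.
#'
#' @inheritParams fit_michaelis_menten
#' @return An object of class `lb_line`: `slope`, `intercept`, `Km`,
#'   `Vmax`, `r_squared` and the transformed `points` data frame.
#' @examples
#' S <- c(0.625, 1.25, 2.5, 5, 10, 20)
#' lineweaver_burk(S, 50 * S / (2 + S))  # slope 0.04, intercept 0.02
#' @export
lineweaver_burk <- function(substrate, velocity = NULL) {
  if (is.data.frame(substrate)) {
    velocity <- substrate$velocity
    substrate <- substrate$substrate
  }
  stopifnot(length(substrate) == length(velocity))
  keep <- velocity > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-velocity point(s) excluded from the reciprocal plot")
    substrate <- substrate[keep]; velocity <- velocity[keep]
  }
  if (length(substrate) < 2L) stop("insufficient data for a reciprocal line")
  x <- 1 / substrate; y <- 1 / velocity
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L]); intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((y - mean(y))^2)
  out <- list(slope = slope, intercept = intercept,
              Km = slope / intercept, Vmax = 1 / intercept,
              r_squared = if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_,
              points = data.frame(inv_S = x, inv_v = y))
  class(out) <- "lb_line"
  out
}

#' @export
print.lb_line <- function(x, digits = 4, ...) {
  cat("Lineweaver-Burk line: 1/v = ", format(x$slope, digits = digits),
      " * 1/S + ", format(x$intercept, digits = digits), "\n", sep = "")
  cat("  back-derived Km = ", format(x$Km, digits = digits),
      ", Vmax = ", format(x$Vmax, digits = digits), "\n", sep = "")
  invisible(x)
}
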