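#' Define a design factor with its coded-to-natural mapping
#'
#' A factor is described by a name, a symbol (A, B, C, ...), a center
#' and a half-range; coded level `x` maps to `center + x * half_range`.
#'
#' @param name factor name (e.g. `"pH"`).
#' @param center natural-unit center of the design region.
#' @param half_range natural-unit half-range (> 0) of the coded unit.
#' @param symbol one-letter role symbol; defaults are assigned by the
#'   design constructors.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pH", center = 6.5, half_range = 1.5)
#' @export
factor_spec <- function(name, center, half_range, symbol = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center), is.numeric(half_range), half_range > 0)
  out <- list(name = name, center = center, half_range = half_range,
              symbol = symbol)
  class(out) <- "factor_spec"
  out
}

# Center = most replicated level (the center point of a CCD/BBD);
# coded unit = smallest nonzero level distance from it (the factorial
# spacing), so factorial runs sit at +/-1 and axial runs at +/-alpha.
.infer_factor_spec <- function(x, name, symbol) {
  tab <- table(x)
  center <- as.numeric(names(tab)[which.max(tab)])
  d <- abs(unique(x) - center)
  d <- d[d > 1e-6 * max(diff(range(x)), 1)]
  if (length(d) == 0L) stop("degenerate factor column '", name, "'")
  factor_spec(name, center, min(d), symbol)
}

.coded_to_natural <- function(coded, factors) {
  nat <- coded
  for (j in seq_along(factors)) {
    nat[, j] <- factors[[j]]$center + coded[, j] * factors[[j]]$half_range
  }
  colnames(nat) <- vapply(factors, `[[`, character(1), "name")
  nat
}

.new_design <- function(coded, kind, factors = NULL, block = NULL) {
  coded <- as.data.frame(coded)
  out <- list(coded = coded,
              natural = if (!is.null(factors))
                as.data.frame(.coded_to_natural(as.matrix(coded), factors)) else NULL,
              block = block, kind = kind, factors = factors,
              n_runs = nrow(coded))
  class(out) <- "doe_design"
  out
}

#' @export
print.doe_design <- function(x, ...) {
  cat(x$kind, " design: ", x$n_runs, " runs, ",
      ncol(x$coded), " columns\n", sep = "")
  d <- x$coded
  if (!is.null(x$natural)) d <- cbind(d, x$natural)
  if (!is.null(x$block)) d$block <- x$block
  print(utils::head(d, 24), ...)
  invisible(x)
}

#' 12-run Plackett-Burman screening design
#'
#' Builds the standard 12-run Plackett-Burman matrix from the cyclic
#' generator row `+ + - + + + - - - + -` (each subsequent row is a right
#' cyclic shift) plus a final all-minus row.  The first `n_factors`
#' columns carry real factors; the remaining columns are dummy columns
#' whose apparent effects estimate the error.  Every column is balanced
#' (six +1, six -1) and all columns are pairwise orthogonal.
#'
#' @param n_factors number of real factors, 1 to 11.
#' @param factor_names optional character vector of factor names.
#' @return A `doe_design` with `kind = "plackett_burman"`, columns named
#'   by the factors then `dummy1`, `dummy2`, ...
#' @examples
#' pb <- plackett_burman_design(7)
#' colSums(pb$coded)          # all zero (balance)
#' crossprod(as.matrix(pb$coded))  # 12 * identity (orthogonality)
#' @export
plackett_burman_design <- function(n_factors, factor_names = NULL) {
  if (n_factors < 1L || n_factors > 11L)
    stop("design too small: the 12-run Plackett-Burman matrix holds at most 11 factors")
  gen <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)
  rows <- lapply(0:10, function(s) gen[((seq_len(11) - 1 - s) %% 11) + 1])
  m <- rbind(do.call(rbind, rows), rep(-1, 11))
  nm <- if (is.null(factor_names)) paste0("F", seq_len(n_factors)) else factor_names
  stopifnot(length(nm) == n_factors)
  n_dummy <- 11L - n_factors
  colnames(m) <- c(nm, if (n_dummy > 0) paste0("dummy", seq_len(n_dummy)))
  d <- .new_design(m, "plackett_burman")
  d$n_factors <- n_factors
  d$n_dummy <- n_dummy
  d
}

#' Screen main effects from a Plackett-Burman experiment
#'
#' Effect of factor j is `mean(y | x_j = +1) - mean(y | x_j = -1)`.
#' The error variance is estimated from the dummy-column effects (the
#' Minitab-style pseudo-error with one degree of freedom per dummy
#' column); each real effect is tested with `t = effect / SE` at
#' `alpha`.  Effects are returned ranked by `|t|`.  Lenth's pseudo
#' standard error is available as an alternative.
#'
#' @param design a `plackett_burman` [plackett_burman_design()].
#' @param response numeric vector of 12 responses, in run order.
#' @param alpha significance level (default 0.05).
#' @param method `"dummy"` (default) or `"lenth"`.
#' @return An object of class `pb_screen`: data frame `effects` with
#'   columns `factor`, `effect`, `t`, `significant`, ranked by `|t|`;
#'   plus `se`, `df`, `method`.
#' @examples
#' pb <- plackett_burman_design(7)
#' set.seed(1)
#' y <- 2 * pb$coded$F1 + rnorm(12, sd = 0.5)
#' pb_effect_screen(pb, y)
#' @export
pb_effect_screen <- function(design, response, alpha = 0.05,
                             method = c("dummy", "lenth")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "doe_design"), design$kind == "plackett_burman")
  if (length(response) != design$n_runs)
    stop("response length must equal the number of runs (", design$n_runs, ")")
  m <- as.matrix(design$coded)
  eff <- colMeans(m * response) * 2  # mean(+1) - mean(-1) on balanced columns
  real <- seq_len(design$n_factors)
  dummy <- setdiff(seq_len(ncol(m)), real)
  if (method == "dummy") {
    if (length(dummy) == 0L) {
      warning("no dummy columns: effects reported without significance flags")
      se <- NA_real_; df <- 0L
    } else {
      se <- sqrt(mean(eff[dummy]^2))
      df <- length(dummy)
    }
  } else {
    s0 <- 1.5 * stats::median(abs(eff[real]))
    se <- 1.5 * stats::median(abs(eff[real])[abs(eff[real]) < 2.5 * s0])
    df <- round(length(real) / 3)
  }
  tval <- if (is.na(se) || se == 0) rep(NA_real_, length(real)) else eff[real] / se
  crit <- if (df > 0) stats::qt(1 - alpha / 2, df) else NA_real_
  tab <- data.frame(factor = colnames(m)[real],
                    effect = unname(eff[real]),
                    t = unname(tval),
                    significant = if (!is.na(crit)) abs(tval) > crit else NA,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(ifelse(is.na(tab$t), tab$effect, tab$t))), ]
  rownames(tab) <- NULL
  out <- list(effects = tab, se = se, df = df, method = method, alpha = alpha)
  class(out) <- "pb_screen"
  out
}

#' @export
print.pb_screen <- function(x, digits = 4, ...) {
  cat("Plackett-Burman effect screen (", x$method, " error, df = ", x$df,
      ")\n", sep = "")
  print(format(x$effects, digits = digits))
  invisible(x)
}

#' Rotatable central composite design for three factors
#'
#' Eight factorial points at coded +/-1, six axial points at +/-alpha
#' with `alpha = 8^(1/4) ~ 1.682` (rotatability), and `n_center` center
#' points.  With `blocks = TRUE` the design splits orthogonally into a
#' factorial block (8 corner runs + 4 centers) and an axial block
#' (6 axial runs + 2 centers), the classical two-block CCD.
#'
#' @param factors list of 3 [factor_spec()] objects.
#' @param n_center total number of center points (default 6).
#' @param blocks split into factorial/axial blocks (default TRUE).
#' @return A `doe_design` with `kind = "central_composite"`, coded and
#'   natural levels, and a `block` factor when blocked.
#' @examples
#' f <- list(factor_spec("pH", 6.5, 1.5), factor_spec("temperature", 30, 10),
#'           factor_spec("inoculum_od", 0.65, 0.35))
#' central_composite_design(f)
#' @export
central_composite_design <- function(factors, n_center = 6L, blocks = TRUE) {
  stopifnot(length(factors) == 3L,
            all(vapply(factors, inherits, logical(1), "factor_spec")))
  alpha <- 8^(1 / 4)
  fact <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1)))
  axial <- rbind(c(-alpha, 0, 0), c(alpha, 0, 0),
                 c(0, -alpha, 0), c(0, alpha, 0),
                 c(0, 0, -alpha), c(0, 0, alpha))
  if (blocks) {
    n_c1 <- ceiling(n_center * 2 / 3)        # centers in the factorial block
    n_c2 <- n_center - n_c1
    coded <- rbind(fact, matrix(0, n_c1, 3), axial, matrix(0, n_c2, 3))
    block <- factor(c(rep(1, 8 + n_c1), rep(2, 6 + n_c2)))
  } else {
    coded <- rbind(fact, axial, matrix(0, n_center, 3))
    block <- NULL
  }
  colnames(coded) <- vapply(factors, `[[`, character(1), "name")
  for (j in 1:3) if (is.na(factors[[j]]$symbol)) factors[[j]]$symbol <- LETTERS[j]
  .new_design(coded, "central_composite", factors, block)
}

#' Box-Behnken design for three factors
#'
#' Twelve edge-midpoint runs (every pair of factors at +/-1 with the
#' third at 0; no corner runs) plus `n_center` center points.
#'
#' @inheritParams central_composite_design
#' @param n_center number of center points (default 3).
#' @return A `doe_design` with `kind = "box_behnken"`.
#' @examples
#' f <- list(factor_spec("pH", 6.5, 1.5), factor_spec("temperature", 30, 10),
#'           factor_spec("inoculum_od", 0.65, 0.35))
#' box_behnken_design(f)
#' @export
box_behnken_design <- function(factors, n_center = 3L) {
  stopifnot(length(factors) == 3L,
            all(vapply(factors, inherits, logical(1), "factor_spec")))
  pm <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  edges <- rbind(cbind(pm, 0), cbind(pm[, 1], 0, pm[, 2]), cbind(0, pm))
  coded <- rbind(edges, matrix(0, n_center, 3))
  colnames(coded) <- vapply(factors, `[[`, character(1), "name")
  for (j in 1:3) if (is.na(factors[[j]]$symbol)) factors[[j]]$symbol <- LETTERS[j]
  .new_design(coded, "box_behnken", factors)
}

#' Fit a second-order response-surface model with full ANOVA
#'
#' Ordinary least squares of the full quadratic (intercept, linear,
#' two-way interaction and pure quadratic terms) on the natural factor
#' levels, optionally with an additive block effect.  A parallel fit on
#' coded levels supplies the ANOVA: per-term sums of squares are the
#' partial (drop-one) sums of squares of the coded fit; the model sum of
#' squares is the extra sum of squares beyond the block; the residual is
#' split into lack of fit and pure error using replicated design points
#' (within block when blocked).  F statistics use the residual mean
#' square; the lack-of-fit F uses the pure-error mean square.
#'
#' @param design a `doe_design` (CCD or BBD with factor specs), or a
#'   data frame of natural factor levels (3 columns).
#' @param response numeric vector, one response per run.
#' @param include_block include the design's block effect (default TRUE
#'   when the design has blocks).
#' @param block optional explicit block factor (when `design` is a data
#'   frame).
#' @param factors optional list of 3 [factor_spec()]s fixing the
#'   coded-to-natural mapping.  When `design` is a plain data frame and
#'   no specs are given, the center is taken as the most replicated
#'   level of each column (the center point) and the coded unit as the
#'   smallest nonzero level distance from it (the factorial spacing).
#' @return An object of class `rsm_fit`: `coefficients` (natural units,
#'   named `intercept`, `A`, `B`, `C`, `AB`, `AC`, `BC`, `A2`, `B2`,
#'   `C2`), `coded_coefficients`, `anova` (data frame with rows Block,
#'   Model, each term, Residual, Lack of fit, Pure error, Cor total),
#'   `r_squared`, `fitted`, `model` (the natural-unit `lm`), `factors`,
#'   `block`.
#' @examples
#' d <- celc307_rsm_runs()
#' fit <- fit_response_surface(d[, c("pH", "temperature", "inoculum_od")],
#'                             d$activity, block = d$block)
#' fit$anova
#' @export
fit_response_surface <- function(design, response, include_block = NULL,
                                 block = NULL, factors = NULL) {
  if (inherits(design, "doe_design")) {
    nat <- design$natural
    if (is.null(nat)) stop("design has no natural levels; supply factor specs")
    if (is.null(block)) block <- design$block
    if (is.null(factors)) factors <- design$factors
  } else {
    nat <- as.data.frame(design)
    if (is.null(factors))
      factors <- lapply(seq_along(nat), function(j)
        .infer_factor_spec(nat[[j]], names(nat)[j], LETTERS[j]))
  }
  stopifnot(ncol(nat) == 3L, length(response) == nrow(nat))
  if (is.null(include_block)) include_block <- !is.null(block)
  if (include_block && is.null(block))
    stop("include_block = TRUE but no block labels available")
  blk <- if (include_block) factor(block) else factor(rep(1, nrow(nat)))
  use_block <- include_block && nlevels(blk) > 1L

  centers <- vapply(factors, `[[`, numeric(1), "center")
  halfr <- vapply(factors, `[[`, numeric(1), "half_range")
  coded <- sweep(sweep(as.matrix(nat), 2, centers), 2, halfr, "/")

  build_df <- function(m) {
    data.frame(y = response, A = m[, 1], B = m[, 2], C = m[, 3], block = blk)
  }
  form <- if (use_block)
    y ~ block + A + B + C + A:B + A:C + B:C + I(A^2) + I(B^2) + I(C^2)
  else
    y ~ A + B + C + A:B + A:C + B:C + I(A^2) + I(B^2) + I(C^2)

  dn <- build_df(as.matrix(nat)); dc <- build_df(coded)
  fit_nat <- stats::lm(form, data = dn)
  fit_cod <- stats::lm(form, data = dc)
  if (any(is.na(stats::coef(fit_nat)))) stop("singular design: model is rank deficient")

  y <- response
  ss_total <- sum((y - mean(y))^2)
  rss <- sum(stats::resid(fit_cod)^2)
  rss_block <- if (use_block) sum(stats::resid(stats::lm(y ~ blk))^2) else ss_total
  ss_block <- ss_total - rss_block
  ss_model <- rss_block - rss
  df_block <- if (use_block) nlevels(blk) - 1L else 0L
  df_model <- 9L
  df_resid <- length(y) - 1L - df_block - df_model

  # partial (drop-one) term SS on the coded fit
  scope <- ~ A + B + C + A:B + A:C + B:C + I(A^2) + I(B^2) + I(C^2)
  # drop1 warns on zero-residual (noiseless) fits; the sums of squares
  # are still exact there
  dr <- suppressWarnings(stats::drop1(fit_cod, scope = scope))
  term_ss <- dr$`Sum of Sq`[-1L]
  term_labels <- rownames(dr)[-1L]
  pretty <- c("A" = "A", "B" = "B", "C" = "C",
              "I(A^2)" = "A2", "I(B^2)" = "B2", "I(C^2)" = "C2",
              "A:B" = "AB", "A:C" = "AC", "B:C" = "BC")
  term_labels <- unname(pretty[term_labels])
  ord <- match(c("A", "B", "C", "AB", "AC", "BC", "A2", "B2", "C2"), term_labels)
  term_ss <- term_ss[ord]; term_labels <- term_labels[ord]

  # pure error from replicated (coded point, block) groups
  key <- apply(cbind(round(coded, 8), as.integer(blk)), 1, paste, collapse = "/")
  groups <- split(y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- sum(vapply(groups, length, integer(1)) - 1L)
  ss_lof <- rss - ss_pe
  df_lof <- df_resid - df_pe

  ms_resid <- rss / df_resid
  mk_row <- function(source, ss, df, with_f = TRUE, ms_err = ms_resid) {
    ms <- if (df > 0) ss / df else NA_real_
    f <- if (with_f && df > 0) ms / ms_err else NA_real_
    p <- if (with_f && df > 0) stats::pf(f, df, if (identical(ms_err, ms_resid)) df_resid else df_pe,
                                         lower.tail = FALSE) else NA_real_
    data.frame(source = source, SS = ss, df = df, MS = ms, F = f, p = p,
               stringsAsFactors = FALSE)
  }
  rows <- list(mk_row("Block", ss_block, df_block, with_f = FALSE),
               mk_row("Model", ss_model, df_model))
  for (i in seq_along(term_labels))
    rows[[length(rows) + 1L]] <- mk_row(term_labels[i], term_ss[i], 1L)
  rows[[length(rows) + 1L]] <- mk_row("Residual", rss, df_resid, with_f = FALSE)
  rows[[length(rows) + 1L]] <- if (df_pe > 0)
    mk_row("Lack of fit", ss_lof, df_lof, ms_err = ss_pe / df_pe)
  else mk_row("Lack of fit", ss_lof, df_lof, with_f = FALSE)
  rows[[length(rows) + 1L]] <- mk_row("Pure error", ss_pe, df_pe, with_f = FALSE)
  rows[[length(rows) + 1L]] <- mk_row("Cor total", ss_total, length(y) - 1L, with_f = FALSE)
  anova_tab <- do.call(rbind, rows)
  rownames(anova_tab) <- NULL

  cf <- stats::coef(fit_nat)
  nm <- names(cf)
  rename <- function(nm) {
    nm[nm == "(Intercept)"] <- "intercept"
    nm <- sub("^I\\(A\\^2\\)$", "A2", nm); nm <- sub("^I\\(B\\^2\\)$", "B2", nm)
    nm <- sub("^I\\(C\\^2\\)$", "C2", nm)
    nm <- sub("^A:B$", "AB", nm); nm <- sub("^A:C$", "AC", nm); nm <- sub("^B:C$", "BC", nm)
    nm
  }
  names(cf) <- rename(nm)
  cc <- stats::coef(fit_cod); names(cc) <- rename(names(cc))

  out <- list(coefficients = cf, coded_coefficients = cc,
              anova = anova_tab,
              r_squared = 1 - rss / (ss_total - ss_block),
              model_F = ss_model / df_model / ms_resid,
              lack_of_fit_F = if (df_pe > 0 && df_lof > 0)
                (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_,
              fitted = stats::fitted(fit_nat),
              residuals = stats::resid(fit_nat),
              model = fit_nat, coded_model = fit_cod,
              factors = factors, block = if (use_block) blk else NULL,
              response = y)
  class(out) <- "rsm_fit"
  out
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat("Second-order response-surface fit (", length(x$response), " runs",
      if (!is.null(x$block)) paste0(", ", nlevels(x$block), " blocks"), ")\n", sep = "")
  cat("Coefficients (natural units):\n")
  print(round(x$coefficients, digits))
  cat("R2 =", format(x$r_squared, digits = digits),
      " model F =", format(x$model_F, digits = digits),
      " lack-of-fit F =", format(x$lack_of_fit_F, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, coded = FALSE, ...)
  if (coded) object$coded_coefficients else object$coefficients

#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  nd <- as.data.frame(newdata)
  names(nd) <- c("A", "B", "C")[seq_len(ncol(nd))]
  cf <- object$coefficients
  blk_adj <- 0
  with(nd, cf[["intercept"]] + cf[["A"]] * A + cf[["B"]] * B + cf[["C"]] * C +
         cf[["AB"]] * A * B + cf[["AC"]] * A * C + cf[["BC"]] * B * C +
         cf[["A2"]] * A^2 + cf[["B2"]] * B^2 + cf[["C2"]] * C^2) + blk_adj
}

#' @export
summary.rsm_fit <- function(object, ...) {
  cat("ANOVA:\n"); print(format(object$anova, digits = 4))
  invisible(object)
}

#' Locate the predicted optimum of a fitted response surface
#'
#' Solves the stationary point of the quadratic in closed form (the
#' gradient linear system).  If the stationary point is a maximum inside
#' the bounds it is returned exactly; otherwise the bound box is scanned
#' on a dense grid (`n_grid` points per axis) and the best point is
#' refined by local ascent (`L-BFGS-B`), which handles boundary optima
#' and saddle surfaces.
#'
#' @param model an `rsm_fit`.
#' @param bounds list or 2-row matrix of per-factor `c(lower, upper)`
#'   bounds in natural units.
#' @param n_grid grid resolution per axis for the fallback search.
#' @return list with `optimum` (named numeric location), `predicted`
#'   (predicted response), `stationary_point`, `stationary_kind`
#'   (`"maximum"`, `"minimum"` or `"saddle"`), `on_boundary`.
#' @examples
#' d <- celc307_rsm_runs()
#' fit <- fit_response_surface(d[, c("pH", "temperature", "inoculum_od")],
#'                             d$activity, block = d$block)
#' optimize_response(fit, list(c(5, 8), c(20, 40), c(0.3, 1)))
#' @export
optimize_response <- function(model, bounds, n_grid = 50L) {
  stopifnot(inherits(model, "rsm_fit"))
  if (is.list(bounds)) bounds <- do.call(cbind, bounds)
  stopifnot(ncol(bounds) == 3L, nrow(bounds) == 2L || nrow(bounds) == 2L)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  cf <- model$coefficients
  Q <- matrix(c(2 * cf[["A2"]], cf[["AB"]], cf[["AC"]],
                cf[["AB"]], 2 * cf[["B2"]], cf[["BC"]],
                cf[["AC"]], cf[["BC"]], 2 * cf[["C2"]]), 3, 3)
  b <- c(cf[["A"]], cf[["B"]], cf[["C"]])
  stat <- tryCatch(solve(Q, -b), error = function(e) rep(NA_real_, 3))
  ev <- tryCatch(eigen(Q, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) rep(NA_real_, 3))
  kind <- if (all(is.finite(ev))) {
    if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  } else "degenerate"
  f <- function(x) predict(model, matrix(x, 1))
  in_bounds <- all(is.finite(stat)) && all(stat >= lo) && all(stat <= hi)
  if (kind == "maximum" && in_bounds) {
    opt <- stat; val <- f(stat); boundary <- FALSE
  } else {
    grid <- expand.grid(seq(lo[1], hi[1], length.out = n_grid),
                        seq(lo[2], hi[2], length.out = n_grid),
                        seq(lo[3], hi[3], length.out = n_grid))
    vals <- predict(model, grid)
    x0 <- as.numeric(grid[which.max(vals), ])
    res <- stats::optim(x0, f, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(fnscale = -1))
    opt <- res$par; val <- res$value
    boundary <- any(abs(opt - lo) < 1e-8 | abs(opt - hi) < 1e-8)
  }
  names(opt) <- vapply(model$factors, `[[`, character(1), "name")
  list(optimum = opt, predicted = unname(val),
       stationary_point = stat, stationary_kind = kind,
       on_boundary = boundary)
}
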