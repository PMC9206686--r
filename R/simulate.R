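# Seeded synthetic-data generators.  Each generator is a pure function
# of its arguments and the seed: the same call with the same seed
# returns the identical dataset, and with zero noise every generator's
# output is an exact fixed point of its fitting stage.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  force(expr)
}

#' Simulate a Michaelis-Menten velocity dataset
#'
#' Velocities `v = Vmax * S / (Km + S)` with additive Gaussian noise of
#' standard deviation `sd_frac * Vmax`, truncated at zero (activities
#' cannot be negative).  Defaults mirror the CelC307 presets: Km 0.46,
#' Vmax 62.58 on the assay's 0.625-20 substrate grid, triplicate
#' measurements.
#'
#' @param Km,Vmax true parameters (Km > 0, Vmax > 0).
#' @param substrate substrate grid.
#' @param sd_frac noise standard deviation as a fraction of Vmax
#'   (>= 0).
#' @param reps replicate measurements per substrate level.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data frame with columns `substrate`, `velocity`, `replicate`.
#' @examples
#' simulate_mm_dataset(Km = 2, Vmax = 50, sd_frac = 0, reps = 1)
#' @export
simulate_mm_dataset <- function(Km = 0.46, Vmax = 62.58,
                                substrate = c(0.625, 1.25, 2.5, 5, 10, 20),
                                sd_frac = 0.03, reps = 3L, seed = NULL) {
  stopifnot(Km > 0, Vmax > 0, length(substrate) > 0)
  if (sd_frac < 0) stop("invalid noise: sd_frac must be >= 0")
  .with_seed(seed, {
    S <- rep(substrate, each = reps)
    v <- Vmax * S / (Km + S) + stats::rnorm(length(S), sd = sd_frac * Vmax)
    data.frame(substrate = S, velocity = pmax(v, 0),
               replicate = rep(seq_len(reps), times = length(substrate)))
  })
}

#' Simulate an inhibitor series under a canonical mechanism
#'
#' Generates one Michaelis-Menten dataset per inhibitor concentration
#' with apparent parameters following the chosen mechanism
#' (`Ki` the inhibition constant, `alpha` the mixed-mechanism factor):
#'
#' * competitive: `Km' = Km (1 + I/Ki)`, `Vmax' = Vmax`;
#' * noncompetitive: `Km' = Km`, `Vmax' = Vmax / (1 + I/Ki)`;
#' * uncompetitive: both divided by `(1 + I/Ki)`;
#' * mixed: `Km' = Km (1 + I/Ki) / (1 + I/(alpha Ki))`,
#'   `Vmax' = Vmax / (1 + I/(alpha Ki))`.
#'
#' Defaults use a mid-grid Km (2) and Vmax 50 so apparent-Km shifts are
#' identifiable on the assay's substrate window, with `Ki = 0.5` and
#' inhibitor levels 0, 0.5, 1 (control plus the two assayed levels).
#'
#' @param mode generating mechanism.
#' @param Km,Vmax uninhibited parameters.
#' @param Ki inhibition constant (> 0).
#' @param alpha mixed-mechanism factor (only used for `mode = "mixed"`).
#' @param inhibitor_conc inhibitor concentrations, must include 0.
#' @inheritParams simulate_mm_dataset
#' @return data frame with columns `inhibitor_conc`, `substrate`,
#'   `velocity`, `replicate` and attribute `inhibitor = mode`.
#' @examples
#' ser <- simulate_inhibition_series("competitive", sd_frac = 0, seed = 1)
#' @export
simulate_inhibition_series <- function(mode = c("competitive", "noncompetitive",
                                                "uncompetitive", "mixed"),
                                       Km = 2, Vmax = 50, Ki = 0.5, alpha = 2,
                                       inhibitor_conc = c(0, 0.5, 1),
                                       substrate = c(0.625, 1.25, 2.5, 5, 10, 20),
                                       sd_frac = 0.03, reps = 3L, seed = NULL) {
  mode <- tryCatch(match.arg(mode), error = function(e) stop("invalid mechanism"))
  stopifnot(Ki > 0, 0 %in% inhibitor_conc)
  .with_seed(seed, {
    out <- lapply(inhibitor_conc, function(I) {
      app <- switch(mode,
        competitive    = c(Km * (1 + I / Ki), Vmax),
        noncompetitive = c(Km, Vmax / (1 + I / Ki)),
        uncompetitive  = c(Km / (1 + I / Ki), Vmax / (1 + I / Ki)),
        mixed          = c(Km * (1 + I / Ki) / (1 + I / (alpha * Ki)),
                           Vmax / (1 + I / (alpha * Ki))))
      d <- simulate_mm_dataset(Km = app[1], Vmax = app[2], substrate = substrate,
                               sd_frac = sd_frac, reps = reps, seed = NULL)
      cbind(inhibitor_conc = I, d)
    })
    out <- do.call(rbind, out)
    attr(out, "inhibitor") <- mode
    out
  })
}

#' Simulate a thermal-inactivation panel under an Arrhenius law
#'
#' Per-temperature rate constants `k_in(T) = A exp(-Ea / (R T))`;
#' residual fractions `exp(-k_in t)` with additive Gaussian noise,
#' clipped to `(0, 1.05]`.  Defaults reproduce the CelC307 regime: Ea
#' 59.29 kJ/mol with the pre-exponential chosen so k_in(40 degC) =
#' 0.0162 min-1, hourly sampling over 6 h.
#'
#' @param Ea_kJ_mol inactivation energy barrier (> 0, kJ/mol).
#' @param A pre-exponential factor (min-1, > 0).
#' @param temperature_C temperature grid (degC).
#' @param time_min time grid (min), including 0.
#' @param sd absolute noise standard deviation on the fraction scale.
#' @param seed integer seed.
#' @return list of time courses (elements `temperature_C`, `time_min`,
#'   `fraction`), the format [inactivation_profile()] consumes.
#' @examples
#' panel <- simulate_inactivation_panel(sd = 0, seed = 1)
#' @export
simulate_inactivation_panel <- function(Ea_kJ_mol = 59.29, A = 1.258e8,
                                        temperature_C = c(40, 60, 70, 80, 90),
                                        time_min = seq(0, 360, by = 60),
                                        sd = 0.01, seed = NULL) {
  stopifnot(Ea_kJ_mol > 0, A > 0)
  if (length(temperature_C) == 0 || length(time_min) == 0)
    stop("invalid design: empty temperature or time grid")
  .with_seed(seed, {
    lapply(temperature_C, function(tc) {
      k <- A * exp(-Ea_kJ_mol * 1000 / (physical_constants$R * celsius_to_kelvin(tc)))
      f <- exp(-k * time_min) + stats::rnorm(length(time_min), sd = sd)
      f <- pmin(f, 1.05)
      f[f <= 0] <- 1e-6   # noise can push a deep-decay point non-positive
      f[time_min == 0] <- 1
      list(temperature_C = tc, time_min = time_min, fraction = f)
    })
  })
}

#' Simulate responses from a known second-order polynomial
#'
#' `y = quadratic(natural levels) + block effect + Gaussian noise`.
#' The coefficient vector uses the same naming as [fit_response_surface()]
#' (`intercept`, `A`, `B`, `C`, `AB`, `AC`, `BC`, `A2`, `B2`, `C2`);
#' the default is the CelC307 fitted polynomial.
#'
#' @param design a `doe_design` with natural levels, or a data frame of
#'   3 natural factor columns.
#' @param coefficients named numeric vector of 10 coefficients.
#' @param block_effects numeric vector of per-block additive effects
#'   (recycled over block levels); ignored when the design is unblocked.
#' @param sd response noise standard deviation.
#' @param seed integer seed.
#' @return numeric response vector, one per run.
#' @examples
#' f <- celc307_rsm_factors()
#' d <- central_composite_design(f)
#' y <- simulate_doe_response(d, sd = 0, seed = 1)
#' @export
simulate_doe_response <- function(design,
                                  coefficients = celc307_quadratic_coefficients(),
                                  block_effects = 0, sd = 1, seed = NULL) {
  nat <- if (inherits(design, "doe_design")) design$natural else as.data.frame(design)
  if (is.null(nat) || ncol(nat) != 3L) stop("dimension error: need 3 natural factor columns")
  need <- c("intercept", "A", "B", "C", "AB", "AC", "BC", "A2", "B2", "C2")
  if (!all(need %in% names(coefficients)))
    stop("dimension error: coefficients must be named ",
         paste(need, collapse = ", "))
  cf <- coefficients
  A <- nat[[1]]; B <- nat[[2]]; C <- nat[[3]]
  mu <- cf[["intercept"]] + cf[["A"]] * A + cf[["B"]] * B + cf[["C"]] * C +
    cf[["AB"]] * A * B + cf[["AC"]] * A * C + cf[["BC"]] * B * C +
    cf[["A2"]] * A^2 + cf[["B2"]] * B^2 + cf[["C2"]] * C^2
  blk <- if (inherits(design, "doe_design") && !is.null(design$block))
    design$block else factor(rep(1, length(mu)))
  be <- rep_len(block_effects, nlevels(blk))
  mu <- mu + be[as.integer(blk)]
  .with_seed(seed, mu + stats::rnorm(length(mu), sd = sd))
}

#' Random protein sequence of a given composition
#'
#' Draws residues independently from the stated composition weights;
#' deterministic per seed.
#'
#' @param length sequence length (>= 2).
#' @param weights named numeric vector of non-negative composition
#'   weights over the 20-letter alphabet (need not sum to 1); default
#'   uniform.
#' @param seed integer seed.
#' @return a protein string.
#' @examples
#' random_protein(10, weights = c(A = 1))  # "AAAAAAAAAA"
#' @export
random_protein <- function(length, weights = NULL, seed = NULL) {
  stopifnot(length >= 2L)
  if (is.null(weights)) weights <- stats::setNames(rep(1, 20), .aa_letters)
  w <- stats::setNames(rep(0, 20), .aa_letters)
  stopifnot(all(names(weights) %in% .aa_letters))
  w[names(weights)] <- weights
  if (all(w == 0) || any(w < 0)) stop("invalid composition: weights must be non-negative, not all zero")
  .with_seed(seed,
    paste(sample(.aa_letters, length, replace = TRUE, prob = w / sum(w)),
          collapse = ""))
}
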