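test_that("generators are pure functions of their seed", {
  expect_identical(simulate_mm_dataset(seed = 4), simulate_mm_dataset(seed = 4))
  expect_identical(simulate_inhibition_series("mixed", seed = 4),
                   simulate_inhibition_series("mixed", seed = 4))
  expect_identical(simulate_inactivation_panel(seed = 4),
                   simulate_inactivation_panel(seed = 4))
  d <- central_composite_design(celc307_rsm_factors())
  expect_identical(simulate_doe_response(d, seed = 4),
                   simulate_doe_response(d, seed = 4))
  expect_identical(random_protein(50, seed = 4), random_protein(50, seed = 4))
  # and different seeds move the noise
  expect_false(identical(simulate_mm_dataset(seed = 4),
                         simulate_mm_dataset(seed = 5)))
})

test_that("noiseless outputs are exact fixed points of their fitting stages", {
  d <- simulate_mm_dataset(Km = 2, Vmax = 50, sd_frac = 0, reps = 1, seed = 1)
  expect_equal(d$velocity, 50 * d$substrate / (2 + d$substrate))
  fit <- fit_michaelis_menten(d)
  expect_equal(coef(fit), c(Km = 2, Vmax = 50), tolerance = 1e-6)

  panel <- simulate_inactivation_panel(Ea_kJ_mol = 60, A = 1e7, sd = 0, seed = 1)
  expect_equal(inactivation_profile(panel)$Ea_kJ_mol, 60, tolerance = 1e-9)
  expect_true(all(vapply(panel, function(p) p$fraction[p$time_min == 0] == 1,
                         logical(1))))

  dd <- central_composite_design(celc307_rsm_factors())
  truth <- celc307_quadratic_coefficients()
  y <- simulate_doe_response(dd, truth, sd = 0, seed = 1)
  fit2 <- fit_response_surface(dd, y, include_block = FALSE)
  expect_equal(fit2$coefficients[names(truth)], truth, tolerance = 1e-6)
})

test_that("replicate means converge to the Michaelis-Menten curve", {
  d <- simulate_mm_dataset(Km = 2, Vmax = 50, substrate = c(1, 5, 20),
                           sd_frac = 0.05, reps = 1000, seed = 77)
  for (S in c(1, 5, 20)) {
    v <- d$velocity[d$substrate == S]
    truth <- 50 * S / (2 + S)
    expect_lt(abs(mean(v) - truth), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("inhibition generator applies the mechanistic laws at [I] = Ki", {
  app <- function(mode) {
    ser <- simulate_inhibition_series(mode, Km = 2, Vmax = 50, Ki = 0.5,
                                      inhibitor_conc = c(0, 0.5), sd_frac = 0,
                                      seed = 1)
    coef(fit_michaelis_menten(ser[ser$inhibitor_conc == 0.5, ]))
  }
  expect_equal(app("competitive"), c(Km = 4, Vmax = 50), tolerance = 1e-5)
  expect_equal(app("noncompetitive"), c(Km = 2, Vmax = 25), tolerance = 1e-5)
  expect_equal(app("uncompetitive"), c(Km = 1, Vmax = 25), tolerance = 1e-5)
})

test_that("inactivation rates increase strictly with temperature", {
  panel <- simulate_inactivation_panel(sd = 0, seed = 1)
  k <- vapply(panel, function(p)
    fit_inactivation_rate(p$time_min, p$fraction)$k_in_per_min, numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("center replicates carry the pure-error chi-square expectation", {
  dd <- central_composite_design(celc307_rsm_factors())
  sspe <- numeric(200)
  for (i in seq_along(sspe)) {
    y <- simulate_doe_response(dd, sd = 1, seed = 8000 + i)
    fit <- fit_response_surface(dd, y, include_block = FALSE)
    sspe[i] <- fit$anova$SS[fit$anova$source == "Pure error"]
  }
  df_pe <- 5  # six center replicates
  # mean of a chi-square(df) is df; standard error sqrt(2 df / n)
  expect_lt(abs(mean(sspe) - df_pe), 4 * sqrt(2 * df_pe / length(sspe)))
})

test_that("random proteins follow the requested composition", {
  expect_equal(random_protein(10, weights = c(A = 1), seed = 1),
               strrep("A", 10))
  s <- random_protein(1e5, weights = c(A = 0.5, G = 0.3, W = 0.2), seed = 12)
  freq <- table(strsplit(s, "")[[1]]) / 1e5
  expect_equal(unname(freq[["A"]]), 0.5, tolerance = 0.02)
  expect_equal(unname(freq[["G"]]), 0.3, tolerance = 0.02)
  expect_equal(unname(freq[["W"]]), 0.2, tolerance = 0.02)
  expect_error(random_protein(10, weights = c(A = 0)), "invalid composition")
})

test_that("invalid noise and empty grids are refused", {
  expect_error(simulate_mm_dataset(sd_frac = -1), "invalid noise")
  expect_error(simulate_inactivation_panel(temperature_C = numeric(0)),
               "invalid design")
})
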