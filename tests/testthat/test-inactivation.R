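test_that("exact exponential decay yields the generating rate", {
  t <- c(0, 60, 120, 240, 360)
  fit <- fit_inactivation_rate(t, exp(-0.05 * t))
  expect_equal(fit$k_in_per_min, 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy decay matches the zero-intercept closed form", {
  t <- c(0, 60, 120, 180, 240, 300, 360)
  set.seed(8)
  f <- exp(-0.01 * t) * exp(rnorm(7, sd = 0.02))
  fit <- fit_inactivation_rate(t, f)
  k_closed <- -sum(t * log(f)) / sum(t^2)
  expect_equal(fit$k_in_per_min, k_closed, tolerance = 1e-12)
  # within 3 standard errors of the truth
  se <- sqrt(sum((log(f) + k_closed * t)^2) / (length(t) - 1) / sum(t^2))
  expect_lt(abs(fit$k_in_per_min - 0.01), 3 * se)
})

test_that("rising activity flags activation, non-positive points drop", {
  t <- c(0, 60, 120, 240)
  expect_warning(fit <- fit_inactivation_rate(t, exp(0.002 * t)), "activation")
  expect_true(fit$activation)
  expect_lt(fit$k_in_per_min, 0)
  expect_warning(fit2 <- fit_inactivation_rate(c(t, 300), c(1, 0.8, 0.5, 0.2, -0.1)),
                 "dropped")
  expect_equal(fit2$n_used, 4L)
  expect_error(
    suppressWarnings(fit_inactivation_rate(c(0, 60), c(-1, -2))), "no decay")
})

test_that("half-life and D obey their exact first-order identities", {
  expect_equal(half_life_and_D(log(2))$t_half_min, 1)
  hd <- half_life_and_D(1.62e-2)
  expect_equal(hd$t_half_min, log(2) / 1.62e-2)   # ~42.79 min
  expect_equal(hd$D_min, log(10) / 1.62e-2)       # ~142.1 min
  for (k in c(0.001, 0.05, 2)) {
    hd <- half_life_and_D(k)
    expect_equal(hd$t_half_min * k, log(2), tolerance = 1e-14)
    expect_equal(hd$D_min * k, log(10), tolerance = 1e-14)
    expect_equal(hd$D_min / hd$t_half_min, log(10) / log(2), tolerance = 1e-14)
  }
  expect_error(half_life_and_D(0), "no decay")
})

test_that("per-minute Eyring mode reproduces table-style dG while identities hold", {
  sf <- inactivation_state_functions(1.62e-2, 59.29, 313.15,
                                     rate_unit_mode = "per_minute")
  expect_equal(sf$dG_kJ_mol, 87.56, tolerance = 1e-3)
  expect_equal(sf$dH_kJ_mol, 59.29 - physical_constants$R * 313.15 / 1000)
  expect_equal(sf$dG_kJ_mol, sf$dH_kJ_mol - 313.15 * sf$dS_J_mol_K / 1000,
               tolerance = 1e-12)
  # standard mode differs by RT ln 60
  sf2 <- inactivation_state_functions(1.62e-2, 59.29, 313.15)
  expect_equal(sf2$dG_kJ_mol - sf$dG_kJ_mol,
               physical_constants$R * 313.15 * log(60) / 1000, tolerance = 1e-10)
})

test_that("a noiseless panel round-trips its Arrhenius parameters", {
  panel <- simulate_inactivation_panel(Ea_kJ_mol = 60, A = 1e7, sd = 0, seed = 1)
  prof <- inactivation_profile(panel)
  expect_equal(prof$Ea_kJ_mol, 60, tolerance = 1e-9)
  expect_equal(prof$arrhenius$A, 1e7, tolerance = 1e-6)
  tab <- prof$table
  # identities on every row
  expect_equal(tab$t_half_min * tab$k_in_per_min, rep(log(2), nrow(tab)))
  expect_equal(tab$D_min * tab$k_in_per_min, rep(log(10), nrow(tab)))
  expect_equal(tab$dH_kJ_mol,
               prof$Ea_kJ_mol - physical_constants$R * celsius_to_kelvin(tab$temperature_C) / 1000)
  # Arrhenius monotonicity: rates rise, half-lives fall with temperature
  expect_true(all(diff(tab$k_in_per_min) > 0))
  expect_true(all(diff(tab$t_half_min) < 0))
  # dG# increases with temperature for barriers above RT
  expect_true(all(diff(tab$dG_kJ_mol) > 0))
})

test_that("one unusable temperature gives a partial profile with a warning", {
  panel <- simulate_inactivation_panel(sd = 0, seed = 1)
  panel[[2]]$fraction <- rep(-1, length(panel[[2]]$fraction))  # unusable
  expect_warning(  # the point-level drop warns first, then the profile
    expect_warning(prof <- inactivation_profile(panel), "non-positive"),
    "dropped")
  expect_equal(nrow(prof$table), length(panel) - 1L)
  expect_equal(prof$dropped, panel[[2]]$temperature_C)
})

test_that("the long-format data frame interface matches the list interface", {
  panel <- simulate_inactivation_panel(sd = 0, seed = 1)
  long <- do.call(rbind, lapply(panel, function(p)
    data.frame(temperature_C = p$temperature_C, time_min = p$time_min,
               fraction = p$fraction)))
  expect_equal(inactivation_profile(long)$table,
               inactivation_profile(panel)$table)
})
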