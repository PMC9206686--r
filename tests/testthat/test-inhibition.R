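test_that("noiseless canonical series classify as their generating mechanism", {
  for (m in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    ser <- simulate_inhibition_series(m, sd_frac = 0, seed = 1)
    v <- classify_inhibition_mode(ser)
    expect_equal(v$mode, m)
  }
})

test_that("apparent parameters follow the mechanistic closed forms", {
  # noncompetitive at [I] = Ki halves Vmax, Km untouched
  ser <- simulate_inhibition_series("noncompetitive", Km = 2, Vmax = 50,
                                    Ki = 0.5, inhibitor_conc = c(0, 0.5),
                                    sd_frac = 0, seed = 1)
  fits <- fit_inhibition_series(ser)
  expect_equal(fits$fits[[2]]$Vmax, 25, tolerance = 1e-5)
  expect_equal(fits$fits[[2]]$Km, 2, tolerance = 1e-5)
  # competitive at [I] = Ki doubles Km
  ser2 <- simulate_inhibition_series("competitive", Km = 2, Vmax = 50,
                                     Ki = 0.5, inhibitor_conc = c(0, 0.5),
                                     sd_frac = 0, seed = 1)
  fits2 <- fit_inhibition_series(ser2)
  expect_equal(fits2$fits[[2]]$Km, 4, tolerance = 1e-5)
  expect_equal(fits2$fits[[2]]$Vmax, 50, tolerance = 1e-5)
})

test_that("series preconditions are enforced", {
  ser <- simulate_inhibition_series("competitive", sd_frac = 0, seed = 1)
  expect_error(fit_inhibition_series(ser[ser$inhibitor_conc > 0, ]), "no control")
  expect_error(fit_inhibition_series(ser[ser$inhibitor_conc == 0, ]),
               "no inhibitor data")
  expect_error(simulate_inhibition_series("cooperative"), "invalid mechanism")
})

test_that("line intersections follow the closed-form algebra", {
  mkfit <- function(Km, Vmax) {
    d <- mm_exact(Km, Vmax)
    fit_michaelis_menten(d)
  }
  # identical Km, different Vmax: crossing on the x-axis at -1/Km
  g <- lb_intersections(list(mkfit(2, 50), mkfit(2, 25)))
  expect_equal(g$intersections$x, -0.5, tolerance = 1e-6)
  expect_equal(g$intersections$y, 0, tolerance = 1e-8)
  expect_equal(g$intersections$label, "on x-axis")
  # identical Vmax, different Km: crossing on the y-axis at 1/Vmax
  g2 <- lb_intersections(list(mkfit(2, 50), mkfit(4, 50)))
  expect_equal(g2$intersections$x, 0, tolerance = 1e-8)
  expect_equal(g2$intersections$y, 1 / 50, tolerance = 1e-6)
  expect_equal(g2$intersections$label, "on y-axis")
  # proportional (Km, Vmax): parallel lines (uncompetitive signature)
  g3 <- lb_intersections(list(mkfit(2, 50), mkfit(1, 25)))
  expect_equal(g3$intersections$label, "parallel")
})

test_that("closed-form intersections agree with a fine-grid crossing search", {
  f1 <- fit_michaelis_menten(mm_exact(2, 50))
  f2 <- fit_michaelis_menten(mm_exact(3, 30))
  g <- lb_intersections(list(f1, f2))
  line <- function(f, x) (f$Km / f$Vmax) * x + 1 / f$Vmax
  xs <- seq(-2, 2, length.out = 4e6)
  gap <- line(f1, xs) - line(f2, xs)
  x_cross <- xs[which.min(abs(gap))]
  expect_lt(abs(g$intersections$x - x_cross), 1e-6)
  expect_lt(abs(g$intersections$y - line(f1, x_cross)), 1e-6)
})

test_that("verdict is invariant to reordering of inhibitor levels", {
  ser <- simulate_inhibition_series("mixed", sd_frac = 0.02, seed = 7)
  shuffled <- ser[rev(seq_len(nrow(ser))), ]
  expect_equal(classify_inhibition_mode(ser)$mode,
               classify_inhibition_mode(shuffled)$mode)
})

test_that("identical kinetics at all levels give verdict none", {
  d0 <- mm_exact(2, 50)
  ser <- do.call(rbind, lapply(c(0, 0.5, 1), function(I)
    cbind(inhibitor_conc = I, d0)))
  expect_equal(classify_inhibition_mode(ser)$mode, "none")
})

test_that("classification matches the published shift patterns", {
  # Vmax falls, Km steady: the maltose-like noncompetitive signature
  ser <- simulate_inhibition_series("noncompetitive", Km = 2, Vmax = 50,
                                    Ki = 1, sd_frac = 0, seed = 1)
  expect_equal(classify_inhibition_mode(ser)$mode, "noncompetitive")
  # both Km and Vmax shifted: the fructose/lactose-like mixed signature
  ser2 <- simulate_inhibition_series("mixed", sd_frac = 0, seed = 1)
  v2 <- classify_inhibition_mode(ser2)
  expect_equal(v2$mode, "mixed")
  hi <- nrow(v2$parameters)
  expect_gt(abs(v2$parameters$Km_shift[hi]), 0.10)
  expect_gt(abs(v2$parameters$Vmax_shift[hi]), 0.10)
})

test_that("a failing sub-fit yields an indeterminate verdict naming the level", {
  ser <- simulate_inhibition_series("competitive", sd_frac = 0, seed = 1)
  # make the top level unfittable: constant velocity
  ser$velocity[ser$inhibitor_conc == 1] <- 10
  expect_warning(v <- classify_inhibition_mode(ser), "fit failed")
  expect_equal(v$mode, "indeterminate")
})
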