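celc_factors <- celc307_rsm_factors()

test_that("Plackett-Burman designs are balanced and orthogonal for all sizes", {
  for (nf in 1:11) {
    pb <- plackett_burman_design(nf)
    m <- as.matrix(pb$coded)
    expect_equal(dim(m), c(12L, 11L))
    expect_equal(unname(colSums(m)), rep(0, 11))          # six +1, six -1
    xtx <- crossprod(m)
    expect_equal(unname(xtx), diag(12, 11))               # pairwise orthogonal
    expect_equal(pb$n_dummy, 11L - nf)
  }
  expect_error(plackett_burman_design(12), "design too small")
})

test_that("effect screen finds a planted main effect and nulls a constant", {
  pb <- plackett_burman_design(7)
  # constant response: all effects vanish
  scr0 <- pb_effect_screen(pb, rep(5, 12))
  expect_equal(scr0$effects$effect, rep(0, 7))
  # planted effect on the first factor equals twice the coded slope
  set.seed(21)
  y <- 2 * pb$coded$F1 + rnorm(12, sd = 0.3)
  scr <- pb_effect_screen(pb, y)
  expect_equal(scr$effects$factor[1], "F1")
  expect_true(scr$effects$significant[1])
  slope <- coef(lm(y ~ pb$coded$F1))[2]
  expect_equal(scr$effects$effect[1], unname(2 * slope), tolerance = 1e-10)
  # no dummy columns: flags unavailable, with warning
  pb11 <- plackett_burman_design(11)
  expect_warning(scr11 <- pb_effect_screen(pb11, y), "no dummy")
  expect_true(all(is.na(scr11$effects$significant)))
})

test_that("the rotatable CCD reproduces the printed axial levels", {
  d <- central_composite_design(celc_factors)
  expect_equal(d$n_runs, 20L)
  cod <- as.matrix(d$coded)
  expect_equal(unname(colMeans(cod)), rep(0, 3), tolerance = 1e-12)
  alpha <- 8^(1 / 4)
  expect_equal(sort(unique(round(cod[, 1], 6))),
               round(c(-alpha, -1, 0, 1, alpha), 6))
  # natural axial levels match the published runs
  nat <- d$natural
  expect_equal(sort(unique(round(nat$pH, 2))), c(3.98, 5, 6.5, 8, 9.02),
               tolerance = 0.01)
  expect_equal(range(nat$temperature), c(30 - 10 * alpha, 30 + 10 * alpha))
  expect_equal(round(range(nat$inoculum_od), 2), c(0.06, 1.24), tolerance = 0.01)
  # two-block split: factorial + 4 centers, axial + 2 centers
  expect_equal(as.vector(table(d$block)), c(12L, 8L))
})

test_that("CCD rotatability: prediction variance depends only on the radius", {
  d <- central_composite_design(celc_factors, blocks = FALSE)
  X <- stats::model.matrix(~ A + B + C + A:B + A:C + B:C + I(A^2) + I(B^2) + I(C^2),
                           data = stats::setNames(d$coded, c("A", "B", "C")))
  XtXi <- solve(crossprod(X))
  set.seed(99)
  r <- 1.2
  h <- replicate(100, {
    u <- rnorm(3); u <- r * u / sqrt(sum(u^2))
    f <- c(1, u, u[1] * u[2], u[1] * u[3], u[2] * u[3], u^2)
    # model.matrix column order: 1, A, B, C, A2, B2, C2, AB, AC, BC
    f <- f[c(1, 2, 3, 4, 8, 9, 10, 5, 6, 7)]
    drop(t(f) %*% XtXi %*% f)
  })
  expect_lt(diff(range(h)), 1e-6)
})

test_that("Box-Behnken runs sit on edge midpoints with no corners", {
  d <- box_behnken_design(celc_factors, n_center = 3)
  cod <- as.matrix(d$coded)
  expect_equal(nrow(cod), 15L)
  non_center <- cod[rowSums(cod != 0) > 0, ]
  expect_true(all(rowSums(non_center == 0) == 1))   # one factor at 0 each
  expect_true(all(rowSums(abs(non_center)) == 2))   # the other two at +/-1
  expect_equal(unname(colSums(cod)), rep(0, 3))     # balance
})

test_that("a noiseless quadratic is recovered exactly with zero residual", {
  d <- central_composite_design(celc_factors)
  truth <- celc307_quadratic_coefficients()
  y <- simulate_doe_response(d, truth, block_effects = 0, sd = 0, seed = 1)
  fit <- fit_response_surface(d, y, include_block = FALSE)
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-6)
  resid_row <- fit$anova[fit$anova$source == "Residual", ]
  expect_equal(resid_row$SS, 0, tolerance = 1e-8)
})

test_that("ANOVA sums of squares and degrees of freedom partition exactly", {
  d <- celc307_rsm_runs()
  fit <- fit_response_surface(d[, c("pH", "temperature", "inoculum_od")],
                              d$activity, block = d$block)
  a <- fit$anova
  g <- function(s) a[a$source == s, ]
  # SS(block) + SS(model) + SS(residual) = SS(corrected total)
  expect_equal(g("Block")$SS + g("Model")$SS + g("Residual")$SS,
               g("Cor total")$SS, tolerance = 1e-8)
  # SS(lack of fit) + SS(pure error) = SS(residual)
  expect_equal(g("Lack of fit")$SS + g("Pure error")$SS, g("Residual")$SS,
               tolerance = 1e-10)
  # df bookkeeping sums to n - 1
  expect_equal(g("Block")$df + g("Model")$df + g("Residual")$df,
               g("Cor total")$df)
  expect_equal(g("Lack of fit")$df + g("Pure error")$df, g("Residual")$df)
  # independent recomputation of the totals from definitions
  expect_equal(g("Cor total")$SS, sum((d$activity - mean(d$activity))^2))
  centers1 <- d$activity[d$run %in% c(3, 5, 9, 12)]
  centers2 <- d$activity[d$run %in% c(16, 17)]
  expect_equal(g("Pure error")$SS,
               sum((centers1 - mean(centers1))^2) + sum((centers2 - mean(centers2))^2),
               tolerance = 1e-10)
})

test_that("coefficient recovery stays inside its interval the expected fraction", {
  d <- central_composite_design(celc_factors)
  truth <- celc307_quadratic_coefficients()
  covered <- matrix(NA, 100, 10)
  for (i in 1:100) {
    y <- simulate_doe_response(d, truth, sd = 1, seed = 7000 + i)
    fit <- fit_response_surface(d, y, include_block = FALSE)
    ci <- suppressMessages(stats::confint(fit$model))
    rn <- rownames(ci)
    rn[rn == "(Intercept)"] <- "intercept"
    rn <- sub("I\\(A\\^2\\)", "A2", rn); rn <- sub("I\\(B\\^2\\)", "B2", rn)
    rn <- sub("I\\(C\\^2\\)", "C2", rn)
    rn <- sub("^A:B$", "AB", rn); rn <- sub("^A:C$", "AC", rn); rn <- sub("^B:C$", "BC", rn)
    rownames(ci) <- rn
    covered[i, ] <- truth[rn] >= ci[, 1] & truth[rn] <= ci[, 2]
  }
  expect_true(all(colMeans(covered) >= 0.90))
})

test_that("optimization returns interior maxima exactly and corner optima for linear models", {
  # concave paraboloid centered in bounds
  d <- central_composite_design(celc_factors)
  cf <- c(intercept = 0, A = 13, B = 6, C = 13, AB = 0, AC = 0, BC = 0,
          A2 = -1, B2 = -0.1, C2 = -10)
  y <- simulate_doe_response(d, cf, sd = 0, seed = 1)
  fit <- fit_response_surface(d, y, include_block = FALSE)
  opt <- optimize_response(fit, list(c(5, 8), c(20, 40), c(0.3, 1)))
  expect_equal(opt$stationary_kind, "maximum")
  expect_equal(unname(opt$optimum), c(6.5, 30, 0.65), tolerance = 1e-6)
  # pure linear model: optimum at a box corner
  cf_lin <- c(intercept = 0, A = 1, B = -1, C = 2, AB = 0, AC = 0, BC = 0,
              A2 = 0, B2 = 0, C2 = 0)
  y2 <- simulate_doe_response(d, cf_lin, sd = 0, seed = 1)
  fit2 <- fit_response_surface(d, y2, include_block = FALSE)
  opt2 <- optimize_response(fit2, list(c(5, 8), c(20, 40), c(0.3, 1)))
  expect_equal(unname(opt2$optimum), c(8, 20, 1), tolerance = 1e-6)
  expect_true(opt2$on_boundary)
})

test_that("the published polynomial predicts ~55.7 at its boundary optimum", {
  d <- celc307_rsm_runs()
  y_pub <- simulate_doe_response(d[, c("pH", "temperature", "inoculum_od")],
                                 celc307_quadratic_coefficients(), sd = 0)
  fit <- fit_response_surface(d[, c("pH", "temperature", "inoculum_od")], y_pub,
                              include_block = FALSE)
  opt <- optimize_response(fit, list(c(5, 8), c(20, 40), c(0.3, 1)))
  expect_equal(unname(opt$optimum[2:3]), c(20, 1), tolerance = 1e-6)
  expect_equal(opt$predicted, 55.7, tolerance = 0.002)
  # the originally reported prediction was 58.4; the polynomial itself
  # cannot exceed ~55.7 on these bounds, which the optimizer makes visible
  expect_lt(opt$predicted, 58.4)
})
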