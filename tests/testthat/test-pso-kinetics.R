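test_that("pso_predict honours its boundary conditions and reported magnitudes", {
  expect_equal(pso_predict(100, 1e-3, 0), 0)
  # saturation limit
  expect_equal(pso_predict(100, 1e-3, 1e9), 100, tolerance = 1e-4)
  # hand evaluation at the reported 50 degC parameters, t = 80 min
  expect_equal(pso_predict(159.15, 12.3074e-4, 80), 149.6, tolerance = 1e-3)
  expect_error(pso_predict(100, 1e-3, -1), "non-negative")
  expect_error(pso_predict(-1, 1e-3, 10), "> 0")
})

test_that("pso_predict is monotone increasing in t, cs and k", {
  t_grid <- seq(1, 200, length.out = 40)
  expect_true(all(diff(pso_predict(150, 1e-3, t_grid)) > 0))
  cs_grid <- seq(50, 250, length.out = 30)
  expect_true(all(diff(vapply(cs_grid, pso_predict, numeric(1),
                              k = 1e-3, times = 40)) > 0))
  k_grid <- seq(1e-4, 5e-3, length.out = 30)
  expect_true(all(diff(vapply(k_grid, function(k) pso_predict(150, k, 40),
                              numeric(1))) > 0))
})

test_that("t / Ct is exactly affine in t (linearization identity)", {
  set.seed(11)
  for (i in 1:20) {
    cs <- runif(1, 50, 250)
    k <- runif(1, 1e-4, 5e-3)
    t <- sort(runif(6, 1, 120))
    z <- t / pso_predict(cs, k, t)
    # second divided differences of an affine function vanish
    slopes <- diff(z) / diff(t)
    expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-10)
    expect_equal(slopes[1], 1 / cs, tolerance = 1e-10)
  }
})

test_that("fit_pso_linearized recovers exact curves to near machine precision", {
  fit <- fit_pso_linearized(pso_curve(100, 1e-3))
  expect_equal(fit$cs, 100, tolerance = 1e-10)
  expect_equal(fit$k, 1e-3, tolerance = 1e-10)
  expect_equal(fit$h, fit$k * fit$cs^2, tolerance = 1e-10)

  fit <- fit_pso_linearized(pso_curve(159.15, 12.3074e-4))
  expect_equal(fit$quality$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$quality$mse, 0, tolerance = 1e-9)
})

test_that("fit_pso_linearized matches an explicit normal-equations oracle on noisy data", {
  set.seed(5)
  times <- seq(10, 80, 10)
  ct <- pso_predict(150, 1e-3, times) + rnorm(length(times), 0, 1)
  fit <- fit_pso_linearized(extraction_curve(times, ct, 50))
  ora <- ols_oracle(times, times / ct)
  expect_equal(fit$cs, 1 / ora[["slope"]], tolerance = 1e-10)
  expect_equal(fit$k, ora[["slope"]]^2 / ora[["intercept"]], tolerance = 1e-10)
})

test_that("fit_pso_linearized flags inadequate data", {
  expect_error(fit_pso_linearized(extraction_curve(c(10, 20), c(50, 80), 50)),
               "fewer than 3")
  # a decreasing curve yields a negative linearization slope
  bad <- extraction_curve(seq(10, 80, 10), seq(80, 10, -10), 50)
  expect_error(fit_pso_linearized(bad), "inadequate")
})

test_that("nonlinear refinement stays near the optimum and cannot worsen the concentration-scale fit", {
  # tiny noise: the linearized estimate is already near the NLS optimum, so
  # the refinement must stay close (exact zero-residual data would make the
  # nls gradient singular, which the fitter reports by keeping the
  # linearized estimate)
  set.seed(20)
  times <- seq(10, 80, 10)
  near <- extraction_curve(times, pso_predict(150, 1e-3, times) +
                             rnorm(8, 0, 0.01), 50)
  lin <- fit_pso_linearized(near)
  ref <- fit_pso_linearized(near, refine = TRUE)
  expect_equal(ref$estimator, "nls-refined")
  expect_equal(ref$cs, lin$cs, tolerance = 1e-3)
  expect_equal(ref$k, lin$k, tolerance = 1e-2)

  set.seed(21)
  times <- seq(10, 80, 10)
  noisy <- extraction_curve(times, pmax(pso_predict(150, 1e-3, times) +
                                          rnorm(8, 0, 2), 0), 50)
  ref2 <- fit_pso_linearized(noisy, refine = TRUE)
  # the refinement minimizes concentration-scale SSE, so it can only improve it
  lin2 <- fit_pso_linearized(noisy)
  expect_lte(ref2$quality$mse, lin2$quality$mse + 1e-12)
})

test_that("initial_rate is k * cs^2", {
  expect_equal(initial_rate(1, 2), 4)
  expect_equal(initial_rate(12.3074e-4, 159.15), 31.17, tolerance = 1e-3)
  expect_error(initial_rate(0, 100), "> 0")
})

test_that("fit_arrhenius inverts exact lines and matches the OLS oracle", {
  # exact two-point construction: ln k = ln 2 - 1000 / T
  Tc <- c(27, 77) # 300, 350 K
  k <- 2 * exp(-1000 / celsius_to_kelvin(Tc))
  fit <- fit_arrhenius(Tc, k)
  expect_equal(fit$ea, 1000 * 8.314, tolerance = 1e-8)
  expect_equal(fit$k0, 2, tolerance = 1e-8)

  # ascending branch of the reported rate constants (30-50 degC)
  Tc <- c(30, 40, 50)
  k <- c(8.2876, 10.1101, 12.3074) * 1e-4
  fit <- fit_arrhenius(Tc, k)
  ora <- ols_oracle(1 / celsius_to_kelvin(Tc), log(k))
  expect_equal(fit$ea, -ora[["slope"]] * 8.314, tolerance = 1e-10)
  expect_equal(fit$k0, exp(ora[["intercept"]]), tolerance = 1e-10)
  expect_equal(fit$ea, 1.6e4, tolerance = 0.01) # apparent Ea ~ 16 kJ/mol

  expect_error(fit_arrhenius(50, 1e-3), "distinct")
  expect_error(fit_arrhenius(c(30, 40), c(1e-3, -1e-3)), "> 0")
})
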