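test_that("crank_y reproduces hand-computed partial sums", {
  # t = 0: Basel partial sum (6/pi^2) * sum_{1..10} n^-2
  expect_equal(crank_y(1e-12, 1.25e-4, 0, n_terms = 10), 0.9421, tolerance = 1e-4)
  # reported 50 degC diffusivity at t = 3000 s: Fourier number ~ 0.244,
  # only the first term survives
  expect_equal(crank_y(12.690e-13, 1.25e-4, 3000, n_terms = 10), 0.0549,
               tolerance = 1e-3)
  expect_error(crank_y(-1e-13, 1.25e-4, 10), ">= 0")
  expect_error(crank_y(1e-13, 0, 10), "> 0")
})

test_that("crank_y(t = 0) increases toward 1 with the truncation order", {
  vals <- vapply(c(1, 2, 5, 10, 50, 200, 5000), function(n) {
    crank_y(1e-12, 1.25e-4, 0, n_terms = n)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # Basel sum: the tail of (6/pi^2) sum n^-2 decays like (6/pi^2)/n
  expect_equal(vals[length(vals)], 1, tolerance = 2e-4)
})

test_that("crank_y is monotone non-increasing in time and diffusivity", {
  t <- seq(0, 5000, length.out = 50)
  y <- crank_y(1e-12, 1.25e-4, t, n_terms = 20)
  expect_true(all(diff(y) < 0))
  de_grid <- seq(1e-13, 5e-12, length.out = 30)
  yd <- vapply(de_grid, crank_y, numeric(1), radius = 1.25e-4,
               time_seconds = 1200, n_terms = 20)
  expect_true(all(diff(yd) < 0))
})

test_that("series truncation: 10 and 20 terms coincide beyond Fourier number 0.01", {
  R <- 1.25e-4
  de <- 1e-12
  t <- seq(0.01, 1, length.out = 40) * R^2 / de # Fourier numbers 0.01..1
  expect_lt(max(abs(crank_y(de, R, t, 10) - crank_y(de, R, t, 20))), 1e-6)
})

test_that("unaccomplished_ratio transforms concentrations and units", {
  cv <- extraction_curve(c(10, 20, 30), c(0, 75, 100), 50)
  ys <- unaccomplished_ratio(cv, c_inf = 100, c0 = 0)
  expect_equal(ys$time_s, c(600, 1200, 1800))
  expect_equal(ys$y, c(1, 0.25, 0))
  expect_error(unaccomplished_ratio(cv, c_inf = 0), "exceed")
  # points above c_inf are dropped with a warning
  expect_warning(ys2 <- unaccomplished_ratio(cv, c_inf = 90), "dropped")
  expect_equal(nrow(ys2), 2)
})

test_that("fit_de recovers a noise-free diffusivity and mirrors the truncation study", {
  R <- 1.25e-4
  truth <- 1e-12
  t_s <- seq(10, 80, 10) * 60
  ys <- data.frame(time_s = t_s, y = crank_y(truth, R, t_s, n_terms = 10))
  fit10 <- fit_de(ys, radius = R, n_terms = 10)
  expect_equal(fit10$de, truth, tolerance = 1e-6)
  expect_equal(fit10$quality$r_squared, 1, tolerance = 1e-9)

  fit20 <- fit_de(ys, radius = R, n_terms = 20)
  expect_equal(fit20$de, fit10$de, tolerance = 1e-6)

  # the 1-term fit cannot represent the short-time data and lands elsewhere
  fit1 <- fit_de(ys, radius = R, n_terms = 1)
  expect_gt(abs(fit1$de - truth) / truth, 1e-3)
  expect_lt(fit1$de, fit10$de) # biased low, as in the reported tables
})

test_that("fit_de agrees with a brute-force grid-search oracle", {
  R <- 1.25e-4
  set.seed(3)
  t_s <- seq(10, 80, 10) * 60
  y <- crank_y(8.7e-13, R, t_s, 10) + rnorm(8, 0, 0.01)
  ys <- data.frame(time_s = t_s, y = pmin(pmax(y, 1e-9), 1))
  fit <- fit_de(ys, radius = R, n_terms = 10)
  grid <- seq(1e-13, 5e-12, length.out = 1000)
  sse <- vapply(grid, function(de) {
    sum((ys$y - crank_y(de, R, t_s, 10))^2)
  }, numeric(1))
  expect_equal(fit$de, grid[which.min(sse)],
               tolerance = 2 * diff(grid[1:2]) / grid[which.min(sse)])
})

test_that("fit_de rejects out-of-domain points and degenerate series", {
  R <- 1.25e-4
  t_s <- seq(10, 80, 10) * 60
  y <- crank_y(1e-12, R, t_s, 10)
  y[1] <- 1.2
  expect_warning(fit <- fit_de(data.frame(time_s = t_s, y = y), radius = R),
                 "rejected")
  expect_equal(fit$de, 1e-12, tolerance = 1e-4)
  expect_error(fit_de(data.frame(time_s = t_s[1:4], y = rep(0.5, 4)), radius = R),
               "identical")
  expect_error(fit_de(data.frame(time_s = t_s[1:2], y = c(0.9, 0.5)), radius = R),
               "fewer than 3")
})

test_that("bootstrap_de is degenerate on perfect data and reproducible by seed", {
  R <- 1.25e-4
  t_s <- seq(10, 80, 10) * 60
  ys <- data.frame(time_s = t_s, y = crank_y(1e-12, R, t_s, 10))
  fit <- fit_de(ys, radius = R, n_terms = 10)
  bt <- bootstrap_de(fit, n_iterations = 50, seed = 4)
  expect_equal(bt$standard_error, 0, tolerance = 1e-18)
  expect_equal(bt$ci_low, fit$de, tolerance = 1e-8)
  expect_equal(bt$ci_high, fit$de, tolerance = 1e-8)

  ysn <- generate_diffusion_dataset(de_by_temperature = 1e-12,
                                    noise_sd_y = 0.01, seed = 9)[[1]]
  fitn <- fit_de(ysn, radius = R, n_terms = 10)
  b1 <- bootstrap_de(fitn, n_iterations = 200, seed = 123)
  b2 <- bootstrap_de(fitn, n_iterations = 200, seed = 123)
  expect_identical(b1$distribution, b2$distribution)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  # percentile construction brackets the median draw
  med <- median(b1$distribution)
  expect_true(b1$ci_low <= med && med <= b1$ci_high)
  # bootstrap_de does not disturb the caller's RNG stream
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(bootstrap_de(fitn, n_iterations = 20, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("leverage-modified resampling widens the interval against small-sample deflation", {
  R <- 1.25e-4
  ys <- generate_diffusion_dataset(de_by_temperature = 1e-12,
                                   noise_sd_y = 0.01, seed = 61)[[1]]
  fit <- fit_de(ys, radius = R, n_terms = 10)
  plain <- bootstrap_de(fit, n_iterations = 400, seed = 62)
  adj <- bootstrap_de(fit, n_iterations = 400, seed = 62,
                      leverage_adjust = TRUE)
  # modified residuals e/sqrt(1 - h) have inflated spread, so the bootstrap
  # SE and interval can only grow
  expect_gt(adj$standard_error, plain$standard_error)
  expect_gt(adj$ci_high - adj$ci_low, plain$ci_high - plain$ci_low)
})

test_that("bootstrap SE grows with the noise level", {
  R <- 1.25e-4
  ses <- vapply(c(0.005, 0.01, 0.02), function(sig) {
    ys <- generate_diffusion_dataset(de_by_temperature = 1e-12,
                                     noise_sd_y = sig, seed = 31)[[1]]
    fit <- fit_de(ys, radius = R, n_terms = 10)
    bootstrap_de(fit, n_iterations = 300, seed = 32)$standard_error
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("Gauss-Newton bootstrap refit agrees with a constrained nls refit", {
  R <- 1.25e-4
  ys <- generate_diffusion_dataset(de_by_temperature = 9e-13,
                                   noise_sd_y = 0.01, seed = 15)[[1]]
  fit <- fit_de(ys, radius = R, n_terms = 10)
  # refit one pseudo-dataset both ways
  set.seed(8)
  eps <- fit$residuals - mean(fit$residuals)
  y_star <- fit$fitted + sample(eps, replace = TRUE)
  kap_gn <- phenolkin:::gauss_newton_kappa(fit$time_s, y_star, fit$kappa, 10)
  refit <- fit_de(data.frame(time_s = fit$time_s, y = y_star),
                  radius = R, n_terms = 10)
  expect_equal(kap_gn * R^2, refit$de, tolerance = 1e-6)
})
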