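# Effective diffusivity from Crank's series solution of Fick's second law
# in a sphere.
#
# For a sphere of radius R with uniform initial solute and a perfectly
# mixed bath, the volume-averaged unaccomplished ratio
#   y(t) = (Cinf - C(t)) / (Cinf - C0)
# follows
#   y(t) = (6/pi^2) * sum_{n>=1} n^-2 exp(-n^2 pi^2 De t / R^2),
# truncated at `n_terms`. The fit works on the well-scaled rate
# kappa = De / R^2 (1/s) and transforms back, with the physical constraint
# De >= 0 imposed through the "port" algorithm of nls(). Uncertainty comes
# from a residual-resampling bootstrap: centered residuals are resampled
# onto the fitted curve and kappa is refitted with an unbounded fast local
# Gauss-Newton started at the full-data estimate (negative draws truncated
# to 0), giving the bootstrap SE and the 95% percentile interval of
# De* = kappa* R^2.

# Series evaluated on the kappa = De/R^2 scale; vectorized over time.
crank_y_kappa <- function(kappa, time_seconds, n_terms) {
  n <- seq_len(n_terms)
  # outer(t, n^2): |t| x |n| matrix of exponents
  E <- exp(-outer(time_seconds, n^2) * (pi^2 * kappa))
  drop(6 / pi^2 * (E %*% (1 / n^2)))
}

# d y / d kappa, used by the Gauss-Newton refit.
crank_dy_dkappa <- function(kappa, time_seconds, n_terms) {
  n <- seq_len(n_terms)
  E <- exp(-outer(time_seconds, n^2) * (pi^2 * kappa))
  drop(-6 * time_seconds * (E %*% rep(1, n_terms)))
}

#' Crank sphere-diffusion series: unaccomplished ratio
#'
#' Evaluates the truncated series solution for the volume-averaged
#' unaccomplished extraction ratio of a sphere. Monotone non-increasing in
#' both time and diffusivity; equals the Basel partial sum
#' (6/pi^2) sum(1/n^2) at t = 0, which approaches 1 as `n_terms` grows.
#'
#' @param de Effective diffusivity De in m^2/s (>= 0).
#' @param radius Particle radius in metres (> 0).
#' @param time_seconds Times in seconds (>= 0); vectorized.
#' @param n_terms Number of series terms (>= 1). Ten terms suffice for
#'   Fourier numbers De*t/R^2 >= 0.01; a single term underestimates y at
#'   short times.
#' @return The unaccomplished ratio y(t).
#' @export
#' @examples
#' crank_y(12.690e-13, 1.25e-4, 3000, n_terms = 10) # ~ 0.0549
crank_y <- function(de, radius, time_seconds, n_terms = 10) {
  if (de < 0) stop_pk("`de` must be >= 0", "phenolkin_validation_error")
  if (radius <= 0) stop_pk("`radius` must be > 0", "phenolkin_validation_error")
  if (any(time_seconds < 0)) {
    stop_pk("`time_seconds` must be non-negative", "phenolkin_validation_error")
  }
  if (n_terms < 1) stop_pk("`n_terms` must be >= 1", "phenolkin_validation_error")
  crank_y_kappa(de / radius^2, time_seconds, as.integer(n_terms))
}

#' Unaccomplished ratio series from an extraction curve
#'
#' Transforms measured concentrations to y_i = (Cinf - Ct_i)/(Cinf - C0)
#' and times from minutes to seconds, the form fitted by [fit_de()].
#' `c_inf` is conventionally the pseudo-second-order saturation
#' concentration fitted at the same temperature (the maximum extractable
#' concentration); `c0 = 0` reflects extraction into initially solute-free
#' solvent. Points with Ct > Cinf (y < 0, impossible under the model) are
#' dropped with a warning.
#'
#' @param curve An [extraction_curve()].
#' @param c_inf Equilibrium concentration Cinf (> `c0`).
#' @param c0 Initial concentration, default 0.
#' @return A data frame with columns `time_s` and `y`.
#' @export
unaccomplished_ratio <- function(curve, c_inf, c0 = 0) {
  stopifnot(inherits(curve, "extraction_curve"))
  if (c_inf <= c0) {
    stop_pk("`c_inf` must exceed `c0`", "phenolkin_validation_error")
  }
  y <- (c_inf - curve$concentrations) / (c_inf - c0)
  keep <- y >= 0
  if (any(!keep)) {
    warning(sprintf("%d point(s) with Ct > Cinf dropped (y < 0)", sum(!keep)))
  }
  data.frame(time_s = curve$times[keep] * 60, y = y[keep])
}

# One-term log-linear initializer: ln y ~ ln(6/pi^2) - pi^2 kappa t on the
# tail half of the series, where the first term dominates.
init_kappa <- function(time_s, y) {
  tail_idx <- which(time_s >= stats::median(time_s) & y > 0 & y < 1)
  if (length(tail_idx) >= 2) {
    f <- tryCatch(lm(log(y[tail_idx]) ~ time_s[tail_idx]), error = function(e) NULL)
    if (!is.null(f)) {
      slope <- unname(coef(f)[2])
      if (is.finite(slope) && slope < 0) return(-slope / pi^2)
    }
  }
  1e-5  # robust fallback, 1/s
}

#' Fit the effective diffusivity to an unaccomplished-ratio series
#'
#' Nonlinear least squares of the truncated Crank series against observed
#' y(t). The optimization runs on kappa = De/R^2 (a well-scaled 1/s
#' quantity) with the physical lower bound kappa >= 0 enforced by the
#' "port" algorithm; the estimate is returned as De = kappa * R^2. The
#' starting value comes from a one-term log-linear fit on the tail of the
#' series.
#'
#' @param y_series Data frame with columns `time_s` (seconds) and `y`, as
#'   produced by [unaccomplished_ratio()] or
#'   [generate_diffusion_dataset()]. Points with y outside (0, 1] are
#'   rejected with a warning.
#' @param radius Particle radius in metres.
#' @param n_terms Series truncation (>= 1).
#' @param init_de Optional starting value for De (m^2/s); overrides the
#'   automatic initializer.
#' @return An object of class `diffusion_fit`: `de`, `kappa`, `n_terms`,
#'   `radius`, `quality` (y-scale), `c_inf`, `c0` when known, plus the
#'   data, fitted values and residuals used by [bootstrap_de()].
#' @export
fit_de <- function(y_series, radius = PARTICLE_RADIUS, n_terms = 10,
                   init_de = NULL) {
  if (!is.data.frame(y_series) || !all(c("time_s", "y") %in% names(y_series))) {
    stop_pk("`y_series` must be a data frame with columns `time_s` and `y`",
            "phenolkin_validation_error")
  }
  if (radius <= 0) stop_pk("`radius` must be > 0", "phenolkin_validation_error")
  t_s <- as.numeric(y_series$time_s)
  y <- as.numeric(y_series$y)
  ok <- y > 0 & y <= 1
  if (any(!ok)) {
    warning(sprintf("%d point(s) with y outside (0, 1] rejected", sum(!ok)))
    t_s <- t_s[ok]
    y <- y[ok]
  }
  if (length(y) < 3) {
    stop_pk("fewer than 3 usable points for the diffusion fit",
            "phenolkin_fit_error")
  }
  if (length(unique(y)) == 1) {
    stop_pk("all y values identical; diffusivity is unidentifiable",
            "phenolkin_validation_error")
  }
  n_terms <- as.integer(n_terms)
  kappa0 <- if (!is.null(init_de)) init_de / radius^2 else init_kappa(t_s, y)

  df <- data.frame(t_s = t_s, y = y)
  fit <- tryCatch(
    nls(y ~ crank_y_kappa(kappa, t_s, n_terms), data = df,
        start = list(kappa = kappa0), algorithm = "port", lower = 0,
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # "port" occasionally reports false convergence on flat stretches of the
    # SSE surface; the damped Gauss-Newton path is immune to that stopping
    # rule, so use it as a fallback (projected onto kappa >= 0).
    kappa_hat <- gauss_newton_kappa(t_s, y, kappa0, n_terms)
    if (!is.finite(kappa_hat)) {
      stop_pk(sprintf("diffusivity fit failed to converge: %s",
                      conditionMessage(fit)),
              "phenolkin_fit_error")
    }
    kappa_hat <- max(kappa_hat, 0)
  } else {
    kappa_hat <- unname(coef(fit)[["kappa"]])
  }
  fitted_y <- crank_y_kappa(kappa_hat, t_s, n_terms)
  structure(
    list(de = kappa_hat * radius^2, kappa = kappa_hat, n_terms = n_terms,
         radius = radius, quality = goodness_of_fit(y, fitted_y),
         time_s = t_s, y = y, fitted = fitted_y, residuals = y - fitted_y),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> De = %.4g m^2/s (n_terms = %d, R = %g m, R^2 = %.4f)\n",
              x$de, x$n_terms, x$radius, x$quality$r_squared))
  invisible(x)
}

# Unbounded one-parameter Gauss-Newton least squares for the Crank series,
# with step halving. Fast enough for ~10^5 bootstrap refits in pure R.
gauss_newton_kappa <- function(time_s, y, kappa0, n_terms,
                               max_iter = 50, tol = 1e-10) {
  kappa <- kappa0
  f <- crank_y_kappa(kappa, time_s, n_terms)
  sse <- sum((y - f)^2)
  for (it in seq_len(max_iter)) {
    J <- crank_dy_dkappa(kappa, time_s, n_terms)
    denom <- sum(J^2)
    if (denom <= 0) return(NA_real_)
    step <- sum((y - f) * J) / denom
    # damped update
    lambda <- 1
    repeat {
      kappa_new <- kappa + lambda * step
      f_new <- crank_y_kappa(kappa_new, time_s, n_terms)
      sse_new <- sum((y - f_new)^2)
      if (sse_new <= sse || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (sse_new > sse) return(NA_real_)  # no descent direction found
    moved <- abs(kappa_new - kappa)
    kappa <- kappa_new
    f <- f_new
    sse <- sse_new
    if (moved <= tol * max(abs(kappa), 1e-30)) break
  }
  kappa
}

#' Residual-resampling bootstrap for the effective diffusivity
#'
#' Implements the residual bootstrap for the Crank fit: (i) work on the
#' reparameterized rate kappa = De/R^2; (ii) take the fitted values and
#' residuals of the full-data fit, centering the residuals
#' (e' = e - mean(e)); (iii) form pseudo-data y* = fitted + resampled e';
#' (iv) refit kappa with an unbounded fast local Gauss-Newton started at
#' the full-data estimate (negative refits truncated to 0, consistent with
#' the De >= 0 constraint of the primary fit); (v) repeat `n_iterations`
#' times; (vi) transform draws to De* = kappa* R^2. Returns the bootstrap
#' standard error (SD of the draws) and the 95% percentile interval
#' (2.5/97.5 quantiles, linear interpolation).
#'
#' All resampling indices are drawn up front from one seeded generator, so
#' results are reproducible given `seed` and independent of evaluation
#' order.
#'
#' With few design points the raw residuals of a fitted model are
#' variance-deflated (by the leverage of each point), so the plain recipe
#' above gives slightly anti-conservative intervals; `leverage_adjust =
#' TRUE` resamples the leverage-modified residuals e/sqrt(1 - h) instead
#' (the small-sample correction of the standard residual-resampling
#' literature). The default keeps the plain recipe.
#'
#' @param fit A converged [fit_de()] result.
#' @param n_iterations Number of bootstrap iterations B (default 2000).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param level Confidence level for the percentile interval.
#' @param leverage_adjust Resample leverage-modified residuals
#'   e/sqrt(1 - h) instead of raw residuals (both are centered).
#' @return An object of class `bootstrap_de`: `point_estimate`,
#'   `standard_error`, `ci_low`, `ci_high`, `n_iterations`, `n_failed`,
#'   `seed`, `distribution` (the B accepted De* draws).
#' @export
bootstrap_de <- function(fit, n_iterations = 2000, seed = NULL, level = 0.95,
                         leverage_adjust = FALSE) {
  stopifnot(inherits(fit, "diffusion_fit"))
  if (n_iterations < 1) {
    stop_pk("`n_iterations` must be >= 1", "phenolkin_validation_error")
  }
  n <- length(fit$y)
  res <- fit$residuals
  if (leverage_adjust) {
    J <- crank_dy_dkappa(fit$kappa, fit$time_s, fit$n_terms)
    h <- J^2 / sum(J^2) # hat-matrix diagonal of the linearized model
    res <- res / sqrt(pmax(1 - h, .Machine$double.eps))
  }
  eps <- res - mean(res)
  idx <- with_seed(seed, matrix(sample.int(n, n * n_iterations, replace = TRUE),
                                nrow = n_iterations, byrow = TRUE))
  draws <- rep(NA_real_, n_iterations)
  for (b in seq_len(n_iterations)) {
    y_star <- fit$fitted + eps[idx[b, ]]
    kap <- gauss_newton_kappa(fit$time_s, y_star, fit$kappa, fit$n_terms)
    if (is.finite(kap)) draws[b] <- max(kap, 0)
  }
  failed <- sum(!is.finite(draws))
  if (failed > 0.05 * n_iterations) {
    stop_pk(sprintf("%d of %d bootstrap refits failed (> 5%%)",
                    failed, n_iterations),
            "phenolkin_fit_error")
  }
  de_draws <- draws[is.finite(draws)] * fit$radius^2
  alpha <- (1 - level) / 2
  ci <- unname(quantile(de_draws, c(alpha, 1 - alpha), type = 7))
  structure(
    list(point_estimate = fit$de,
         standard_error = if (length(de_draws) > 1) sd(de_draws) else 0,
         ci_low = ci[1], ci_high = ci[2],
         n_iterations = n_iterations, n_failed = failed, seed = seed,
         distribution = de_draws),
    class = "bootstrap_de"
  )
}

#' @export
print.bootstrap_de <- function(x, ...) {
  cat(sprintf("<bootstrap_de> De = %.4g m^2/s, SE = %.3g, %s CI [%.4g, %.4g] (B = %d, %d failed)\n",
              x$point_estimate, x$standard_error, "95%",
              x$ci_low, x$ci_high, x$n_iterations, x$n_failed))
  invisible(x)
}
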