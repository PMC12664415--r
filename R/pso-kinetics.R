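# Pseudo-second-order (PSO) extraction kinetics.
#
# The dissolution rate is taken proportional to the squared distance from
# saturation, dC/dt = k (Cs - Ct)^2 with C(0) = 0, whose solution is
#   Ct = Cs^2 k t / (1 + Cs k t).
# The model linearizes exactly as t/Ct = 1/(k Cs^2) + t/Cs, so an OLS fit of
# t/Ct on t yields Cs from the slope and the initial extraction rate
# h = k Cs^2 from the intercept. The temperature dependence of k is
# described by the Arrhenius law k = k0 exp(-Ea / (R T)).

#' Predict a pseudo-second-order extraction curve
#'
#' @param cs Saturation concentration Cs (mg GAE/g d.w., > 0).
#' @param k Rate constant (g d.w. / (mg GAE min), > 0).
#' @param times Times in minutes (>= 0); vectorized.
#' @return Concentrations Ct = Cs^2 k t / (1 + Cs k t); 0 at t = 0,
#'   approaching `cs` as t grows.
#' @export
#' @examples
#' pso_predict(159.15, 12.3074e-4, 80) # ~ 149.6
pso_predict <- function(cs, k, times) {
  if (cs <= 0 || k <= 0) {
    stop_pk("`cs` and `k` must be > 0", "phenolkin_validation_error")
  }
  if (any(times < 0)) {
    stop_pk("`times` must be non-negative", "phenolkin_validation_error")
  }
  cs^2 * k * times / (1 + cs * k * times)
}

#' Initial extraction rate
#'
#' h = k Cs^2, the model's rate at t -> 0; characterizes the fast
#' "washing" phase of the biphasic extraction profile.
#'
#' @inheritParams pso_predict
#' @return h in mg GAE / (g d.w. min).
#' @export
initial_rate <- function(k, cs) {
  if (k <= 0 || cs <= 0) {
    stop_pk("`k` and `cs` must be > 0", "phenolkin_validation_error")
  }
  k * cs^2
}

#' Fit the pseudo-second-order model by its exact linearization
#'
#' Regresses t/Ct on t (the model's linear form); slope = 1/Cs and
#' intercept = 1/h give Cs, h, and k = slope^2/intercept. Fit quality
#' (R^2, MSE, RMSE) is computed on the original concentration scale —
#' observed Ct against the model at the fitted parameters — which is the
#' scale on which such fits are conventionally reported.
#'
#' Standard errors of Cs and k are propagated from the OLS slope/intercept
#' covariance by the delta method.
#'
#' @param curve An [extraction_curve()].
#' @param refine If `TRUE`, refine the linearized estimate by direct
#'   nonlinear least squares on the concentration scale (Levenberg-style
#'   `nls`), initialized at the linearized solution.
#' @return An object of class `pso_fit` with fields `cs`, `k`, `h`,
#'   `cs_se`, `k_se`, `quality`, `temperature`, `method`, `replicate`,
#'   `estimator`.
#' @export
fit_pso_linearized <- function(curve, refine = FALSE) {
  stopifnot(inherits(curve, "extraction_curve"))
  t <- curve$times
  ct <- curve$concentrations
  usable <- t > 0 & ct > 0
  if (any(!usable)) {
    dropped <- sum(!usable & t > 0)  # t = 0 is expected and silently excluded
    if (dropped > 0) {
      warning(sprintf("%d point(s) with Ct <= 0 at t > 0 excluded from the linearized fit",
                      dropped))
    }
  }
  t <- t[usable]
  ct <- ct[usable]
  if (length(t) < 3) {
    stop_pk("fewer than 3 usable points (t > 0, Ct > 0) for the linearized fit",
            "phenolkin_fit_error")
  }
  z <- t / ct
  ols <- lm(z ~ t)
  intercept <- unname(coef(ols)[1])   # 1/h
  slope <- unname(coef(ols)[2])       # 1/Cs
  if (slope <= 0 || intercept <= 0) {
    stop_pk("non-positive slope or intercept in the t/Ct vs t regression: the pseudo-second-order model is inadequate for this curve",
            "phenolkin_fit_error")
  }
  cs <- 1 / slope
  k <- slope^2 / intercept
  estimator <- "linearized"

  cs_se <- k_se <- NA_real_
  # vcov warns on zero-residual data ("essentially perfect fit"); the SEs
  # are then ~0 and still valid
  V <- tryCatch(suppressWarnings(vcov(ols)), error = function(e) NULL)
  if (!is.null(V) && all(is.finite(V))) {
    # delta method: cs = 1/b1; k = b1^2/b0 with b0 = intercept, b1 = slope
    cs_se <- sqrt(V[2, 2]) / slope^2
    grad <- c(-slope^2 / intercept^2, 2 * slope / intercept)  # d k / d(b0, b1)
    k_se <- sqrt(drop(t(grad) %*% V %*% grad))
  }

  if (refine) {
    df <- data.frame(t = t, ct = ct)
    nl <- tryCatch(
      nls(ct ~ cs_^2 * k_ * t / (1 + cs_ * k_ * t), data = df,
          start = list(cs_ = cs, k_ = k)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      est <- coef(nl)
      cs <- unname(est["cs_"])
      k <- unname(est["k_"])
      se <- tryCatch(sqrt(diag(vcov(nl))), error = function(e) c(NA_real_, NA_real_))
      cs_se <- unname(se[1])
      k_se <- unname(se[2])
      estimator <- "nls-refined"
    } else {
      warning("nonlinear refinement failed to converge; linearized estimate retained")
    }
  }

  quality <- goodness_of_fit(ct, pso_predict(cs, k, t))
  structure(
    list(cs = cs, k = k, h = initial_rate(k, cs), cs_se = cs_se, k_se = k_se,
         quality = quality, temperature = curve$temperature,
         method = curve$method, replicate = curve$replicate,
         estimator = estimator),
    class = "pso_fit"
  )
}

#' @export
print.pso_fit <- function(x, ...) {
  cat(sprintf("<pso_fit> %s @ %g degC: Cs = %.4f mg/g, k = %.4g g/(mg min), h = %.4g (R^2 = %.4f)\n",
              x$method, x$temperature, x$cs, x$k, x$h, x$quality$r_squared))
  invisible(x)
}

#' Arrhenius fit of rate constants across temperature
#'
#' OLS of ln k on 1/T (T in kelvin via the package's +273 convention):
#' activation energy Ea = -slope * R_gas and pre-exponential factor
#' k0 = exp(intercept).
#'
#' Extraction rate constants are frequently non-monotone over a wide
#' temperature window (thermal degradation sets in at the top of the
#' range); restrict `temperature`/`k` to the ascending branch when an
#' apparent activation energy for the intact-extraction regime is wanted.
#'
#' @param temperature Temperatures in degrees Celsius (>= 2 distinct).
#' @param k Rate constants (> 0), same length.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @return An object of class `arrhenius_fit` with `ea` (J/mol), `k0`, and
#'   `quality` (on the ln k scale).
#' @export
fit_arrhenius <- function(temperature, k, gas_constant = GAS_CONSTANT) {
  temperature <- as.numeric(temperature)
  k <- as.numeric(k)
  if (length(temperature) != length(k)) {
    stop_pk("`temperature` and `k` must have the same length",
            "phenolkin_validation_error")
  }
  if (any(k <= 0)) {
    stop_pk("all rate constants must be > 0", "phenolkin_validation_error")
  }
  if (length(unique(temperature)) < 2) {
    stop_pk("need >= 2 distinct temperatures for an Arrhenius fit",
            "phenolkin_validation_error")
  }
  inv_T <- 1 / celsius_to_kelvin(temperature)
  lnk <- log(k)
  fit <- lm(lnk ~ inv_T)
  slope <- unname(coef(fit)[2])
  quality <- if (length(lnk) > 2) {
    goodness_of_fit(lnk, unname(predict(fit)))
  } else {
    # two points determine the line exactly; R^2 = 1 by construction
    structure(list(r_squared = 1, mse = 0, rmse = 0, n_points = 2L),
              class = "fit_quality")
  }
  structure(
    list(ea = -slope * gas_constant, k0 = exp(unname(coef(fit)[1])),
         quality = quality, n = length(k)),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.4g J/mol, k0 = %.4g (n = %d, R^2 = %.4f)\n",
              x$ea, x$k0, x$n, x$quality$r_squared))
  invisible(x)
}
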