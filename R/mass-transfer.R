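# External (film) mass transfer and the Biot-number diagnostic.
#
# Near-exhaustive first-order depletion of the extractable pool gives the
# log-linear law ln(Cs / (Cs - Ct)) = (KT / Lc) t, so the slope of that
# regression (through the origin, since C(0) = 0) times the characteristic
# length Lc yields the external mass-transfer coefficient KT in m/s. The
# Biot number Bi = KT L / De compares internal diffusion resistance with
# the external film resistance; Bi > 50 marks internal-diffusion control.

#' External mass-transfer coefficient from the log-linear depletion law
#'
#' Regresses ln(Cs/(Cs - Ct)) on time in seconds, through the origin
#' (exact at t = 0 when extraction starts from solute-free solvent), and
#' scales the slope (1/s) by the characteristic length to get KT in m/s.
#' Points with Ct >= Cs (outside the log domain) are dropped with a
#' warning.
#'
#' @param curve An [extraction_curve()] (times in minutes).
#' @param cs Saturation concentration (> 0), typically the
#'   pseudo-second-order Cs at the same temperature.
#' @param characteristic_length Lc in metres; defaults to the sphere's
#'   volume-to-surface ratio `radius / 3`.
#' @param radius Particle radius used for the Lc default.
#' @param intercept If `TRUE`, fit with a free intercept instead of through
#'   the origin.
#' @return An object of class `mass_transfer_fit` with `kt` (m/s),
#'   `slope` (1/s), `characteristic_length`, `quality`, `temperature`,
#'   `method`.
#' @export
fit_kt <- function(curve, cs, characteristic_length = NULL,
                   radius = PARTICLE_RADIUS, intercept = FALSE) {
  stopifnot(inherits(curve, "extraction_curve"))
  if (!is.numeric(cs) || cs <= 0) {
    stop_pk("`cs` must be > 0", "phenolkin_validation_error")
  }
  lc <- characteristic_length %||% (radius / 3)
  if (lc <= 0) {
    stop_pk("`characteristic_length` must be > 0", "phenolkin_validation_error")
  }
  t_s <- curve$times * 60
  ct <- curve$concentrations
  ok <- ct < cs & t_s > 0
  if (any(ct >= cs)) {
    warning(sprintf("%d point(s) with Ct >= Cs dropped (outside the log domain)",
                    sum(ct >= cs)))
  }
  t_s <- t_s[ok]
  ct <- ct[ok]
  if (length(t_s) < 3) {
    stop_pk("fewer than 3 usable points (0 < Ct < Cs) for the mass-transfer fit",
            "phenolkin_fit_error")
  }
  z <- log(cs / (cs - ct))
  if (all(z == 0)) {
    stop_pk("all concentrations are zero: no mass transfer to fit",
            "phenolkin_validation_error")
  }
  if (intercept) {
    f <- lm(z ~ t_s)
    slope <- unname(coef(f)[2])
    zhat <- unname(predict(f))
  } else {
    f <- lm(z ~ t_s - 1)
    slope <- unname(coef(f)[1])
    zhat <- slope * t_s
  }
  if (slope <= 0) {
    stop_pk("non-positive depletion slope: no net transfer detected",
            "phenolkin_fit_error")
  }
  structure(
    list(kt = slope * lc, slope = slope, characteristic_length = lc,
         quality = goodness_of_fit(z, zhat),
         temperature = curve$temperature, method = curve$method),
    class = "mass_transfer_fit"
  )
}

#' @export
print.mass_transfer_fit <- function(x, ...) {
  cat(sprintf("<mass_transfer_fit> KT = %.4g m/s (Lc = %.4g m, R^2 = %.4f)\n",
              x$kt, x$characteristic_length, x$quality$r_squared))
  invisible(x)
}

#' Biot number for solid-liquid extraction
#'
#' Bi = KT * L / De, the ratio of internal diffusion resistance to
#' external film resistance. The characteristic length `length` is by
#' convention the particle diameter 2R in this package's reporting (the
#' convention under which the published transport tables for this system
#' are internally consistent); pass R to use the radius convention.
#'
#' @param kt External mass-transfer coefficient, m/s (> 0).
#' @param length Characteristic length, metres (> 0).
#' @param de Effective diffusivity, m^2/s (> 0).
#' @return The dimensionless Biot number.
#' @export
#' @examples
#' biot_number(5.4194e-6, 2.5e-4, 8.728e-13) # ~ 1553
biot_number <- function(kt, length, de) {
  if (any(de <= 0)) stop_pk("`de` must be > 0", "phenolkin_domain_error")
  if (any(kt <= 0) || any(length <= 0)) {
    stop_pk("`kt` and `length` must be > 0", "phenolkin_validation_error")
  }
  kt * length / de
}

#' Classify the rate-limiting mass-transfer step
#'
#' Internal diffusion controls the extraction when Bi > 50 (strict);
#' otherwise the external film does.
#'
#' @param biot Biot number (> 0); vectorized.
#' @return `"internal-diffusion-limited"` or `"external-transfer-limited"`.
#' @export
classify_rate_limit <- function(biot) {
  if (any(biot <= 0)) stop_pk("`biot` must be > 0", "phenolkin_validation_error")
  ifelse(biot > 50, "internal-diffusion-limited", "external-transfer-limited")
}
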