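# Spectrophotometric assay quantification: Folin-Ciocalteu total phenolics
# (gallic-acid equivalents), aluminium chloride total flavonoids (catechin
# equivalents), and DPPH radical-scavenging activity.

#' Fit a linear standard curve
#'
#' Ordinary least squares of absorbance on standard concentration
#' (forward calibration); the inverse map is applied analytically when
#' quantifying samples, avoiding any regression-direction ambiguity.
#'
#' @param concentration Standard concentrations in mg/L (>= 2 distinct).
#' @param absorbance Measured absorbances, same length.
#' @param analyte Label for the standard, e.g. `"gallic-acid"` or
#'   `"catechin"`.
#' @return An object of class `calibration` with `slope` (absorbance per
#'   mg/L), `intercept`, `r_squared`, `analyte` and the concentration
#'   `range` of the standards.
#' @export
#' @examples
#' fit_calibration(c(200, 600, 1000), c(0.2, 0.6, 1.0))
fit_calibration <- function(concentration, absorbance, analyte = "gallic-acid") {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) != length(absorbance) || length(concentration) < 2) {
    stop_pk("need >= 2 (concentration, absorbance) pairs of equal length",
            "phenolkin_validation_error")
  }
  if (length(unique(concentration)) < 2) {
    stop_pk("calibration requires >= 2 distinct standard concentrations",
            "phenolkin_validation_error")
  }
  fit <- lm(absorbance ~ concentration)
  slope <- unname(coef(fit)[2])
  if (slope == 0) {
    stop_pk("calibration slope is zero; standards carry no signal",
            "phenolkin_validation_error")
  }
  r2 <- if (length(unique(absorbance)) > 1) {
    goodness_of_fit(absorbance, unname(predict(fit)))$r_squared
  } else {
    NA_real_
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
         analyte = analyte, range = range(concentration)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %s: A = %.6g * C + %.6g (R^2 = %s, C in %g..%g mg/L)\n",
              x$analyte, x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$range[1], x$range[2]))
  invisible(x)
}

#' Describe an assayed extract sample
#'
#' @param absorbance Sample absorbance (blank-corrected as measured).
#' @param blank_absorbance Blank absorbance (used by the DPPH assay).
#' @param extract_volume Volume of original extract in litres.
#' @param dilution_factor Dilution applied before the assay; default 20
#'   (total phenolics). Use 40 for the flavonoid assay.
#' @param dry_weight Dry weight of the extracted sample in grams.
#' @return An object of class `assay_sample`.
#' @export
assay_sample <- function(absorbance, blank_absorbance = NA_real_,
                         extract_volume = 0.08, dilution_factor = 20,
                         dry_weight = 4) {
  if (extract_volume <= 0) {
    stop_pk("`extract_volume` must be > 0", "phenolkin_validation_error")
  }
  if (dry_weight <= 0) {
    stop_pk("`dry_weight` must be > 0", "phenolkin_validation_error")
  }
  if (dilution_factor < 1) {
    stop_pk("`dilution_factor` must be >= 1", "phenolkin_validation_error")
  }
  structure(
    list(absorbance = absorbance, blank_absorbance = blank_absorbance,
         extract_volume = extract_volume, dilution_factor = dilution_factor,
         dry_weight = dry_weight),
    class = "assay_sample"
  )
}

#' Convert an assay absorbance into mg equivalents per g dry weight
#'
#' Inverts the standard curve to get the analyte concentration
#' C = (A - intercept)/slope in mg/L, then scales to the sample:
#' content = C * V * Df / W, the standard Folin-Ciocalteu / AlCl3 formula
#' (mg GAE or CE per g dry weight).
#'
#' A warning is raised when the absorbance falls outside the calibrated
#' range or when the inferred concentration is negative; values are
#' returned as computed, never clamped.
#'
#' @param calibration A [fit_calibration()] result.
#' @param sample An [assay_sample()].
#' @return Content in mg equivalents per g dry weight.
#' @export
content_from_assay <- function(calibration, sample) {
  stopifnot(inherits(calibration, "calibration"), inherits(sample, "assay_sample"))
  conc <- (sample$absorbance - calibration$intercept) / calibration$slope
  if (conc < 0) {
    warning(sprintf("negative inferred concentration (%.4g mg/L); returned as computed", conc))
  } else if (!is.null(calibration$range) && !anyNA(calibration$range) &&
             conc != 0 &&  # a true blank is legitimate
             (conc < calibration$range[1] || conc > calibration$range[2])) {
    warning(sprintf(
      "inferred concentration %.4g mg/L lies outside the calibrated range %g..%g mg/L",
      conc, calibration$range[1], calibration$range[2]))
  }
  conc * sample$extract_volume * sample$dilution_factor / sample$dry_weight
}

#' DPPH radical-scavenging activity (% inhibition)
#'
#' `100 * (A_blank - A_sample) / A_blank`. Values below 0 (sample more
#' absorbing than the blank) are reported as computed with a warning.
#'
#' @param blank_absorbance Absorbance of the blank control at 517 nm (> 0).
#' @param sample_absorbance Absorbance of the reaction mixture.
#' @return Percent inhibition.
#' @export
#' @examples
#' dpph_inhibition(0.8, 0.2) # 75 %
dpph_inhibition <- function(blank_absorbance, sample_absorbance) {
  if (any(blank_absorbance <= 0)) {
    stop_pk("`blank_absorbance` must be > 0", "phenolkin_domain_error")
  }
  out <- 100 * (blank_absorbance - sample_absorbance) / blank_absorbance
  if (any(out < 0)) {
    warning("sample absorbance exceeds blank: negative inhibition reported as computed")
  }
  out
}
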