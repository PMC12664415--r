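# Seeded generators of study-like extraction datasets.
#
# The generators state the world the validation suite lives in: triplicate
# pseudo-second-order curves at five temperatures (30-70 degC) sampled
# 10-80 min at 10-min intervals, with additive homoscedastic Gaussian
# noise of 1 mg/g, truth parameters set to the reported reference
# magnitudes; plus Crank-model unaccomplished-ratio series with Gaussian
# y-noise. Every generator is a pure function of (spec, seed).

#' Specification for a synthetic pseudo-second-order dataset
#'
#' Defaults emulate the reference study design: temperatures 30-70 degC,
#' times 10-80 min in 10-min steps, triplicates, saturation
#' concentrations and rate constants at the reported per-temperature
#' magnitudes, additive Gaussian noise with SD 1 mg/g, and a global
#' maximum extractable content of 175 mg/g.
#'
#' @param temperatures Temperatures in degC.
#' @param times Sampling times in minutes.
#' @param replicates Number of replicate curves per temperature.
#' @param cs_by_temperature Named or positional vector of true Cs, one per
#'   temperature.
#' @param k_by_temperature True rate constants, one per temperature;
#'   alternatively supply `ea` and `k0` to derive them from the Arrhenius
#'   law.
#' @param ea,k0 Optional Arrhenius parameterization of the rate constants
#'   (J/mol and rate units); used when `k_by_temperature` is `NULL`.
#' @param noise_sd Additive Gaussian noise SD, mg/g (>= 0).
#' @param c_max Maximum extractable concentration, mg/g; all Cs must lie
#'   below it.
#' @param method_label Method label stamped on every curve.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(temperatures = c(30, 40, 50, 60, 70),
                           times = seq(10, 80, by = 10),
                           replicates = 3,
                           cs_by_temperature = NULL,
                           k_by_temperature = NULL,
                           ea = NULL, k0 = NULL,
                           noise_sd = 1.0,
                           c_max = 175,
                           method_label = "UAE",
                           seed = 1L) {
  ref <- reference_kinetics()
  if (is.null(cs_by_temperature)) {
    cs_by_temperature <- ref$cs[match(temperatures, ref$temperature)]
    if (anyNA(cs_by_temperature)) {
      stop_pk("no default Cs for a requested temperature; supply `cs_by_temperature`",
              "phenolkin_validation_error")
    }
  }
  if (is.null(k_by_temperature)) {
    if (!is.null(ea) && !is.null(k0)) {
      k_by_temperature <- k0 * exp(-ea / (GAS_CONSTANT * celsius_to_kelvin(temperatures)))
    } else {
      k_by_temperature <- ref$k[match(temperatures, ref$temperature)]
      if (anyNA(k_by_temperature)) {
        stop_pk("no default k for a requested temperature; supply `k_by_temperature` or (ea, k0)",
                "phenolkin_validation_error")
      }
    }
  }
  stopifnot(length(cs_by_temperature) == length(temperatures),
            length(k_by_temperature) == length(temperatures))
  if (noise_sd < 0) stop_pk("`noise_sd` must be >= 0", "phenolkin_validation_error")
  if (replicates < 1) stop_pk("`replicates` must be >= 1", "phenolkin_validation_error")
  if (any(cs_by_temperature >= c_max)) {
    stop_pk("all true Cs must lie below `c_max`", "phenolkin_validation_error")
  }
  structure(
    list(temperatures = temperatures, times = times, replicates = replicates,
         cs_by_temperature = cs_by_temperature,
         k_by_temperature = k_by_temperature,
         noise_sd = noise_sd, c_max = c_max, method_label = method_label,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic pseudo-second-order study dataset
#'
#' For each temperature and replicate, Ct = pso_predict(Cs, k, t) plus
#' N(0, noise_sd^2), truncated below at 0 and above at `c_max`.
#' Deterministic given the spec's seed; the true parameters are recorded
#' in each curve's `meta` (`true_cs`, `true_k`) and every curve is
#' labelled `synthetic = TRUE`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [study_dataset()].
#' @export
generate_pso_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    curves <- list()
    for (i in seq_along(spec$temperatures)) {
      mu <- pso_predict(spec$cs_by_temperature[i], spec$k_by_temperature[i],
                        spec$times)
      for (r in seq_len(spec$replicates)) {
        ct <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
        ct <- pmin(pmax(ct, 0), spec$c_max)
        curves[[length(curves) + 1L]] <- extraction_curve(
          spec$times, ct, spec$temperatures[i], spec$method_label, r,
          meta = list(true_cs = spec$cs_by_temperature[i],
                      true_k = spec$k_by_temperature[i],
                      synthetic = TRUE))
      }
    }
    study_dataset(curves)
  })
}

#' Generate synthetic Crank-model unaccomplished-ratio series
#'
#' y(t) = crank_y(De, R, t, n_terms = 50) + N(0, noise_sd_y^2), clipped to
#' (0, 1] (lower clip at 1e-9 to keep the log-linear initializer usable).
#' Times are supplied in minutes and returned in seconds.
#'
#' @param de_by_temperature True diffusivities (m^2/s); defaults to the
#'   reported n = 10 reference magnitudes at 30-70 degC. Names (or the
#'   `temperatures` argument) label the output.
#' @param radius Particle radius, m.
#' @param times Sampling times in minutes.
#' @param noise_sd_y Gaussian noise SD on the y scale.
#' @param seed Integer seed.
#' @param temperatures Optional labels, same length as
#'   `de_by_temperature`.
#' @param n_terms Series truncation used for the true curves (50 terms is
#'   effectively exact over the design's Fourier numbers).
#' @return A named list of data frames with columns `time_s`, `y`; each
#'   carries its true De as attribute `true_de`.
#' @export
generate_diffusion_dataset <- function(de_by_temperature = NULL,
                                       radius = PARTICLE_RADIUS,
                                       times = seq(10, 80, by = 10),
                                       noise_sd_y = 0.01,
                                       seed = 1L,
                                       temperatures = NULL,
                                       n_terms = 50) {
  if (is.null(de_by_temperature)) {
    ref <- reference_diffusion()
    ref <- ref[ref$n_terms == 10, ]
    de_by_temperature <- ref$de
    temperatures <- temperatures %||% ref$temperature
  }
  if (any(de_by_temperature < 0)) {
    stop_pk("`de_by_temperature` must be >= 0", "phenolkin_validation_error")
  }
  if (noise_sd_y < 0) stop_pk("`noise_sd_y` must be >= 0", "phenolkin_validation_error")
  temperatures <- temperatures %||% seq_along(de_by_temperature)
  with_seed(seed, {
    out <- lapply(seq_along(de_by_temperature), function(i) {
      t_s <- times * 60
      y <- crank_y(de_by_temperature[i], radius, t_s, n_terms) +
        stats::rnorm(length(t_s), 0, noise_sd_y)
      y <- pmin(pmax(y, 1e-9), 1)
      df <- data.frame(time_s = t_s, y = y)
      attr(df, "true_de") <- de_by_temperature[i]
      df
    })
    names(out) <- as.character(temperatures)
    out
  })
}

#' Generate a matched UAE/CSE synthetic pair
#'
#' Emulates running the same design with and without ultrasonic
#' assistance: the CSE arm's true parameters are the UAE arm's attenuated
#' by fixed factors (defaults cs x 0.90, k x 0.65, the reported UAE/CSE
#' ratios at the optimum condition).
#'
#' @param spec A [synthetic_spec()] describing the UAE arm.
#' @param cse_attenuation Named numeric vector with elements `cs` and `k`
#'   in (0, 1].
#' @return A [study_dataset()] containing both method arms.
#' @export
generate_uae_cse_pair <- function(spec = synthetic_spec(),
                                  cse_attenuation = c(cs = 0.90, k = 0.65)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(cse_attenuation <= 0) || any(cse_attenuation > 1)) {
    stop_pk("`cse_attenuation` factors must lie in (0, 1]",
            "phenolkin_validation_error")
  }
  uae_spec <- spec
  uae_spec$method_label <- "UAE"
  cse_spec <- spec
  cse_spec$method_label <- "CSE"
  cse_spec$cs_by_temperature <- spec$cs_by_temperature * cse_attenuation[["cs"]]
  cse_spec$k_by_temperature <- spec$k_by_temperature * cse_attenuation[["k"]]
  cse_spec$seed <- spec$seed + 1L  # independent noise in the control arm
  uae <- generate_pso_dataset(uae_spec)
  cse <- generate_pso_dataset(cse_spec)
  study_dataset(c(uae$curves, cse$curves))
}
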