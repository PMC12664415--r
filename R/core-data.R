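# Domain containers and shared numerical utilities.
#
# The unit conventions used everywhere downstream:
#   time          minutes at the data boundary (converted to seconds only
#                 where a diffusion/mass-transfer fit needs SI time)
#   concentration mg gallic-acid equivalents per g dry weight (mg GAE/g d.w.)
#   temperature   degrees Celsius at the boundary, kelvin internally

#' Construct an extraction time course
#'
#' One extraction curve: the concentration of extracted solute measured at a
#' series of sampling times, at a fixed temperature, for one extraction
#' method and replicate. This is the raw material of every fit in the
#' package.
#'
#' @param times Sampling times in minutes; strictly increasing, all >= 0.
#' @param concentrations Extract concentrations in mg GAE per g dry weight;
#'   finite and non-negative, same length as `times`.
#' @param temperature Extraction temperature in degrees Celsius.
#' @param method Method label, typically `"UAE"` (ultrasound-assisted) or
#'   `"CSE"` (conventional shaking extraction).
#' @param replicate Replicate identifier.
#' @param meta Named list of free annotations (ethanol fraction, solvent-to-
#'   solid ratio, ultrasonic frequency, ...). Preserved, never interpreted.
#' @return An object of class `extraction_curve`.
#' @export
#' @examples
#' extraction_curve(seq(10, 80, 10), c(80, 110, 125, 133, 138, 141, 143, 145),
#'                  temperature = 50)
extraction_curve <- function(times, concentrations, temperature,
                             method = "UAE", replicate = 1L, meta = list()) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations)) {
    stop_pk("`times` and `concentrations` must have the same length",
            "phenolkin_validation_error")
  }
  if (anyNA(times) || any(!is.finite(times)) || any(times < 0)) {
    stop_pk("`times` must be finite and non-negative", "phenolkin_validation_error")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_pk("`times` must be strictly increasing", "phenolkin_validation_error")
  }
  if (anyNA(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations < 0)) {
    stop_pk("`concentrations` must be finite and non-negative",
            "phenolkin_validation_error")
  }
  structure(
    list(times = times, concentrations = concentrations,
         temperature = as.numeric(temperature), method = as.character(method),
         replicate = replicate, meta = meta),
    class = "extraction_curve"
  )
}

#' @export
print.extraction_curve <- function(x, ...) {
  cat(sprintf("<extraction_curve> %s, %g degC, replicate %s: %d points, t = %g..%g min\n",
              x$method, x$temperature, as.character(x$replicate),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Bundle extraction curves with the study's physical constants
#'
#' @param curves List of [extraction_curve()] objects.
#' @param particle_radius Particle radius in metres (sphere model); default
#'   [PARTICLE_RADIUS] = 1.25e-4 m (0.25 mm mean diameter).
#' @param gas_constant Gas constant in J mol^-1 K^-1.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(curves, particle_radius = PARTICLE_RADIUS,
                          gas_constant = GAS_CONSTANT) {
  if (inherits(curves, "extraction_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "extraction_curve"))) {
    stop_pk("`curves` must be a non-empty list of extraction_curve objects",
            "phenolkin_validation_error")
  }
  if (!is.numeric(particle_radius) || particle_radius <= 0) {
    stop_pk("`particle_radius` must be > 0", "phenolkin_validation_error")
  }
  keys <- vapply(curves, function(cv) {
    paste(cv$temperature, cv$method, cv$replicate, sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop_pk("duplicate (temperature, method, replicate) combination in dataset",
            "phenolkin_validation_error")
  }
  structure(
    list(curves = curves, particle_radius = particle_radius,
         gas_constant = gas_constant),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d curves, particle radius %g m\n",
              length(x$curves), x$particle_radius))
  invisible(x)
}

#' @export
as.data.frame.study_dataset <- function(x, ...) {
  rows <- lapply(x$curves, function(cv) {
    df <- data.frame(time = cv$times, concentration = cv$concentrations,
                     temperature = cv$temperature, method = cv$method,
                     replicate = cv$replicate, stringsAsFactors = FALSE)
    for (nm in names(cv$meta)) df[[nm]] <- cv$meta[[nm]]
    df
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (nm in setdiff(all_names, names(df))) df[[nm]] <- NA
    df[all_names]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

REQUIRED_COLUMNS <- c("time", "concentration", "temperature", "method", "replicate")

#' Read extraction curves from a delimited text file
#'
#' Expects long-format data with one row per measurement and columns for
#' time (minutes), concentration (mg GAE/g d.w.), temperature (degrees C),
#' method and replicate. Column names can be remapped through `dialect`.
#' Unknown columns are preserved into each curve's `meta` (constant within
#' a curve) so that annotations such as ethanol fraction survive a
#' round-trip.
#'
#' @param path Path to a CSV (default) or TSV file with a header row.
#' @param dialect Named character vector mapping standard names to the
#'   file's column names, e.g. `c(temperature = "temp_C")`.
#' @param sep Field separator; defaults to tab for `.tsv` files and comma
#'   otherwise.
#' @return A [study_dataset()]; one curve per (temperature, method,
#'   replicate) group with times sorted ascending.
#' @export
read_curves <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop_pk(sprintf("file not found: %s", path), "phenolkin_config_error")
  }
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  # apply dialect: dialect["temperature"] = "temp_C" renames temp_C -> temperature
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      src <- dialect[[std]]
      if (!src %in% names(raw)) {
        stop_pk(sprintf("dialect maps '%s' to column '%s' which is absent", std, src),
                "phenolkin_config_error")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  missing <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing)) {
    stop_pk(sprintf("required column(s) missing: %s",
                    paste(missing, collapse = ", ")),
            "phenolkin_config_error")
  }
  for (col in c("time", "concentration", "temperature")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      stop_pk(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                      raw[[col]][bad[1]], col, bad[1]),
              "phenolkin_parse_error")
    }
    raw[[col]] <- parsed
  }
  meta_cols <- setdiff(names(raw), REQUIRED_COLUMNS)
  key <- paste(raw$temperature, raw$method, raw$replicate, sep = "\r")
  curves <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    grp <- raw[idx, , drop = FALSE]
    if (anyDuplicated(grp$time)) {
      stop_pk(sprintf(
        "duplicate time %g within group (T=%g, method=%s, replicate=%s)",
        grp$time[duplicated(grp$time)][1], grp$temperature[1],
        grp$method[1], grp$replicate[1]),
        "phenolkin_validation_error")
    }
    ord <- order(grp$time)
    grp <- grp[ord, , drop = FALSE]
    meta <- lapply(meta_cols, function(nm) {
      v <- unique(grp[[nm]])
      if (length(v) == 1) v else grp[[nm]]
    })
    names(meta) <- meta_cols
    extraction_curve(grp$time, grp$concentration, grp$temperature[1],
                     grp$method[1], grp$replicate[1], meta)
  })
  names(curves) <- NULL
  study_dataset(curves)
}

#' Write a study dataset to delimited text
#'
#' Inverse of [read_curves()]: emits the long-format schema (time,
#' concentration, temperature, method, replicate, plus any meta columns).
#'
#' @param dataset A [study_dataset()].
#' @param path Output file path.
#' @param sep Field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_curves <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "study_dataset"))
  df <- as.data.frame(dataset)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Goodness-of-fit metrics on the response scale
#'
#' Computes the coefficient of determination R^2 = 1 - SSres/SStot, the mean
#' square error MSE = SSres/n and its square root RMSE, comparing observed
#' and model-predicted responses. R^2 is not clipped: a fit worse than the
#' mean yields a negative value.
#'
#' @param observed Numeric vector of experimental values.
#' @param predicted Numeric vector of model values, same length.
#' @return An object of class `fit_quality` with fields `r_squared`, `mse`,
#'   `rmse` and `n_points`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4)) # R^2 = 0.5, MSE = 1/3
goodness_of_fit <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    stop_pk("`observed` and `predicted` must have the same length",
            "phenolkin_validation_error")
  }
  n <- length(observed)
  if (n < 2) {
    stop_pk("at least 2 points are required", "phenolkin_validation_error")
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_pk("R^2 is undefined: observed values are all identical (zero total sum of squares)",
            "phenolkin_domain_error")
  }
  mse <- ss_res / n
  structure(
    list(r_squared = 1 - ss_res / ss_tot, mse = mse, rmse = sqrt(mse),
         n_points = n),
    class = "fit_quality"
  )
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("<fit_quality> R^2 = %.4f, MSE = %.4g, RMSE = %.4g (n = %d)\n",
              x$r_squared, x$mse, x$rmse, x$n_points))
  invisible(x)
}

#' Signed percent change relative to a reference value
#'
#' `100 * (value - reference) / reference`. Used for the UAE-vs-CSE and
#' temperature-endpoint summaries (e.g. the rise of the effective
#' diffusivity from 30 to 40 degC).
#'
#' @param reference Baseline value (non-zero).
#' @param value New value.
#' @return Percent change; positive for an increase.
#' @export
#' @examples
#' relative_change(8.728, 10.410) # +19.27 %
relative_change <- function(reference, value) {
  if (any(reference == 0)) {
    stop_pk("`reference` must be non-zero", "phenolkin_domain_error")
  }
  100 * (value - reference) / reference
}
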