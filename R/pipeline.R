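# End-to-end study orchestration: per (method, temperature) group,
# pseudo-second-order fit -> unaccomplished ratio -> Crank diffusivity fit
# with bootstrap -> external mass transfer and Biot number; across
# temperatures, Arrhenius and Van't Hoff fits; assembled into
# publication-style report tables.

#' Configuration for a full study run
#'
#' Defaults are frozen to the reference study's settings: 0.125 mm
#' particle radius, bootstrap B = 2000, series truncations (1, 10, 20),
#' Biot length = particle diameter 2R, depletion-law characteristic
#' length Lc = R/3, and a global maximum extractable content of
#' 175 mg/g.
#'
#' @param particle_radius Particle radius, m.
#' @param characteristic_length Lc for the mass-transfer slope;
#'   default `particle_radius / 3`.
#' @param biot_length Length used in the Biot number; default
#'   `2 * particle_radius` (diameter convention).
#' @param n_terms Series truncations to fit, e.g. `c(1, 10, 20)`.
#' @param bootstrap_B Bootstrap iterations per diffusion fit.
#' @param seed Base seed; every bootstrap derives a deterministic
#'   sub-seed from it.
#' @param c_max Maximum extractable concentration for the equilibrium
#'   constant.
#' @param gas_constant Gas constant, J mol^-1 K^-1.
#' @param refine_pso Refine the linearized kinetics fit by direct
#'   nonlinear least squares.
#' @param arrhenius_temperatures Optional subset of temperatures (degC)
#'   for the Arrhenius fit; rate constants of extraction are often
#'   non-monotone over a wide window, so the ascending branch may be the
#'   meaningful regime. `NULL` uses all temperatures.
#' @return A list of class `study_config`.
#' @export
study_config <- function(particle_radius = PARTICLE_RADIUS,
                         characteristic_length = NULL,
                         biot_length = NULL,
                         n_terms = c(1, 10, 20),
                         bootstrap_B = 2000,
                         seed = 1L,
                         c_max = 175,
                         gas_constant = GAS_CONSTANT,
                         refine_pso = FALSE,
                         arrhenius_temperatures = NULL) {
  structure(
    list(particle_radius = particle_radius,
         characteristic_length = characteristic_length %||% (particle_radius / 3),
         biot_length = biot_length %||% (2 * particle_radius),
         n_terms = as.integer(n_terms),
         bootstrap_B = as.integer(bootstrap_B),
         seed = as.integer(seed),
         c_max = c_max,
         gas_constant = gas_constant,
         refine_pso = isTRUE(refine_pso),
         arrhenius_temperatures = arrhenius_temperatures),
    class = "study_config"
  )
}

# Average replicate curves onto their common time grid.
mean_curve <- function(curves) {
  times <- Reduce(intersect, lapply(curves, `[[`, "times"))
  if (length(times) < 3) {
    stop_pk("replicates share fewer than 3 common time points",
            "phenolkin_validation_error")
  }
  times <- sort(times)
  conc <- rowMeans(vapply(curves, function(cv) {
    cv$concentrations[match(times, cv$times)]
  }, numeric(length(times))))
  extraction_curve(times, conc, curves[[1]]$temperature,
                   curves[[1]]$method, "mean")
}

#' Run the full extraction-modelling pipeline on a dataset
#'
#' For every (method, temperature) group: fits the pseudo-second-order
#' model per replicate (aggregated as mean +/- SD across replicates),
#' builds the unaccomplished-ratio series of the replicate-mean curve
#' with Cinf set to the fitted mean Cs, fits the Crank diffusivity at
#' each requested series truncation with a residual bootstrap, and fits
#' the external mass-transfer coefficient and Biot number. Across
#' temperatures within a method it fits the Arrhenius line to the rate
#' constants and the Van't Hoff thermodynamic chain to the saturation
#' concentrations. A failing group is recorded and skipped; the run
#' errors only if no group succeeds.
#'
#' @param dataset A [study_dataset()].
#' @param config A [study_config()].
#' @return An object of class `report_bundle` with data-frame tables
#'   `kinetics_table`, `diffusion_table`, `transport_thermo_table`,
#'   `comparison_table` (when two methods are present), the underlying
#'   fit objects in `fits`, and `provenance` (config, seed, package
#'   version, aggregated warnings and per-group errors).
#' @export
run_study <- function(dataset, config = study_config()) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(config, "study_config"))
  warn_log <- character()
  err_log <- character()
  note <- function(group, msgs) {
    if (length(msgs)) warn_log <<- c(warn_log, sprintf("[%s] %s", group, msgs))
  }
  collect <- function(group, expr) {
    msgs <- character()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        err_log <<- c(err_log, sprintf("[%s] %s", group, conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    note(group, msgs)
    res
  }

  keys <- vapply(dataset$curves, function(cv) {
    paste(cv$method, cv$temperature, sep = "\r")
  }, character(1))
  groups <- split(dataset$curves, keys)

  kin_rows <- list()
  dif_rows <- list()
  trn_rows <- list()
  fits <- list()
  boot_counter <- 0L

  for (gk in names(groups)) {
    curves <- groups[[gk]]
    method <- curves[[1]]$method
    temp <- curves[[1]]$temperature
    label <- sprintf("%s %g degC", method, temp)

    pso_fits <- collect(label, lapply(curves, fit_pso_linearized,
                                      refine = config$refine_pso))
    if (is.null(pso_fits)) next
    cs_vals <- vapply(pso_fits, `[[`, numeric(1), "cs")
    k_vals <- vapply(pso_fits, `[[`, numeric(1), "k")
    qual <- vapply(pso_fits, function(f) {
      c(f$quality$r_squared, f$quality$mse, f$quality$rmse)
    }, numeric(3))
    cs_mean <- mean(cs_vals)
    k_mean <- mean(k_vals)
    kin_rows[[gk]] <- data.frame(
      method = method, temperature = temp,
      cs = cs_mean, cs_sd = if (length(cs_vals) > 1) sd(cs_vals) else NA_real_,
      k = k_mean, k_sd = if (length(k_vals) > 1) sd(k_vals) else NA_real_,
      h = initial_rate(k_mean, cs_mean),
      r_squared = mean(qual[1, ]), mse = mean(qual[2, ]), rmse = mean(qual[3, ]))

    mc <- collect(label, mean_curve(curves))
    if (is.null(mc)) next
    ys <- collect(label, unaccomplished_ratio(mc, c_inf = cs_mean))

    de_main <- NA_real_
    group_fits <- list(pso = pso_fits)
    if (!is.null(ys)) {
      for (nt in config$n_terms) {
        boot_counter <- boot_counter + 1L
        dfit <- collect(label, fit_de(ys, radius = config$particle_radius,
                                      n_terms = nt))
        if (is.null(dfit)) next
        boot <- collect(label, bootstrap_de(
          dfit, n_iterations = config$bootstrap_B,
          seed = (config$seed + 7919L * boot_counter) %% .Machine$integer.max))
        if (is.null(boot)) next
        dif_rows[[paste(gk, nt)]] <- data.frame(
          method = method, temperature = temp, n_terms = nt,
          de = dfit$de, se = boot$standard_error,
          ci_low = boot$ci_low, ci_high = boot$ci_high,
          r_squared = dfit$quality$r_squared)
        group_fits[[paste0("diffusion_n", nt)]] <- dfit
        group_fits[[paste0("bootstrap_n", nt)]] <- boot
        if (nt == max(config$n_terms)) de_main <- dfit$de
      }
    }

    mt <- collect(label, fit_kt(mc, cs = cs_mean,
                                characteristic_length = config$characteristic_length,
                                radius = config$particle_radius))
    if (!is.null(mt)) group_fits$mass_transfer <- mt
    bi <- if (!is.null(mt) && is.finite(de_main)) {
      biot_number(mt$kt, config$biot_length, de_main)
    } else {
      NA_real_
    }
    trn_rows[[gk]] <- data.frame(
      method = method, temperature = temp, de = de_main,
      kt = if (!is.null(mt)) mt$kt else NA_real_, biot = bi,
      rate_limit = if (is.finite(bi)) classify_rate_limit(bi) else NA_character_)
    fits[[gk]] <- group_fits
  }

  if (!length(kin_rows)) {
    stop_pk("no (method, temperature) group could be fitted", "phenolkin_fit_error")
  }
  kinetics_table <- do.call(rbind, kin_rows)
  kinetics_table <- kinetics_table[order(kinetics_table$method,
                                         kinetics_table$temperature), ]
  rownames(kinetics_table) <- NULL
  diffusion_table <- if (length(dif_rows)) {
    d <- do.call(rbind, dif_rows)
    d <- d[order(d$method, d$temperature, d$n_terms), ]
    rownames(d) <- NULL
    d
  } else {
    NULL
  }
  transport_table <- do.call(rbind, trn_rows)

  # Across-temperature fits per method
  method_fits <- list()
  for (m in unique(kinetics_table$method)) {
    sub <- kinetics_table[kinetics_table$method == m, ]
    lab <- sprintf("%s across temperatures", m)
    arr_sub <- sub
    if (!is.null(config$arrhenius_temperatures)) {
      arr_sub <- sub[sub$temperature %in% config$arrhenius_temperatures, ]
    }
    arr <- if (nrow(arr_sub) >= 2) {
      collect(lab, fit_arrhenius(arr_sub$temperature, arr_sub$k,
                                 config$gas_constant))
    } else {
      NULL
    }
    thermo <- if (nrow(sub) >= 2) {
      collect(lab, thermo_chain(sub$temperature, sub$cs, config$c_max,
                                config$gas_constant))
    } else {
      NULL
    }
    method_fits[[m]] <- list(arrhenius = arr, thermo = thermo)
  }

  # Merge thermodynamics into the transport table
  transport_table$delta_h <- NA_real_
  transport_table$delta_s <- NA_real_
  transport_table$delta_g <- NA_real_
  for (m in names(method_fits)) {
    th <- method_fits[[m]]$thermo
    if (is.null(th)) next
    sel <- transport_table$method == m
    transport_table$delta_h[sel] <- th$delta_h
    transport_table$delta_s[sel] <- th$delta_s
    tk <- celsius_to_kelvin(transport_table$temperature[sel])
    transport_table$delta_g[sel] <- gibbs_energy(th$delta_h, th$delta_s, tk)
  }
  transport_table <- transport_table[order(transport_table$method,
                                           transport_table$temperature), ]
  rownames(transport_table) <- NULL

  bundle <- structure(
    list(kinetics_table = kinetics_table,
         diffusion_table = diffusion_table,
         transport_thermo_table = transport_table,
         comparison_table = NULL,
         fits = fits, method_fits = method_fits,
         provenance = list(
           config = unclass(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("phenolkin")),
           warnings = warn_log, errors = err_log)),
    class = "report_bundle"
  )
  if (length(unique(kinetics_table$method)) >= 2) {
    bundle$comparison_table <- compare_methods(bundle)
  }
  bundle
}

#' Compare UAE and CSE arms of a report bundle
#'
#' Builds a side-by-side table of the fitted parameters (Cs, k, De, KT)
#' for the two method labels at the comparison temperature (default: the
#' temperature at which the first method's Cs peaks — the optimum
#' condition), with signed percent differences of the first method
#' relative to the second (`relative_change(cse, uae)`).
#'
#' @param bundle A [run_study()] result containing both methods.
#' @param methods Character vector of two method labels; default
#'   `c("UAE", "CSE")` intersected with what is present.
#' @param temperature Comparison temperature (degC); default the first
#'   method's Cs-optimal temperature.
#' @return A data frame with columns `parameter`, the two method values,
#'   and `percent_change`.
#' @export
compare_methods <- function(bundle, methods = NULL, temperature = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  kin <- bundle$kinetics_table
  present <- unique(kin$method)
  methods <- methods %||% intersect(c("UAE", "CSE"), present)
  if (length(methods) < 2) {
    stop_pk("both method labels must be present to compare", "phenolkin_validation_error")
  }
  m1 <- methods[1]
  m2 <- methods[2]
  if (!all(c(m1, m2) %in% present)) {
    stop_pk(sprintf("method(s) absent from the bundle: %s",
                    paste(setdiff(c(m1, m2), present), collapse = ", ")),
            "phenolkin_validation_error")
  }
  sub1 <- kin[kin$method == m1, ]
  temperature <- temperature %||% sub1$temperature[which.max(sub1$cs)]
  trn <- bundle$transport_thermo_table
  grab <- function(m) {
    kr <- kin[kin$method == m & kin$temperature == temperature, ]
    tr <- trn[trn$method == m & trn$temperature == temperature, ]
    if (!nrow(kr)) {
      stop_pk(sprintf("method %s has no fit at %g degC", m, temperature),
              "phenolkin_validation_error")
    }
    c(cs = kr$cs[1], k = kr$k[1],
      de = if (nrow(tr)) tr$de[1] else NA_real_,
      kt = if (nrow(tr)) tr$kt[1] else NA_real_)
  }
  v1 <- grab(m1)
  v2 <- grab(m2)
  out <- data.frame(parameter = names(v1), v1 = unname(v1), v2 = unname(v2),
                    percent_change = unname(relative_change(v2, v1)),
                    temperature = temperature)
  names(out)[2:3] <- c(m1, m2)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n\nKinetics (pseudo-second-order):\n")
  print(x$kinetics_table, digits = 6)
  if (!is.null(x$diffusion_table)) {
    cat("\nEffective diffusivity (Crank series):\n")
    print(x$diffusion_table, digits = 4)
  }
  cat("\nTransport & thermodynamics:\n")
  print(x$transport_thermo_table, digits = 6)
  if (!is.null(x$comparison_table)) {
    cat("\nMethod comparison:\n")
    print(x$comparison_table, digits = 6)
  }
  if (length(x$provenance$warnings)) {
    cat(sprintf("\n%d warning(s) logged; see $provenance$warnings\n",
                length(x$provenance$warnings)))
  }
  if (length(x$provenance$errors)) {
    cat(sprintf("%d group error(s); see $provenance$errors\n",
                length(x$provenance$errors)))
  }
  invisible(x)
}

# --- JSON serialization -----------------------------------------------------

strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Serialize a result object to JSON
#'
#' Field names follow the object's own field names. Works for every
#' result class in the package (fit objects, bootstrap results, report
#' bundles, ...).
#'
#' @param x A package result object (or any list).
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string (class `json`).
#' @export
as_json <- function(x, ...) {
  jsonlite::toJSON(strip_classes(x), auto_unbox = TRUE, digits = NA,
                   dataframe = "rows", null = "null", na = "null", ...)
}

#' Write a report bundle to disk
#'
#' Emits one CSV per report table (`kinetics.csv`, `diffusion.csv`,
#' `transport_thermo.csv`, `comparison.csv`), the full bundle as
#' `bundle.json`, and the provenance (config, seed, versions, warnings)
#' as `provenance.json`.
#'
#' @param bundle A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(bundle$kinetics_table, file.path(dir, "kinetics.csv"),
            row.names = FALSE)
  if (!is.null(bundle$diffusion_table)) {
    write.csv(bundle$diffusion_table, file.path(dir, "diffusion.csv"),
              row.names = FALSE)
  }
  write.csv(bundle$transport_thermo_table,
            file.path(dir, "transport_thermo.csv"), row.names = FALSE)
  if (!is.null(bundle$comparison_table)) {
    write.csv(bundle$comparison_table, file.path(dir, "comparison.csv"),
              row.names = FALSE)
  }
  light <- bundle
  light$fits <- NULL  # fit internals (data vectors, draws) stay in R
  writeLines(as_json(light), file.path(dir, "bundle.json"))
  writeLines(as_json(bundle$provenance), file.path(dir, "provenance.json"))
  invisible(dir)
}
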