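#' @importFrom stats coef lm nls predict quantile sd vcov
#' @importFrom utils read.csv write.csv write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_pk <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenolkin_error")))
}

#' Convert Celsius to absolute temperature
#'
#' Single point of truth for the Kelvin conversion used throughout the
#' package. The offset is 273 (not 273.15): extraction studies in this
#' field routinely round the conversion, and the package's thermodynamic
#' chain is self-consistent only under this convention.
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @export
#' @examples
#' celsius_to_kelvin(30) # 303
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + 273
}

#' Universal gas constant (J mol^-1 K^-1)
#' @export
GAS_CONSTANT <- 8.314

#' Default particle radius (m)
#'
#' Radius of the milled leaf particle modelled as a sphere, corresponding
#' to a mean particle diameter of 0.25 mm.
#' @export
PARTICLE_RADIUS <- 1.25e-4
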