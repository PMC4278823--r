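#' Physical constants and temperature conversion
#'
#' `k_boltzmann()` returns the Boltzmann constant in eV/K (CODATA value),
#' the single source of truth used throughout the package. `t_ref()` returns
#' the default reference temperature, 301.15 K (28 degrees C), at which the
#' baseline demographic rates are defined. `celsius_to_kelvin()` and
#' `kelvin_to_celsius()` convert between the experimentalist-facing Celsius
#' scale (used in designs and data files) and the Kelvin scale in which all
#' model arithmetic is done.
#'
#' @param x temperature(s) to convert.
#' @return A numeric scalar (constants) or vector (conversions).
#' @examples
#' celsius_to_kelvin(28) # 301.15
#' @export
k_boltzmann <- function() 8.617333262e-5

#' @rdname k_boltzmann
#' @export
t_ref <- function() 301.15

#' @rdname k_boltzmann
#' @export
celsius_to_kelvin <- function(x) {
  stopifnot(is.numeric(x))
  x + 273.15
}

#' @rdname k_boltzmann
#' @export
kelvin_to_celsius <- function(x) {
  stopifnot(is.numeric(x))
  x - 273.15
}
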