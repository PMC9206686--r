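#' Physical constants used throughout the thermodynamic calculations
#'
#' Gas constant `R` (J mol-1 K-1), Boltzmann constant `kB` (J K-1),
#' Planck constant `h` (J s) and Avogadro's number `N_A` (mol-1), the
#' 2019 SI exact values.  All Eyring and Arrhenius computations in the
#' package draw on this list so that every stage uses identical constants.
#'
#' @format A named list with elements `R`, `kB`, `h`, `N_A`.
#' @examples
#' physical_constants$R
#' @export
physical_constants <- list(
  R   = 8.314,          # J mol-1 K-1
  kB  = 1.380649e-23,   # J K-1
  h   = 6.62607015e-34, # J s
  N_A = 6.02214076e23   # mol-1
)

#' Convert degrees Celsius to Kelvin
#'
#' Single central conversion used at every package boundary that accepts
#' temperatures in degrees Celsius.
#'
#' @param temp_C numeric vector of temperatures in degrees Celsius.
#' @return numeric vector of temperatures in Kelvin.
#' @examples
#' celsius_to_kelvin(40) # 313.15
#' @export
celsius_to_kelvin <- function(temp_C) {
  stopifnot(is.numeric(temp_C))
  temp_C + 273.15
}
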