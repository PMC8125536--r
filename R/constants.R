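# Physical constants (CODATA 2018) and unit conversions.
# Internal energy unit is cm^-1 throughout; fields in Gauss; hyperfine input
# in MHz; microwave frequency in GHz.

.const <- list(
  h       = 6.62607015e-34,    # Planck, J s
  mu_B    = 9.2740100783e-24,  # Bohr magneton, J/T
  k_B     = 1.380649e-23,      # Boltzmann, J/K
  c_cm    = 2.99792458e10      # speed of light, cm/s
)

# Bohr magneton in cm^-1 per Gauss: mu_B * 1e-4 T/G / (h c)
.beta_cmG <- .const$mu_B * 1e-4 / (.const$h * .const$c_cm)
# Boltzmann constant in cm^-1 per K
.kB_cmK <- .const$k_B / (.const$h * .const$c_cm)
# frequency conversions to cm^-1
.ghz_to_cm <- 1e9 / .const$c_cm
.mhz_to_cm <- 1e6 / .const$c_cm

#' Effective g-value of a resonance field
#'
#' The convention used on every field axis here: `g_eff = h nu / (beta B)`,
#' the apparent g-value of a transition observed at field `field_G` for
#' microwave frequency `frequency_GHz`.  Effective g-values of intradoublet
#' transitions can far exceed the intrinsic g ~ 2 because of zero-field
#' splitting (e.g. the g4.1 signal).
#'
#' @param field_G resonance field in Gauss (> 0).
#' @param frequency_GHz microwave frequency in GHz.
#' @return dimensionless effective g-value.
#' @seealso [field_for_g()] for the inverse.
#' @examples
#' effective_g(3347, 9.369115)  # ~ 2.00
#' effective_g(1633, 9.369115)  # ~ 4.10
#' @export
effective_g <- function(field_G, frequency_GHz) {
  stopifnot(is.numeric(field_G), is.numeric(frequency_GHz))
  if (any(field_G <= 0)) stop("`field_G` must be positive")
  if (any(frequency_GHz <= 0)) stop("`frequency_GHz` must be positive")
  (frequency_GHz * .ghz_to_cm) / (.beta_cmG * field_G)
}

#' Resonance field for a given effective g-value
#'
#' Inverse of [effective_g()]: `B = h nu / (g beta)`.
#'
#' @param g effective g-value (> 0).
#' @param frequency_GHz microwave frequency in GHz.
#' @return field in Gauss.
#' @export
field_for_g <- function(g, frequency_GHz) {
  if (any(g <= 0)) stop("`g` must be positive")
  (frequency_GHz * .ghz_to_cm) / (.beta_cmG * g)
}

#' Convert a hyperfine splitting from MHz to Gauss
#'
#' Field-domain spacing of a splitting of `value_MHz` observed at g-value
#' `g`: `dB = h * value / (g mu_B)`.  A 250 MHz coupling at g = 2.00 is
#' ~89.3 G, the dominant line spacing of the S2 multiline signal.
#'
#' @param value_MHz splitting in MHz.
#' @param g g-value at which the splitting is observed (> 0).
#' @return splitting in Gauss.
#' @export
mhz_to_gauss <- function(value_MHz, g) {
  if (any(g <= 0)) stop("`g` must be positive")
  value_MHz * .mhz_to_cm / (g * .beta_cmG)
}

#' Convert a field-domain splitting from Gauss to MHz
#'
#' Inverse of [mhz_to_gauss()].
#'
#' @param value_G splitting in Gauss.
#' @param g g-value at which the splitting is observed (> 0).
#' @return splitting in MHz.
#' @export
gauss_to_mhz <- function(value_G, g) {
  if (any(g <= 0)) stop("`g` must be positive")
  value_G * g * .beta_cmG / .mhz_to_cm
}
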