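# CODATA-2018 exact values; everything downstream derives from these.
.codata <- list(
  k_B  = 1.380649e-23,    # Boltzmann constant, J K^-1
  h    = 6.62607015e-34,  # Planck constant, J s
  N_A  = 6.02214076e23,   # Avogadro constant, mol^-1
  R    = 8.314462618,     # molar gas constant, J mol^-1 K^-1
  c_cm = 2.99792458e10    # speed of light, cm s^-1
)

#' Physical constants used throughout the package
#'
#' Returns the fixed CODATA-2018 values of the Boltzmann constant (`k_B`,
#' J K^-1), Planck constant (`h`, J s), Avogadro constant (`N_A`, mol^-1),
#' molar gas constant (`R`, J mol^-1 K^-1) and the speed of light in
#' cm s^-1 (`c_cm`, used to convert wavenumbers to frequencies).
#'
#' @return Named list of constants.
#' @examples
#' cst <- physical_constants()
#' cst$k_B * 298.15 / cst$h  # Eyring prefactor at 298.15 K, ~6.2124e12 s^-1
#' @export
physical_constants <- function() .codata

# Eyring prefactor k_B*T/h in s^-1
.prefactor <- function(temperature) .codata$k_B * temperature / .codata$h
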