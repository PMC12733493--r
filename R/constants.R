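# Physical constants (internal units: Angstrom, kcal/mol, elementary charge)

#' Physical constants used internally
#'
#' Boltzmann constant in kcal/(mol K) and the Coulomb conversion factor
#' in kcal A / (mol e^2), i.e. `u_coul = COULOMB_KCAL * q1 * q2 / r`.
#'
#' @keywords internal
#' @name rism-constants
NULL

KB_KCAL <- 0.0019872041      # kcal / (mol K)
COULOMB_KCAL <- 332.06371    # kcal A / (mol e^2)
BOHR_PER_ANG <- 1.8897259886 # CUBE files are written in Bohr

#' @keywords internal
kT_kcal <- function(temperature) KB_KCAL * temperature
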