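## Physical constants and unit helpers shared across modules.

#' @keywords internal
KB_KCAL <- 0.0019872041   # Boltzmann constant, kcal mol^-1 K^-1

#' @keywords internal
L_BP_NM <- 0.34           # standard base-pair rise used by the rod model, nm

#' @keywords internal
DEFAULT_TEMPERATURE <- 300 # K

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Thermal energy k_B T
#'
#' @param temperature Temperature in Kelvin.
#' @return k_B T in kcal/mol (0.5962 kcal/mol at 300 K).
#' @export
kbt <- function(temperature = DEFAULT_TEMPERATURE) KB_KCAL * temperature

## Names of the six inter-bp and six intra-bp helical parameters, in the
## order used everywhere in the package: translations first, then rotations.
STEP_PAR_NAMES <- c("shift", "slide", "rise", "tilt", "roll", "twist")
INTRA_PAR_NAMES <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
TWIST_IDX <- 6L
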