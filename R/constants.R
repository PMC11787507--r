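#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
NULL

HEMES <- c("I", "III", "IV")
HEME_ALIAS <- c(I = "1", III = "3", IV = "4")
HEME_PAIRS <- c("I-III", "I-IV", "III-IV")

# Boltzmann constant in meV/K; one electron per heme so 1 mV == 1 meV.
KB_MEV <- 1000 * 8.617333262e-5

#' Thermal energy in meV
#'
#' @param temperature Absolute temperature in kelvin.
#' @return `kT` in meV (24.83 meV at the default 288.15 K).
#' @export
kT_meV <- function(temperature = 288.15) KB_MEV * temperature
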