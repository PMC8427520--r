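# Package-wide unit system: Angstrom, ps, K, kcal/mol, amu.

# Boltzmann constant, kcal/(mol K)
.kB <- 0.0019872041

# (kcal/mol/Angstrom)/amu -> Angstrom/ps^2
.acc_conv <- 418.4

# kB in amu Angstrom^2 / (ps^2 K); sets Maxwell-Boltzmann velocity widths
.kB_vel <- .kB * .acc_conv

#' Boltzmann constant in package units
#'
#' @return kB in kcal/(mol K).
#' @export
boltzmann_kcal <- function() .kB
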