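#' Physical constants and field conditions
#'
#' Unit conventions used throughout the package:
#' \itemize{
#'   \item magnetic fields in microtesla (uT),
#'   \item first-order rate constants in inverse microseconds (us^-1),
#'   \item time in microseconds,
#'   \item Hamiltonians in angular frequency units of rad/us,
#'   \item hyperfine couplings supplied in MHz (linear frequency) and
#'     multiplied by 2*pi on entering a Hamiltonian.
#' }
#'
#' `gyromagnetic_ratio(g)` returns the electron gyromagnetic ratio
#' g * mu_B / hbar expressed in rad us^-1 uT^-1; `larmor_frequency_MHz(B_uT)`
#' is the corresponding precession frequency in MHz (about 1.4 MHz at
#' 50 uT, the scale that sets the minimum coherence time for
#' magnetosensitivity).
#'
#' `GMF_uT` (55.26 uT) and `HMF_uT` (0.29 uT) are the geomagnetic and
#' hypomagnetic exposure conditions compared by the yield ratio chi(B).
#'
#' @param g electron g-factor (dimensionless).
#' @param B_uT field magnitude in uT.
#' @return `gyromagnetic_ratio`: rad us^-1 uT^-1. `larmor_frequency_MHz`:
#'   MHz.
#' @examples
#' larmor_frequency_MHz(50) # ~1.4 MHz
#' @export
gyromagnetic_ratio <- function(g = G_ELECTRON) {
  # mu_B [J/T] / hbar [J s] -> rad s^-1 T^-1; 1e-12 converts to rad us^-1 uT^-1
  g * 9.2740100783e-24 / 1.054571817e-34 * 1e-12
}

#' @rdname gyromagnetic_ratio
#' @export
larmor_frequency_MHz <- function(B_uT, g = G_ELECTRON) {
  gyromagnetic_ratio(g) * B_uT / (2 * pi)
}

#' @rdname gyromagnetic_ratio
#' @export
G_ELECTRON <- 2.0023

#' @rdname gyromagnetic_ratio
#' @export
GMF_uT <- 55.26

#' @rdname gyromagnetic_ratio
#' @export
HMF_uT <- 0.29

# MHz (linear frequency) -> rad/us (angular frequency)
MHZ_TO_ANGULAR <- 2 * pi
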