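#' Physical constants used in transition-state analysis
#'
#' Exact SI values of the Boltzmann and Planck constants and the molar gas
#' constant in the thermochemical units conventional in enzyme kinetics
#' (kcal/(mol K) for enthalpies, cal/(mol K) for entropies).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{h}{Planck constant, J s.}
#'   \item{R_kcal}{Gas constant, kcal/(mol K).}
#'   \item{R_cal}{Gas constant, cal/(mol K).}
#' }
#' @export
#' @examples
#' opsin_constants$kB * 298.15 / opsin_constants$h  # Eyring prefactor at 25 C
opsin_constants <- list(
  kB     = 1.380649e-23,
  h      = 6.62607015e-34,
  R_kcal = 1.98720425864083e-3,
  R_cal  = 1.98720425864083
)

#' Number density of liquid water
#'
#' Converts the bulk density of water into a number density in molecules per
#' cubic Angstrom, rho * N_A / M * 1e-24. With the conventional round molar
#' mass of 18.0 g/mol this gives the standard 3.35e-2 H2O/A^3 used to convert
#' cavity volumes into water-molecule capacities; the exact molar mass
#' 18.015 g/mol gives 3.343e-2 (0.2% lower).
#'
#' @param density Water density in g/mL (default 1).
#' @param molar_mass Molar mass of water in g/mol (default 18.0).
#' @return Number density in molecules per cubic Angstrom.
#' @seealso [water_capacity()]
#' @export
#' @examples
#' h2o_per_cubic_angstrom()         # 0.0335
#' h2o_per_cubic_angstrom(molar_mass = 18.015)
h2o_per_cubic_angstrom <- function(density = 1, molar_mass = 18.0) {
  stopifnot(is.numeric(density), density > 0,
            is.numeric(molar_mass), molar_mass > 0)
  density * 6.02214076e23 / molar_mass * 1e-24
}
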