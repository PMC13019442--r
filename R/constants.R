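#' Physical constants and unit conventions
#'
#' All quantities in the package use a single unit system: lengths in
#' Angstrom, energies in kcal/mol, temperatures in Kelvin. The Boltzmann
#' constant in these units is `kB = 0.0019872041` kcal/(mol K), and the
#' standard-state volume per molecule at 1 M is `v0 = 1660` Angstrom^3.
#'
#' @return A named list with elements `kB` (kcal/mol/K), `v0` (Angstrom^3),
#'   and `omega_s3` (the surface measure of the unit quaternion sphere S^3,
#'   `2 * pi^2`, used as the unrestrained rotational volume).
#' @examples
#' dbfe_constants()$kB * 300 # kT at 300 K, ~0.596 kcal/mol
#' @export
dbfe_constants <- function() {
  list(kB = 0.0019872041, v0 = 1660, omega_s3 = 2 * pi^2)
}

#' @keywords internal
.kB <- 0.0019872041

#' @keywords internal
.V0 <- 1660
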