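#' Physical constants used by the transport calculations
#'
#' Single source of truth for the fundamental constants entering the
#' Marcus-theory transport chain. Energies are handled in eV throughout,
#' so Boltzmann's constant is given in eV/K and the reduced Planck
#' constant in eV·s; the elementary charge (in C) only enters where a
#' result must be expressed in SI electrical units.
#'
#' @return A list with components `e` (elementary charge, C), `hbar`
#'   (reduced Planck constant, eV·s) and `kB` (Boltzmann constant, eV/K).
#' @examples
#' physical_constants()$kB * 298  # thermal energy at 298 K, in eV
#' @export
physical_constants <- function() {
  list(
    e    = 1.602176634e-19,  # C (exact, SI 2019)
    hbar = 6.582119569e-16,  # eV s
    kB   = 8.617333262e-5    # eV / K
  )
}

# Angstrom to metre; all unit conversion happens at type boundaries.
.A_TO_M <- 1e-10
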