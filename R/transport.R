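# Marcus-theory charge transport chain: orbital splittings ->
# transfer integrals -> rate upper bound -> diffusion -> mobility ->
# carrier density -> conductivity -> conductance.

#' Dimer frontier-orbital energies
#'
#' Scalar outputs of an electronic-structure calculation on an aromatic
#' dimer, from which the energy-gap scheme extracts transfer integrals.
#'
#' @param E_HOMO,E_HOMOm1 Dimer HOMO and HOMO-1 energies, eV.
#' @param E_LUMO,E_LUMOp1 Dimer LUMO and LUMO+1 energies, eV.
#' @return Object of class `orbital_energies`.
#' @export
orbital_energies <- function(E_HOMO, E_HOMOm1, E_LUMO, E_LUMOp1) {
  if (E_HOMOm1 > E_HOMO)
    stop("orbital ordering violated: E_HOMO-1 > E_HOMO")
  if (E_LUMOp1 < E_LUMO)
    stop("orbital ordering violated: E_LUMO+1 < E_LUMO")
  structure(list(E_HOMO = E_HOMO, E_HOMOm1 = E_HOMOm1,
                 E_LUMO = E_LUMO, E_LUMOp1 = E_LUMOp1),
            class = "orbital_energies")
}

#' Transfer integrals from dimer orbital splittings
#'
#' Energy-gap scheme: the hole (electron) coupling is half the dimer
#' HOMO/HOMO-1 (LUMO+1/LUMO) splitting.
#'
#' @param energies An [orbital_energies()] object.
#' @return List with `t_hole` and `t_elec`, eV (non-negative).
#' @export
transfer_integral <- function(energies) {
  list(t_hole = (energies$E_HOMO - energies$E_HOMOm1) / 2,
       t_elec = (energies$E_LUMOp1 - energies$E_LUMO) / 2)
}

#' Four-point energies for the reorganization energy
#'
#' Single-point energies of donor (D) and acceptor (A) with subscripts
#' geometry then charge state: e.g. `E_cn_D` is the neutral donor in
#' its charged-state optimized geometry.
#'
#' @param E_cn_D,E_nn_D Donor energies (charged-geometry/neutral-charge
#'   and neutral-geometry/neutral-charge), eV.
#' @param E_nc_A,E_cc_A Acceptor energies (neutral-geometry/charged and
#'   charged-geometry/charged), eV.
#' @return Object of class `four_point_energies`.
#' @export
four_point_energies <- function(E_cn_D, E_nn_D, E_nc_A, E_cc_A) {
  vals <- c(E_cn_D, E_nn_D, E_nc_A, E_cc_A)
  if (!all(is.finite(vals))) stop("non-finite four-point energies")
  structure(list(E_cn_D = E_cn_D, E_nn_D = E_nn_D,
                 E_nc_A = E_nc_A, E_cc_A = E_cc_A),
            class = "four_point_energies")
}

#' Reorganization energy from four-point energies
#'
#' `lambda = (E_cn_D - E_nn_D) + (E_nc_A - E_cc_A)`: the donor and
#' acceptor relaxation costs of moving the charge.
#'
#' @param energies A [four_point_energies()] object.
#' @return Reorganization energy, eV.
#' @export
reorganization_energy <- function(energies) {
  (energies$E_cn_D - energies$E_nn_D) +
    (energies$E_nc_A - energies$E_cc_A)
}

#' Marcus rate upper bound
#'
#' The zero-driving-force (delta G = 0) prefactor of the Marcus
#' electron-transfer rate,
#' `w = (t^2 / hbar) * sqrt(pi / (lambda * kB * T))`
#' (equivalently `(2 pi / hbar) t^2 / sqrt(4 pi lambda kB T)`), which
#' bounds the rate from above when the driving force is unknown.
#'
#' @param t Transfer integral, eV.
#' @param lambda Reorganization energy, eV (> 0).
#' @param temperature Temperature, K (> 0); default 298.
#' @return Rate in s^-1.
#' @export
marcus_rate_upper <- function(t, lambda, temperature = 298) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  const <- physical_constants()
  (t^2 / const$hbar) * sqrt(pi / (lambda * const$kB * temperature))
}

#' One-dimensional diffusion coefficient
#'
#' `D = w0 * z0^2` for hopping at effective rate `w0` over a periodic
#' cell of height `z0` along the stacking axis.
#'
#' @param w0 Effective (bottleneck) transfer rate, s^-1.
#' @param z0 Height of the unit periodic cell, Angstrom.
#' @return Diffusion coefficient, m^2 s^-1.
#' @export
diffusion_coefficient <- function(w0, z0) {
  if (z0 <= 0) stop("z0 must be > 0")
  w0 * (z0 * .A_TO_M)^2
}

#' Charge mobility by the Einstein relation
#'
#' `mu = e D / (kB T)`; with the thermal energy expressed in eV this is
#' numerically `D / (kB_eV * T)`.
#'
#' @param D Diffusion coefficient, m^2 s^-1.
#' @param temperature Temperature, K (> 0); default 298.
#' @return Mobility, m^2 V^-1 s^-1.
#' @export
charge_mobility <- function(D, temperature = 298) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  D / (physical_constants()$kB * temperature)
}

#' Carrier number density of the aromatic packing
#'
#' Upper-bound carrier concentration: `carriers_per_cell` aromatic
#' sites (4 per smallest symmetric unit) in a cylindrical cell of
#' radius `r0` and height `z0`:
#' `rho = carriers_per_cell / (pi r0^2 z0)`.
#'
#' @param r0 Radius of the aromatic packing, Angstrom (default 13).
#' @param z0 Cell height, Angstrom.
#' @param carriers_per_cell Aromatic sites per cell (default 4).
#' @return Number density, m^-3.
#' @export
carrier_density <- function(r0 = 13, z0, carriers_per_cell = 4L) {
  if (r0 <= 0 || z0 <= 0) stop("r0 and z0 must be > 0")
  carriers_per_cell / (pi * (r0 * .A_TO_M)^2 * (z0 * .A_TO_M))
}

#' Electrical conductivity
#'
#' `sigma = e rho (mu_h + mu_e)`.
#'
#' @param rho Carrier density, m^-3.
#' @param mu_hole,mu_elec Hole and electron mobilities, m^2 V^-1 s^-1.
#' @return Conductivity, S m^-1.
#' @export
conductivity <- function(rho, mu_hole, mu_elec) {
  if (rho < 0 || mu_hole < 0 || mu_elec < 0)
    stop("negative transport inputs")
  physical_constants()$e * rho * (mu_hole + mu_elec)
}

#' Conductance of a conductor segment
#'
#' `G = sigma S / l` for cross-sectional area `S` and length `l`.
#'
#' @param sigma Conductivity, S m^-1.
#' @param area_S Cross-sectional area, Angstrom^2.
#' @param length_l Conductor length, Angstrom.
#' @return Conductance, S.
#' @export
conductance <- function(sigma, area_S, length_l) {
  if (area_S <= 0 || length_l <= 0) stop("area and length must be > 0")
  sigma * (area_S * .A_TO_M^2) / (length_l * .A_TO_M)
}

#' Transport input bundle
#'
#' Collects every scalar the transport chain needs. Defaults: T = 298 K
#' (reproduces the published mobilities from the published diffusion
#' coefficients to 3 significant figures); z0 = 3.10 Angstrom (periodic
#' cell height back-derived from the published rate/diffusion pairs);
#' r0 = 13 Angstrom; ring cross-section `area_S` = pi (1.39 + 1.7)^2
#' ~ 30 Angstrom^2 (carbocycle circumradius plus a carbon van der Waals
#' radius). `rho` may be supplied directly to override the cylindrical
#' cell estimate.
#'
#' @param t_hole,t_elec Transfer integrals, eV.
#' @param lambda Reorganization energy, eV.
#' @param temperature Temperature, K.
#' @param z0 Periodic cell height, Angstrom.
#' @param r0 Packing radius, Angstrom.
#' @param area_S Conductor cross-section, Angstrom^2.
#' @param length_l Conductor length, Angstrom (typically the bottleneck
#'   interaromatic distance); `NA` defers to the symmetric unit.
#' @param rho Optional direct carrier density, m^-3.
#' @param carriers_per_cell Aromatic sites per cell (default 4).
#' @return Object of class `transport_inputs`.
#' @export
transport_inputs <- function(t_hole, t_elec, lambda, temperature = 298,
                             z0 = 3.10, r0 = 13,
                             area_S = pi * (1.39 + 1.7)^2,
                             length_l = NA_real_, rho = NULL,
                             carriers_per_cell = 4L) {
  vals <- c(t_hole, t_elec, lambda, temperature, z0, r0, area_S)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("transport inputs must be finite and non-negative")
  if (lambda <= 0 || temperature <= 0 || z0 <= 0)
    stop("lambda, temperature and z0 must be > 0")
  structure(list(t_hole = t_hole, t_elec = t_elec, lambda = lambda,
                 temperature = temperature, z0 = z0, r0 = r0,
                 area_S = area_S, length_l = length_l, rho = rho,
                 carriers_per_cell = as.integer(carriers_per_cell)),
            class = "transport_inputs")
}

#' Read / write transport inputs as JSON
#'
#' Keys: `t_hole_eV`, `t_elec_eV`, `lambda_eV`, `temperature_K`,
#' `z0_A`, `r0_A`, `area_A2`, `length_A`, optional `rho_per_m3`.
#'
#' @param path JSON file path.
#' @param inputs A `transport_inputs` object (write).
#' @return A `transport_inputs` object (read); `path` invisibly
#'   (write).
#' @export
read_transport_inputs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transport_inputs(
    t_hole = x$t_hole_eV, t_elec = x$t_elec_eV, lambda = x$lambda_eV,
    temperature = if (!is.null(x$temperature_K)) x$temperature_K else 298,
    z0 = if (!is.null(x$z0_A)) x$z0_A else 3.10,
    r0 = if (!is.null(x$r0_A)) x$r0_A else 13,
    area_S = if (!is.null(x$area_A2)) x$area_A2 else pi * (1.39 + 1.7)^2,
    length_l = if (!is.null(x$length_A)) x$length_A else NA_real_,
    rho = x$rho_per_m3)
}

#' @rdname read_transport_inputs
#' @export
write_transport_inputs <- function(inputs, path) {
  jsonlite::write_json(list(
    t_hole_eV = inputs$t_hole, t_elec_eV = inputs$t_elec,
    lambda_eV = inputs$lambda, temperature_K = inputs$temperature,
    z0_A = inputs$z0, r0_A = inputs$r0, area_A2 = inputs$area_S,
    length_A = inputs$length_l, rho_per_m3 = inputs$rho),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Full Marcus transport chain for a symmetric pathway unit
#'
#' Chains the individual operations: per-carrier Marcus rate upper
#' bounds from (t, lambda, T); the effective rate `W0` is the minimum
#' per-step rate over the symmetric unit (with one coupling per carrier
#' this is the carrier's own rate, associated with the bottleneck
#' distance); diffusion over the periodic cell; Einstein mobility;
#' carrier density (direct or cylindrical-cell); conductivity; and
#' conductance over the bottleneck length. The result carries every
#' intermediate as an audit trail.
#'
#' @param unit A `symmetric_unit` (supplies the bottleneck length when
#'   `inputs$length_l` is `NA`), or `NULL` if `length_l` is given.
#' @param inputs A [transport_inputs()] object.
#' @return Object of class `transport_result` with fields `w_hole`,
#'   `w_elec` (s^-1), `D_hole`, `D_elec` (m^2 s^-1), `mu_hole`,
#'   `mu_elec` (m^2 V^-1 s^-1), `rho` (m^-3), `sigma` (S m^-1), `G`
#'   (S), plus the echoed `inputs` and `bottleneck_A`.
#' @export
transport_report <- function(unit, inputs) {
  stopifnot(inherits(inputs, "transport_inputs"))
  length_l <- inputs$length_l
  if (is.na(length_l)) {
    if (is.null(unit))
      stop("missing inputs: conductor length (supply length_l or a ",
           "symmetric unit)")
    length_l <- bottleneck_distance(unit)
  }
  w_hole <- marcus_rate_upper(inputs$t_hole, inputs$lambda,
                              inputs$temperature)
  w_elec <- marcus_rate_upper(inputs$t_elec, inputs$lambda,
                              inputs$temperature)
  D_hole <- diffusion_coefficient(w_hole, inputs$z0)
  D_elec <- diffusion_coefficient(w_elec, inputs$z0)
  mu_hole <- charge_mobility(D_hole, inputs$temperature)
  mu_elec <- charge_mobility(D_elec, inputs$temperature)
  rho <- if (!is.null(inputs$rho)) inputs$rho
         else carrier_density(inputs$r0, inputs$z0,
                              inputs$carriers_per_cell)
  sigma <- conductivity(rho, mu_hole, mu_elec)
  G <- conductance(sigma, inputs$area_S, length_l)
  structure(list(w_hole = w_hole, w_elec = w_elec,
                 D_hole = D_hole, D_elec = D_elec,
                 mu_hole = mu_hole, mu_elec = mu_elec,
                 rho = rho, sigma = sigma, G = G,
                 bottleneck_A = length_l, inputs = inputs),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result>\n")
  cat(sprintf("  rate bound w      : hole %.3e, electron %.3e s^-1\n",
              x$w_hole, x$w_elec))
  cat(sprintf("  diffusion D       : hole %.3e, electron %.3e m^2/s\n",
              x$D_hole, x$D_elec))
  cat(sprintf("  mobility mu       : hole %.3e, electron %.3e m^2/(V s)\n",
              x$mu_hole, x$mu_elec))
  cat(sprintf("  carrier density   : %.3e m^-3\n", x$rho))
  cat(sprintf("  conductivity sigma: %.2f S/m\n", x$sigma))
  cat(sprintf("  conductance G     : %.3e S (l = %.2f A)\n",
              x$G, x$bottleneck_A))
  invisible(x)
}

#' Transport result as a Table-1-style data frame
#'
#' @param result A `transport_result`.
#' @return Data frame with one row per quantity and hole/electron
#'   columns where applicable.
#' @export
transport_table <- function(result) {
  data.frame(
    quantity = c("Transfer integral (eV)",
                 "Rate upper bound (s^-1)",
                 "Diffusion coefficient (m^2 s^-1)",
                 "Charge mobility (m^2 V^-1 s^-1)",
                 "Carrier density (m^-3)",
                 "Conductivity (S m^-1)",
                 "Conductance (uS)"),
    hole = c(result$inputs$t_hole, result$w_hole, result$D_hole,
             result$mu_hole, NA, NA, NA),
    electron = c(result$inputs$t_elec, result$w_elec, result$D_elec,
                 result$mu_elec, NA, NA, NA),
    total = c(NA, NA, NA, NA, result$rho, result$sigma, result$G * 1e6))
}
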