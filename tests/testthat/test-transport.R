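# Marcus-theory transport chain.

test_that("transfer integrals are half the dimer splittings", {
  en <- orbital_energies(E_HOMO = -5.0, E_HOMOm1 = -5.2,
                         E_LUMO = -1.0, E_LUMOp1 = -0.9)
  ti <- transfer_integral(en)
  expect_equal(ti$t_hole, 0.1, tolerance = 1e-12)
  expect_equal(ti$t_elec, 0.05, tolerance = 1e-12)
  degen <- orbital_energies(-5, -5, -1, -1)
  expect_equal(transfer_integral(degen)$t_hole, 0)
  expect_error(orbital_energies(-5.2, -5.0, -1, -0.9), "ordering")
  expect_error(orbital_energies(-5.0, -5.2, -0.9, -1.0), "ordering")
})

test_that("reorganization energy sums donor and acceptor relaxations", {
  expect_equal(reorganization_energy(make_reorg_fixture(0.19, 0.18)),
               0.37, tolerance = 1e-12)
  same <- four_point_energies(-10, -10, -10, -10)
  expect_equal(reorganization_energy(same), 0)
  donor_only <- make_reorg_fixture(0.21, 0)
  expect_equal(reorganization_energy(donor_only), 0.21,
               tolerance = 1e-12)
})

test_that("marcus rate bound matches independent arithmetic", {
  expect_equal(marcus_rate_upper(0, 0.37, 298), 0)
  # independent evaluation of (t^2/hbar) sqrt(pi / (lambda kB T))
  tvals <- c(3.25e-2, 1.56e-2, 2.93e-2, 1.46e-2)
  for (t in tvals) {
    oracle <- (t^2 / 6.582119569e-16) *
      sqrt(pi / (0.37 * 8.617333262e-5 * 298))
    expect_equal(marcus_rate_upper(t, 0.37, 298), oracle,
                 tolerance = 1e-12)
  }
  expect_equal(marcus_rate_upper(3.25e-2, 0.37, 298), 2.918e13,
               tolerance = 1e-3)
  # quadratic in the coupling
  expect_equal(marcus_rate_upper(2 * 0.02, 0.37, 298),
               4 * marcus_rate_upper(0.02, 0.37, 298),
               tolerance = 1e-12)
  expect_error(marcus_rate_upper(0.02, 0, 298), "lambda")
  expect_error(marcus_rate_upper(0.02, 0.37, -1), "temperature")
})

test_that("diffusion coefficient converts the cell height correctly", {
  expect_equal(diffusion_coefficient(1e13, 1), 1e-7, tolerance = 1e-12)
  expect_equal(diffusion_coefficient(0, 3.1), 0)
  w <- marcus_rate_upper(3.25e-2, 0.37, 298)
  expect_equal(diffusion_coefficient(w, 3.10), w * (3.10e-10)^2,
               tolerance = 1e-12)
  expect_equal(diffusion_coefficient(w, 3.10), 2.8e-6,
               tolerance = 0.01)
})

test_that("Einstein mobility reproduces the published pairs at 298 K", {
  # (D, mu) pairs for both pilus models, hole and electron carriers
  pairs <- rbind(c(2.81e-6, 1.09e-4), c(6.50e-7, 2.53e-5),
                 c(2.28e-6, 8.86e-5), c(5.65e-7, 2.19e-5))
  for (i in seq_len(nrow(pairs)))
    expect_equal(charge_mobility(pairs[i, 1L], 298), pairs[i, 2L],
                 tolerance = 0.01)
  # the implied mu/D ratios agree with each other within 1 %
  ratios <- pairs[, 2L] / pairs[, 1L]
  expect_lt((max(ratios) - min(ratios)) / mean(ratios), 0.01)
  expect_equal(charge_mobility(0, 298), 0)
})

test_that("carrier density follows the cylindrical cell formula", {
  expect_equal(carrier_density(13, 18.83), 4.00e26, tolerance = 0.005)
  expect_equal(carrier_density(13, 2 * 18.83),
               carrier_density(13, 18.83) / 2, tolerance = 1e-12)
  expect_equal(carrier_density(13, 18.83, carriers_per_cell = 0L), 0)
})

test_that("conductivity reproduces the published values from mobilities", {
  expect_equal(conductivity(4.00e26, 2.53e-5, 1.09e-4), 8601.51,
               tolerance = 0.005)
  expect_equal(conductivity(4.00e26, 2.19e-5, 8.86e-5), 7073.26,
               tolerance = 0.005)
  expect_equal(conductivity(0, 1e-5, 1e-5), 0)
})

test_that("conductance converts geometry to SI exactly", {
  expect_equal(conductance(1, 1e20, 1e10), 1, tolerance = 1e-12)
  expect_equal(conductance(8.60e3, 30, 6.1), 4.23e-6, tolerance = 0.01)
  expect_equal(conductance(100, 30, 12.2),
               conductance(100, 30, 6.1) / 2, tolerance = 1e-12)
  expect_error(conductance(1, -1, 1), "area")
})

test_that("transport_report equals the manual composition of operations", {
  inp <- transport_inputs(t_hole = 1.56e-2, t_elec = 3.25e-2,
                          lambda = 0.37, length_l = 6.1, rho = 4.00e26)
  res <- transport_report(NULL, inp)
  w_h <- marcus_rate_upper(1.56e-2, 0.37, 298)
  w_e <- marcus_rate_upper(3.25e-2, 0.37, 298)
  D_h <- diffusion_coefficient(w_h, 3.10)
  D_e <- diffusion_coefficient(w_e, 3.10)
  mu_h <- charge_mobility(D_h, 298)
  mu_e <- charge_mobility(D_e, 298)
  sig <- conductivity(4.00e26, mu_h, mu_e)
  expect_identical(res$w_hole, w_h)
  expect_identical(res$w_elec, w_e)
  expect_identical(res$D_hole, D_h)
  expect_identical(res$mu_elec, mu_e)
  expect_identical(res$sigma, sig)
  expect_identical(res$G, conductance(sig, inp$area_S, 6.1))
})

test_that("zero couplings give an all-zero transport result", {
  inp <- transport_inputs(t_hole = 0, t_elec = 0, lambda = 0.37,
                          length_l = 5, rho = 4.00e26)
  res <- transport_report(NULL, inp)
  expect_equal(res$w_hole + res$w_elec + res$D_hole + res$mu_elec +
                 res$sigma + res$G, 0)
})

test_that("the chain is homogeneous of degree 2 in the couplings", {
  base <- transport_inputs(t_hole = 1.46e-2, t_elec = 2.93e-2,
                           lambda = 0.37, length_l = 5.9, rho = 4.00e26)
  for (c_scale in c(2, 3, 0.5)) {
    scaled <- transport_inputs(t_hole = c_scale * base$t_hole,
                               t_elec = c_scale * base$t_elec,
                               lambda = 0.37, length_l = 5.9,
                               rho = 4.00e26)
    r1 <- transport_report(NULL, base)
    r2 <- transport_report(NULL, scaled)
    expect_equal(r2$sigma / r1$sigma, c_scale^2, tolerance = 1e-9)
    expect_equal(r2$G / r1$G, c_scale^2, tolerance = 1e-9)
  }
})

test_that("the bottleneck length comes from the symmetric unit", {
  spec <- synthetic_spec()
  asm <- make_pathway_pilus(spec)
  g <- build_ring_graph(asm, 7)
  p <- shortest_ring_path(g, "s1:r1", sprintf("s%d:r1", spec$n_subunits))
  u <- extract_symmetric_unit(g, p, 7L)
  inp <- transport_inputs(t_hole = 1.56e-2, t_elec = 3.25e-2,
                          lambda = 0.37, rho = 4.00e26)
  res <- transport_report(u, inp)
  expect_equal(res$bottleneck_A, 6.1, tolerance = 1e-6)
  expect_error(transport_report(NULL, inp), "length")
})

test_that("transport inputs round-trip through JSON", {
  inp <- transport_inputs(t_hole = 1.56e-2, t_elec = 3.25e-2,
                          lambda = 0.37, temperature = 300, z0 = 3.2,
                          r0 = 12, area_S = 28, length_l = 6.1,
                          rho = 3.9e26)
  path <- withr::local_tempfile(fileext = ".json")
  write_transport_inputs(inp, path)
  back <- read_transport_inputs(path)
  for (f in c("t_hole", "t_elec", "lambda", "temperature", "z0", "r0",
              "area_S", "length_l", "rho"))
    expect_equal(back[[f]], inp[[f]], tolerance = 1e-12)
})

test_that("the transport table mirrors the result fields", {
  inp <- transport_inputs(t_hole = 1.56e-2, t_elec = 3.25e-2,
                          lambda = 0.37, length_l = 6.1, rho = 4.00e26)
  res <- transport_report(NULL, inp)
  tab <- transport_table(res)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$electron[4L], res$mu_elec)
  expect_equal(tab$total[6L], res$sigma)
  expect_equal(tab$total[7L], res$G * 1e6)
})
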