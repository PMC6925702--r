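# Synthetic fixtures: ideal hexagonal rings, an idealized
# aromatic-bearing pilin, planted-parameter pilus assemblies, rotation
# angle ensembles and orbital-energy tables. Every generator is
# deterministic under a fixed seed.

#' Specification for the synthetic generators
#'
#' Bundles the seed, the coordinate noise, the planted helical and
#' pathway parameters and the angle-ensemble layout consumed by the
#' generators. Defaults plant the lowest-energy pilus model's pathway
#' geometry (d1 = 3.9, d2 = 6.1, d3 = 5.1 Angstrom) on a right-handed
#' helix rotating 100.8 degrees per subunit (the type IV pilus symmetry
#' of the homologous reference filament) with a 13 A rise, chosen so
#' the planted three-step chain is the unique inter-ring geodesic at
#' the default 7 A graph cutoff (see [make_pathway_pilus()]).
#'
#' @param seed Integer RNG seed.
#' @param noise Coordinate noise sigma, Angstrom (>= 0).
#' @param rise,rotation,n_subunits Planted helical parameters.
#' @param d1,d2,d3 Pathway distances to plant, Angstrom.
#' @param blob_centers,blob_sizes,blob_spread Rotation-angle ensemble
#'   layout for the clustering fixtures: blob centers (degrees), sizes
#'   and half-width of the uniform spread.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, noise = 0,
                           rise = 13, rotation = 100.8,
                           n_subunits = 14L,
                           d1 = 3.9, d2 = 6.1, d3 = 5.1,
                           blob_centers = c(58, 112, 146),
                           blob_sizes = c(55L, 30L, 15L),
                           blob_spread = 8) {
  if (noise < 0) stop("noise must be >= 0")
  structure(list(seed = as.integer(seed), noise = noise, rise = rise,
                 rotation = rotation, n_subunits = as.integer(n_subunits),
                 d1 = d1, d2 = d2, d3 = d3,
                 blob_centers = blob_centers, blob_sizes = blob_sizes,
                 blob_spread = blob_spread),
            class = "synthetic_spec")
}

# Orthonormal in-plane basis perpendicular to a unit normal.
plane_basis <- function(normal) {
  ref <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2L] * u[3L] - normal[3L] * u[2L],
         normal[3L] * u[1L] - normal[1L] * u[3L],
         normal[1L] * u[2L] - normal[2L] * u[1L])
  list(u = u, v = v)
}

# Hexagon vertex order around the ring (bonded neighbors adjacent).
RING_CYCLE <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")

#' Ideal hexagonal aromatic ring
#'
#' A regular hexagon of C-C bond length 1.39 Angstrom (so circumradius
#' 1.39 A) in the plane perpendicular to `normal`, centered exactly at
#' `center`, with atoms named CG, CD1, CD2, CE1, CE2, CZ in bonded
#' order around the cycle.
#'
#' @param center Ring centroid, length-3 vector (Angstrom).
#' @param normal Unit ring normal.
#' @param type `"F"` or `"Y"`.
#' @param in_plane_rotation Rotation of the vertices about the normal,
#'   degrees.
#' @param chain,resno,subunit Identity stamped on the ring.
#' @return An [aromatic_ring()] object.
#' @export
make_ring <- function(center, normal = c(0, 0, 1), type = "F",
                      in_plane_rotation = 0, chain = "A", resno = 1L,
                      subunit = NA_integer_) {
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("zero ring normal")
  normal <- normal / nrm
  basis <- plane_basis(normal)
  ang <- (in_plane_rotation + seq(0, 300, by = 60)) * pi / 180
  verts <- t(vapply(ang, function(a)
    center + 1.39 * (cos(a) * basis$u + sin(a) * basis$v), numeric(3L)))
  rownames(verts) <- RING_CYCLE
  coords <- verts[RING_ATOMS, , drop = FALSE]
  aromatic_ring(coords, chain = chain, resno = resno, type = type,
                subunit = subunit)
}

# Atom table rows for one aromatic residue built from a ring (ring
# carbons only, plus the Tyr hydroxyl for realism).
ring_atom_rows <- function(ring, chain, resno, resname, serial_start) {
  nm <- rownames(ring$coords)
  df <- data.frame(serial = seq.int(serial_start,
                                    serial_start + length(nm) - 1L),
                   name = nm, resname = resname, chain = chain,
                   resno = resno,
                   x = ring$coords[, 1L], y = ring$coords[, 2L],
                   z = ring$coords[, 3L], element = "C",
                   stringsAsFactors = FALSE)
  if (resname == "TYR") {
    cz <- ring$coords["CZ", ]
    dir <- cz - ring$centroid
    oh <- cz + 1.36 * dir / sqrt(sum(dir^2))
    df <- rbind(df, data.frame(serial = serial_start + length(nm),
                               name = "OH", resname = resname,
                               chain = chain, resno = resno,
                               x = oh[1L], y = oh[2L], z = oh[3L],
                               element = "O", stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  df
}

# Mature-sequence aromatic layout: F at 1, 24, 51; Y at 27, 32, 57.
AROMATIC_LAYOUT <- c(`1` = "PHE", `24` = "PHE", `27` = "TYR",
                     `32` = "TYR", `51` = "PHE", `57` = "TYR")

#' Idealized aromatic-bearing pilin
#'
#' A 61-residue poly-alanine alpha-helix (textbook geometry: 1.5 A rise
#' and 100 degrees twist per residue, giving 3.8 A between consecutive
#' C-alpha atoms) carrying full six-carbon aromatic rings at the
#' mature-sequence positions 1, 24, 27, 32, 51 and 57 (Phe at 1, 24,
#' 51; Tyr at 27, 32, 57). The ring centroid sits 3.4 A radially
#' outward from the C-alpha. Gaussian coordinate noise of sd
#' `spec$noise` is added under `spec$seed`; zero noise gives
#' byte-identical output for equal seeds.
#'
#' @param spec A [synthetic_spec()].
#' @param chain Chain id (default `"A"`).
#' @return A [pilin_structure()] with 61 residues and 6 aromatic rings.
#' @export
make_ideal_pilin <- function(spec = synthetic_spec(), chain = "A") {
  n_res <- 61L
  rise <- 1.5; twist <- 100  # per residue
  # C-alpha helix radius giving 3.8 A between consecutive C-alphas
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2 * pi / 180))
  rows <- list()
  serial <- 1L
  for (i in seq_len(n_res)) {
    th <- (i - 1L) * twist * pi / 180
    z <- (i - 1L) * rise
    ca <- c(radius * cos(th), radius * sin(th), z)
    outward <- c(cos(th), sin(th), 0)
    resname <- if (as.character(i) %in% names(AROMATIC_LAYOUT))
      AROMATIC_LAYOUT[[as.character(i)]] else "ALA"
    # simplified backbone: N/C flank the C-alpha along the helix path
    n_at <- c(radius * cos(th - 0.35), radius * sin(th - 0.35), z - 0.55)
    c_at <- c(radius * cos(th + 0.35), radius * sin(th + 0.35), z + 0.55)
    o_at <- c_at + 1.23 * outward
    cb <- ca + 1.53 * outward
    bk <- data.frame(
      serial = seq.int(serial, serial + 4L),
      name = c("N", "CA", "C", "O", "CB"), resname = resname,
      chain = chain, resno = i,
      x = c(n_at[1L], ca[1L], c_at[1L], o_at[1L], cb[1L]),
      y = c(n_at[2L], ca[2L], c_at[2L], o_at[2L], cb[2L]),
      z = c(n_at[3L], ca[3L], c_at[3L], o_at[3L], cb[3L]),
      element = c("N", "C", "C", "O", "C"), stringsAsFactors = FALSE)
    serial <- serial + 5L
    rows[[length(rows) + 1L]] <- bk
    if (resname != "ALA") {
      ring <- make_ring(center = ca + 3.4 * outward,
                        normal = c(-sin(th), cos(th), 0),
                        type = unname(AROMATIC_RESIDUES[resname]),
                        chain = chain, resno = i)
      rr <- ring_atom_rows(ring, chain, i, resname, serial)
      serial <- serial + nrow(rr)
      rows[[length(rows) + 1L]] <- rr
    }
  }
  atoms <- do.call(rbind, rows)
  if (spec$noise > 0) {
    atoms[, c("x", "y", "z")] <- with_local_seed(spec$seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(atoms), sd = spec$noise),
               ncol = 3L))
  }
  pilin_structure(atoms)
}

#' Pilus assembly with planted pathway distances
#'
#' Builds an assembly whose F1/F24/Y27 rings realize the planted
#' consecutive interaromatic distances (d1, d2, d3) exactly, repeating
#' with the helical period, while Y32/F51/Y57 sit more than 8 A away
#' from every pathway ring (mimicking the large intra-subunit
#' separations of the isolated pilin, so they stay off the transfer
#' path at the default 7 A graph cutoff).
#'
#' Construction: F1, F24 and Y27 of one subunit are stacked on a line
#' parallel to the axis at radius r, separated by d1 and d2; the
#' closing distance to F1 of the next subunit fixes r through the
#' screw operation, so the triple is realizable iff
#' `d3^2 > (rise - d1 - d2)^2`. The generator additionally verifies
#' that no other pair of pathway rings comes within 7 A, i.e. that the
#' planted chain is the unique geodesic at the default graph cutoff,
#' and raises an infeasibility error otherwise.
#'
#' @param spec A [synthetic_spec()]; `rise`, `rotation`, `n_subunits`,
#'   `d1`-`d3`, `noise` and `seed` are used.
#' @return A `pilus_assembly`.
#' @export
make_pathway_pilus <- function(spec = synthetic_spec()) {
  chord2 <- spec$d3^2 - (spec$rise - (spec$d1 + spec$d2))^2
  if (chord2 <= 0)
    stop(sprintf(
      "unrealizable pathway distances (%.2f, %.2f, %.2f) at rise %.2f: ",
      spec$d1, spec$d2, spec$d3, spec$rise),
      "d3^2 must exceed (rise - d1 - d2)^2")
  r <- sqrt(chord2) / (2 * sin(spec$rotation / 2 * pi / 180))
  path_z <- c(0, spec$d1, spec$d1 + spec$d2)
  off_r <- r + 9
  off_z <- c(2, 5, 8)
  centers <- list(`1` = c(r, 0, path_z[1L]),
                  `24` = c(r, 0, path_z[2L]),
                  `27` = c(r, 0, path_z[3L]),
                  `32` = c(-off_r, 0, off_z[1L]),
                  `51` = c(-off_r, 0, off_z[2L]),
                  `57` = c(-off_r, 0, off_z[3L]))
  rows <- list(); serial <- 1L
  for (rn in names(AROMATIC_LAYOUT)) {
    resname <- AROMATIC_LAYOUT[[rn]]
    ring <- make_ring(center = centers[[rn]], normal = c(0, 0, 1),
                      type = unname(AROMATIC_RESIDUES[resname]),
                      chain = "A", resno = as.integer(rn))
    rr <- ring_atom_rows(ring, "A", as.integer(rn), resname, serial)
    serial <- serial + nrow(rr)
    rows[[length(rows) + 1L]] <- rr
  }
  subunit <- pilin_structure(do.call(rbind, rows))
  params <- helical_params(rise = spec$rise, rotation = spec$rotation,
                           n_subunits = spec$n_subunits,
                           radius_to_com = r)
  assembly <- apply_helical_symmetry(subunit, params)
  if (spec$noise > 0) {
    assembly$subunits <- with_local_seed(spec$seed,
      lapply(assembly$subunits, function(s) {
        s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] +
          matrix(stats::rnorm(3L * nrow(s$atoms), sd = spec$noise),
                 ncol = 3L)
        s
      }))
  }
  # verify the planted geometry on the noise-free construction: the
  # off-path rings keep their >= 8 A margin and the planted chain is
  # the only set of pathway edges under a 7 A cutoff
  if (spec$noise == 0) {
    rings <- assembly_rings(assembly)
    on_path <- vapply(rings, function(x) x$resno %in% c(1L, 24L, 27L),
                      logical(1L))
    for (a in rings[!on_path]) for (b in rings[on_path]) {
      if (interaromatic_distance(a, b) < 8)
        stop("unrealizable pathway distances: off-path ring within ",
             "8 A of the pathway")
    }
    pr <- rings[on_path]
    planted_step <- function(a, b) {
      (a$subunit == b$subunit &&
         paste(a$resno, b$resno) %in% c("1 24", "24 1", "24 27", "27 24")) ||
      (abs(a$subunit - b$subunit) == 1L &&
         paste(min(a$resno, b$resno), max(a$resno, b$resno)) == "1 27")
    }
    for (i in seq_along(pr)) for (j in seq_along(pr)) {
      if (j <= i) next
      close_enough <- interaromatic_distance(pr[[i]], pr[[j]]) <= 7
      if (close_enough && !planted_step(pr[[i]], pr[[j]]))
        stop(sprintf(
          "unrealizable pathway distances: stray contact %s - %s ",
          ring_id(pr[[i]]), ring_id(pr[[j]])),
          "under the 7 A cutoff; the planted chain would not be the ",
          "unique geodesic")
    }
  }
  assembly
}

#' Synthetic rotation-angle model ensemble
#'
#' Draws rotation angles from uniform blobs (one per cluster center)
#' with pseudo-energies increasing away from the first blob, emulating
#' the clustered docking-model ensembles used to pick the converged
#' basin.
#'
#' @param spec A [synthetic_spec()]; uses `blob_centers`, `blob_sizes`,
#'   `blob_spread` and `seed`.
#' @return Data frame with `id`, `rotation_angle`, `energy_score`.
#' @export
make_angle_ensemble <- function(spec = synthetic_spec()) {
  with_local_seed(spec$seed, {
    rows <- lapply(seq_along(spec$blob_centers), function(b) {
      ang <- stats::runif(spec$blob_sizes[b],
                          spec$blob_centers[b] - spec$blob_spread,
                          spec$blob_centers[b] + spec$blob_spread)
      data.frame(rotation_angle = ang,
                 energy_score = -30 + 5 * (b - 1L) +
                   stats::rnorm(spec$blob_sizes[b], sd = 1))
    })
    out <- do.call(rbind, rows)
    out$id <- sprintf("model_%03d", seq_len(nrow(out)))
    out[, c("id", "rotation_angle", "energy_score")]
  })
}

#' Dimer orbital-energy fixture with prescribed transfer integrals
#'
#' Builds an [orbital_energies()] object whose HOMO/HOMO-1 and
#' LUMO+1/LUMO splittings are exactly `2 * t_hole` and `2 * t_elec`, so
#' [transfer_integral()] inverts it exactly. The absolute energies are
#' gauge: shifting `base_energy` leaves the integrals unchanged.
#'
#' @param t_hole,t_elec Target transfer integrals, eV (>= 0).
#' @param base_energy Dimer HOMO energy, eV (default -5).
#' @param gap HOMO-LUMO gap, eV (default 3).
#' @return An `orbital_energies` object.
#' @export
make_orbital_fixture <- function(t_hole, t_elec, base_energy = -5,
                                 gap = 3) {
  if (t_hole < 0 || t_elec < 0) stop("transfer integrals must be >= 0")
  orbital_energies(E_HOMO = base_energy,
                   E_HOMOm1 = base_energy - 2 * t_hole,
                   E_LUMO = base_energy + gap,
                   E_LUMOp1 = base_energy + gap + 2 * t_elec)
}

#' Four-point reorganization-energy fixture
#'
#' Builds a [four_point_energies()] object whose donor and acceptor
#' relaxation terms are `lambda_D` and `lambda_A`, so
#' [reorganization_energy()] returns `lambda_D + lambda_A` exactly.
#'
#' @param lambda_D,lambda_A Donor and acceptor components, eV.
#' @param base_energy Reference energy, eV (gauge; default -1000).
#' @return A `four_point_energies` object.
#' @export
make_reorg_fixture <- function(lambda_D, lambda_A,
                               base_energy = -1000) {
  four_point_energies(E_cn_D = base_energy + lambda_D,
                      E_nn_D = base_energy,
                      E_nc_A = base_energy + lambda_A,
                      E_cc_A = base_energy)
}
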