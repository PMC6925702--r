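# Helical assembly: symmetry operator, assembly construction and
# geometric measurements.

#' Helical symmetry parameters
#'
#' The rigid-body screw operation relating consecutive subunits of a
#' helical polymer: an axial rise (Angstrom) plus an azimuthal rotation
#' (degrees) about the helix axis. The convention is right-handed:
#' positive rotation is counter-clockwise looking down +z; set
#' `handedness = "left"` to flip.
#'
#' @param rise Rise per subunit, Angstrom (> 0).
#' @param rotation Rotation per subunit, degrees in (0, 360).
#' @param n_subunits Number of subunits (>= 1); default 21.
#' @param radius_to_com Distance from the axis to the subunit center of
#'   mass, Angstrom (informational; used by [align_to_axis()]).
#' @param handedness `"right"` (default) or `"left"`.
#' @return An object of class `helical_params`.
#' @export
helical_params <- function(rise, rotation, n_subunits = 21L,
                           radius_to_com = NA_real_,
                           handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  if (!is.finite(rise) || rise <= 0) stop("rise must be > 0")
  if (!is.finite(rotation) || rotation <= 0 || rotation >= 360)
    stop("rotation must lie in (0, 360) degrees")
  if (n_subunits < 1L) stop("n_subunits must be >= 1")
  structure(list(rise = rise, rotation = rotation,
                 n_subunits = as.integer(n_subunits),
                 radius_to_com = radius_to_com, handedness = handedness),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "<helical_params> rise %.3f A, rotation %.3f deg, n = %d (%s-handed)\n",
    x$rise, x$rotation, x$n_subunits, x$handedness))
  invisible(x)
}

# Rotation matrix about +z by `deg` degrees (counter-clockwise from +z).
rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3L, 3L, byrow = TRUE)
}

# Apply a rigid transform x -> R x + t to all atoms of a pilin;
# optionally relabel the chain.
transform_pilin <- function(structure, rotation = diag(3L),
                            translation = c(0, 0, 0), chain = NULL) {
  xyz <- pilin_coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, `+`)
  atoms <- structure$atoms
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  if (!is.null(chain)) atoms$chain <- chain
  pilin_structure(atoms)
}

# Chain id sequence: A..Z, then AA, AB, ... (two-character ids; these
# cannot be written to fixed-column PDB, see write_pdb()).
chain_id_seq <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  two <- paste0(rep(LETTERS, each = 26L), rep(LETTERS, times = 26L))
  c(LETTERS, two[seq_len(extra)])
}

#' Align a pilin subunit to the helix axis
#'
#' Rotates the structure so the principal axis of the C-alpha atoms of
#' the designated helical segment (default: all residues) is parallel to
#' +z, with the N-to-C direction pointing up. If `radius_to_com` is
#' given, the center of mass is then translated in the xy-plane onto the
#' +x direction at that radial distance; the axial position is left
#' unchanged. The operation is idempotent.
#'
#' @param structure A `pilin` object with >= 3 C-alpha atoms in the
#'   segment.
#' @param segment Optional `c(first_resno, last_resno)` delimiting the
#'   helical segment used to define the axis.
#' @param radius_to_com Optional target radial distance of the center of
#'   mass from the z-axis, Angstrom.
#' @return The aligned `pilin`.
#' @export
align_to_axis <- function(structure, segment = NULL, radius_to_com = NULL) {
  a <- structure$atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  if (!is.null(segment))
    ca <- ca[ca$resno >= segment[1L] & ca$resno <= segment[2L], , drop = FALSE]
  if (nrow(ca) < 3L)
    stop("axis alignment needs >= 3 C-alpha atoms in the segment")
  X <- as.matrix(ca[, c("x", "y", "z")])
  X0 <- sweep(X, 2L, colMeans(X))
  if (all(abs(X0) < 1e-9)) stop("degenerate (coincident) C-alpha set")
  sv <- svd(X0)
  v <- sv$v[, 1L]
  # orient N -> C along +v
  if (sum(X0[nrow(X0), ] * v) - sum(X0[1L, ] * v) < 0) v <- -v
  # rotation taking v onto +z (Rodrigues)
  z <- c(0, 0, 1)
  cosang <- sum(v * z)
  if (cosang < 1 - 1e-12) {
    if (cosang < -1 + 1e-12) {
      R <- diag(c(1, -1, -1))  # 180 deg about x
    } else {
      k <- c(v[2L] * z[3L] - v[3L] * z[2L],
             v[3L] * z[1L] - v[1L] * z[3L],
             v[1L] * z[2L] - v[2L] * z[1L])
      k <- k / sqrt(sum(k^2))
      K <- matrix(c(0, -k[3L], k[2L], k[3L], 0, -k[1L], -k[2L], k[1L], 0),
                  3L, 3L, byrow = TRUE)
      sinang <- sqrt(max(0, 1 - cosang^2))
      R <- diag(3L) + sinang * K + (1 - cosang) * (K %*% K)
    }
  } else R <- diag(3L)
  out <- transform_pilin(structure, rotation = R)
  if (!is.null(radius_to_com)) {
    com <- colMeans(pilin_coords(out))
    out <- transform_pilin(out,
                           translation = c(radius_to_com - com[1L],
                                           -com[2L], 0))
  }
  out
}

#' Build a pilus assembly by applying the helical symmetry operator
#'
#' Subunit i (i = 0 .. n-1) is the input subunit rotated by i times the
#' rotation angle about +z and translated by i times the rise along +z.
#' Chains are labelled A, B, C, ... in order (two-character ids beyond
#' 26 subunits).
#'
#' @param subunit An axis-aligned `pilin`.
#' @param params A [helical_params()] object.
#' @return An object of class `pilus_assembly` with elements `params`
#'   and `subunits`.
#' @export
apply_helical_symmetry <- function(subunit, params) {
  stopifnot(inherits(params, "helical_params"))
  sgn <- if (params$handedness == "right") 1 else -1
  ids <- chain_id_seq(params$n_subunits)
  subunits <- lapply(seq_len(params$n_subunits) - 1L, function(i) {
    transform_pilin(subunit,
                    rotation = rotation_z(sgn * i * params$rotation),
                    translation = c(0, 0, i * params$rise),
                    chain = ids[i + 1L])
  })
  structure(list(params = params, subunits = subunits),
            class = "pilus_assembly")
}

#' @export
print.pilus_assembly <- function(x, ...) {
  cat(sprintf("<pilus_assembly> %d subunits (%s), rise %.3f A, rotation %.3f deg\n",
              length(x$subunits),
              paste0(x$subunits[[1L]]$chain, "..",
                     x$subunits[[length(x$subunits)]]$chain),
              x$params$rise, x$params$rotation))
  invisible(x)
}

#' Recover helical parameters from an assembly
#'
#' Estimates the rise as the mean axial displacement between
#' consecutive subunit centroids and the rotation as the mean azimuthal
#' displacement of the centroids about +z. Exact on ideal assemblies;
#' on noisy ones the error scales with the coordinate noise.
#'
#' @param assembly A `pilus_assembly` with >= 2 subunits of identical
#'   atom counts.
#' @return A [helical_params()] object (handedness as observed).
#' @export
estimate_helical_params <- function(assembly) {
  subs <- assembly$subunits
  if (length(subs) < 2L)
    stop("parameter estimation needs >= 2 subunits")
  counts <- vapply(subs, function(s) nrow(s$atoms), integer(1L))
  if (length(unique(counts)) != 1L)
    stop("subunit atom counts differ")
  cents <- t(vapply(subs, function(s) colMeans(pilin_coords(s)),
                    numeric(3L)))
  rises <- diff(cents[, 3L])
  ang <- atan2(cents[, 2L], cents[, 1L]) * 180 / pi
  dang <- diff(ang)
  dang <- (dang + 360) %% 360         # into [0, 360)
  right_handed <- mean(dang) <= 180
  rot <- if (right_handed) mean(dang) else 360 - mean(dang)
  helical_params(rise = mean(rises), rotation = rot,
                 n_subunits = length(subs),
                 radius_to_com = mean(sqrt(cents[, 1L]^2 + cents[, 2L]^2)),
                 handedness = if (right_handed) "right" else "left")
}

#' Pilus diameter
#'
#' Twice the maximum radial distance of any atom from the helix axis
#' (+z). Defined from atom centers; add `padding` (e.g. a van der Waals
#' radius) to each side if a surface diameter is wanted.
#'
#' @param assembly A non-empty `pilus_assembly`.
#' @param padding Radial padding per side, Angstrom (default 0).
#' @return Diameter in Angstrom.
#' @export
measure_diameter <- function(assembly, padding = 0) {
  subs <- assembly$subunits
  if (length(subs) == 0L) stop("empty assembly")
  rmax <- max(vapply(subs, function(s) {
    xyz <- pilin_coords(s)
    sqrt(max(xyz[, 1L]^2 + xyz[, 2L]^2))
  }, numeric(1L)))
  2 * (rmax + padding)
}
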