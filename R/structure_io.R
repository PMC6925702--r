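# Structure I/O: PDB reading/writing, aromatic ring extraction,
# Kabsch superposition and hydropathy profiles.

RING_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
AROMATIC_RESIDUES <- c(PHE = "F", TYR = "Y")

#' Construct a pilin structure from an atom table
#'
#' A pilin structure is the per-chain container for all coordinate-based
#' operations: one chain of a (mature-numbered) pilin subunit with its
#' ordered residues and atoms.
#'
#' @param atoms Data frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `element`.
#' @return An object of class `pilin`.
#' @export
pilin_structure <- function(atoms) {
  required <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom table")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$resno < 1L))
    stop("residue numbers must be >= 1 (mature-pilin numbering)")
  if (length(unique(atoms$chain)) != 1L)
    stop("a pilin structure holds exactly one chain")
  resno_order <- unique(atoms$resno)
  if (is.unsorted(resno_order, strictly = TRUE))
    stop("residue numbers must be strictly increasing within the chain")
  structure(list(chain = atoms$chain[1L],
                 atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "pilin")
}

#' @export
print.pilin <- function(x, ...) {
  cat(sprintf("<pilin> chain %s: %d residues, %d atoms\n",
              x$chain, length(unique(x$atoms$resno)), nrow(x$atoms)))
  invisible(x)
}

#' Coordinate matrix of a pilin structure
#'
#' @param structure A `pilin` object.
#' @return An n x 3 numeric matrix of atom positions (Angstrom).
#' @export
pilin_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' One-letter amino-acid sequence of a pilin structure
#'
#' @param structure A `pilin` object.
#' @return Character scalar, one letter per residue in chain order;
#'   unknown residue names become `X`.
#' @export
pilin_sequence <- function(structure) {
  first <- structure$atoms[!duplicated(structure$atoms$resno), ]
  letters1 <- bio3d::aa321(first$resname)
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# ---------------------------------------------------------------------------
# PDB reading / writing (format handling delegated to bio3d)

#' Read a PDB file into pilin structures
#'
#' Parses ATOM/HETATM records and returns one structure per chain. Only
#' the first altloc of each atom is kept; for multi-model (NMR) files a
#' single model is read (the first by default).
#'
#' @param path Path to a PDB file.
#' @param model Model index for multi-model files (default 1).
#' @return A named list of [pilin_structure()] objects, one per chain.
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_idx) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path)
  # validate the fixed-column coordinate fields before delegating
  for (i in atom_idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed ATOM record at line %d: too short", i))
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed ATOM record at line %d: bad coordinate field", i))
  }
  pdb <- bio3d::read.pdb(path, multi = (model > 1L), verbose = FALSE)
  atoms <- pdb$atom
  if (model > 1L) {
    if (model > nrow(pdb$xyz)) stop("model index out of range: ", model)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }
  # keep first altloc: blank/'A' or first occurrence per (chain, resno, name)
  keep <- atoms$alt %in% c("", " ", NA, "A")
  atoms <- atoms[keep, , drop = FALSE]
  dup <- duplicated(atoms[, c("chain", "resno", "elety")])
  atoms <- atoms[!dup, , drop = FALSE]
  atoms$chain[is.na(atoms$chain)] <- "A"
  out <- lapply(split(seq_len(nrow(atoms)), atoms$chain), function(idx) {
    a <- atoms[idx, , drop = FALSE]
    pilin_structure(data.frame(
      serial = a$eleno, name = a$elety, resname = a$resid,
      chain = a$chain, resno = a$resno,
      x = a$x, y = a$y, z = a$z,
      element = ifelse(is.na(a$elesy) | a$elesy == "",
                       substr(trimws(a$elety), 1L, 1L), a$elesy),
      stringsAsFactors = FALSE))
  })
  out[order(names(out))]
}

#' Write pilin structures to a PDB file
#'
#' @param structures A single `pilin` or a list of them (e.g. the
#'   subunits of an assembly); chains are written in list order.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "pilin")) structures <- list(structures)
  if (inherits(structures, "pilus_assembly")) structures <- structures$subunits
  atoms <- do.call(rbind, lapply(structures, function(s) s$atoms))
  if (any(nchar(atoms$chain) > 1L))
    stop("PDB fixed-column format holds single-character chain ids; ",
         "found: ", paste(unique(atoms$chain[nchar(atoms$chain) > 1L]),
                          collapse = ", "))
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = seq_len(nrow(atoms)), elety = atoms$name,
                   chain = atoms$chain, elesy = atoms$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Aromatic rings

#' Build an aromatic ring object from six ring-carbon positions
#'
#' The ring of both Phe and Tyr is taken as the six-carbon carbocycle
#' CG, CD1, CD2, CE1, CE2, CZ (the Tyr hydroxyl oxygen is excluded).
#' The centroid is the arithmetic mean of the six carbons; the normal is
#' the unit eigenvector of the smallest principal component of the
#' centered ring atoms, with its sign chosen to point into the +z
#' half-space (ties resolved toward +z).
#'
#' @param coords 6 x 3 matrix of ring-carbon positions, rows named by
#'   ring atom.
#' @param chain Chain id.
#' @param resno Residue number (mature numbering).
#' @param type `"F"` or `"Y"`.
#' @param subunit Optional integer subunit index within an assembly.
#' @return An object of class `aromatic_ring` with `centroid` and unit
#'   `normal`.
#' @export
aromatic_ring <- function(coords, chain = "A", resno = 1L, type = "F",
                          subunit = NA_integer_) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 6L || ncol(coords) != 3L)
    stop("an aromatic ring has exactly six ring carbons")
  if (!all(is.finite(coords))) stop("non-finite ring coordinates")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2L, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3L]
  if (normal[3L] < 0 || (normal[3L] == 0 && (normal[1L] < 0 ||
      (normal[1L] == 0 && normal[2L] < 0))))
    normal <- -normal
  normal <- normal / sqrt(sum(normal^2))
  structure(list(chain = chain, resno = as.integer(resno), type = type,
                 subunit = subunit, coords = coords,
                 centroid = centroid, normal = normal),
            class = "aromatic_ring")
}

#' Extract the aromatic rings of a pilin structure
#'
#' Finds every PHE/TYR residue and returns its six-carbon ring.
#'
#' @param structure A `pilin` object.
#' @param subunit Optional subunit index stamped on each ring.
#' @return List of [aromatic_ring()] objects in residue order.
#' @export
extract_aromatic_rings <- function(structure, subunit = NA_integer_) {
  a <- structure$atoms
  arom <- a[a$resname %in% names(AROMATIC_RESIDUES), , drop = FALSE]
  rings <- list()
  for (rn in unique(arom$resno)) {
    res <- arom[arom$resno == rn, , drop = FALSE]
    missing_at <- setdiff(RING_ATOMS, res$name)
    if (length(missing_at) > 0L)
      stop(sprintf(
        "incomplete aromatic ring: chain %s residue %s (%d) missing %s",
        structure$chain, res$resname[1L], rn,
        paste(missing_at, collapse = ", ")))
    res <- res[match(RING_ATOMS, res$name), , drop = FALSE]
    coords <- as.matrix(res[, c("x", "y", "z")])
    rownames(coords) <- RING_ATOMS
    rings[[length(rings) + 1L]] <- aromatic_ring(
      coords, chain = structure$chain, resno = rn,
      type = unname(AROMATIC_RESIDUES[res$resname[1L]]), subunit = subunit)
  }
  rings
}

# ---------------------------------------------------------------------------
# Superposition

#' Kabsch least-squares superposition and RMSD
#'
#' Finds the proper rotation (determinant +1) and translation that
#' superpose `coords_b` onto `coords_a` with minimal root-mean-square
#' deviation, using the singular value decomposition of the covariance
#' of the centered point sets.
#'
#' @param coords_a,coords_b n x 3 matrices of corresponding points,
#'   n >= 3.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3, det +1) and
#'   `translation` (length 3): the superposed B is
#'   `coords_b %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B)) stop("point sets must have equal length")
  if (nrow(A) < 3L) stop("superposition needs at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(B0, A0)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A0)^2)))
  list(rmsd = rmsd, rotation = R,
       translation = ca - as.vector(R %*% cb))
}

#' Superposition RMSD between two point sets
#'
#' @inheritParams kabsch_superpose
#' @return The least-squares RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  kabsch_superpose(coords_a, coords_b)$rmsd
}

# ---------------------------------------------------------------------------
# Hydropathy

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Sliding-window hydropathy profile of a protein sequence
#'
#' Computes the mean per-residue hydropathy in a centered sliding
#' window; positions without a full window are omitted. The default
#' scale is Kyte-Doolittle; any named per-letter scale may be supplied.
#'
#' @param sequence One-letter amino-acid string.
#' @param window Odd window width, `<= nchar(sequence)`.
#' @param scale Named numeric vector of per-letter hydropathy values.
#' @return Data frame with `position` (center residue index, 1-based)
#'   and `score`.
#' @export
hydropathy_profile <- function(sequence, window = 9L,
                               scale = KYTE_DOOLITTLE) {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window > n) stop("window exceeds sequence length")
  unknown <- which(!letters1 %in% names(scale))
  if (length(unknown) > 0L)
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 letters1[unknown[1L]], unknown[1L]))
  vals <- scale[letters1]
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half + 1L, n - half)
  scores <- vapply(centers, function(i)
    mean(vals[(i - half):(i + half)]), numeric(1L))
  data.frame(position = centers, score = unname(scores))
}
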