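# Independent brute-force oracles used against the package
# implementations. These deliberately take the slow, enumerative route.

# Best superposition RMSD by coarse Euler-angle grid search followed by
# Nelder-Mead polish; independent of the SVD route.
oracle_superpose_rmsd <- function(A, B) {
  A0 <- sweep(A, 2L, colMeans(A))
  B0 <- sweep(B, 2L, colMeans(B))
  euler_rot <- function(p) {
    ca <- cos(p[1L]); sa <- sin(p[1L])
    cb <- cos(p[2L]); sb <- sin(p[2L])
    cg <- cos(p[3L]); sg <- sin(p[3L])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3L, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3L, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3L, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((B0 %*% t(euler_rot(p)) - A0)^2)))
  grid <- seq(0, 2 * pi - 1e-9, length.out = 13L)
  best <- NULL; best_val <- Inf
  for (a in grid) for (b in grid[grid <= pi]) for (g in grid) {
    v <- obj(c(a, b, g))
    if (v < best_val) { best_val <- v; best <- c(a, b, g) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  opt$value
}

# All simple paths between two nodes of a weighted undirected graph
# given as an adjacency weight matrix (NA = no edge); returns the
# minimum total weight (Inf if unreachable).
oracle_shortest_path_length <- function(W, from, to) {
  n <- nrow(W)
  best <- Inf
  visit <- function(node, used, acc) {
    if (acc >= best) return(invisible(NULL))
    if (node == to) { best <<- acc; return(invisible(NULL)) }
    for (nxt in seq_len(n)) {
      if (!used[nxt] && !is.na(W[node, nxt]))
        visit(nxt, `[<-`(used, nxt, TRUE), acc + W[node, nxt])
    }
  }
  visit(from, `[<-`(rep(FALSE, n), from, TRUE), 0)
  best
}

# Optimal 1-D k-means WCSS by exhausting contiguous partitions of the
# sorted values (the optimal 1-D partition is contiguous in sort
# order).
oracle_kmeans_wcss <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  splits <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0L, splits[, j], n)
    wcss <- 0
    for (b in seq_len(k)) {
      seg <- xs[(bounds[b] + 1L):bounds[b + 1L]]
      wcss <- wcss + sum((seg - mean(seg))^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

# Build a pilus_assembly in which each supplied centroid becomes a
# lone PHE ring in its own subunit; used to exercise graph/path code on
# arbitrary geometries.
assembly_from_centroids <- function(centroids) {
  subunits <- lapply(seq_len(nrow(centroids)), function(i) {
    ring <- make_ring(centroids[i, ], normal = c(0, 0, 1), type = "F",
                      chain = piliconduct:::chain_id_seq(i)[i], resno = 1L)
    atoms <- piliconduct:::ring_atom_rows(
      ring, piliconduct:::chain_id_seq(i)[i], 1L, "PHE", 1L)
    pilin_structure(atoms)
  })
  structure(list(params = helical_params(1, 90, length(subunits)),
                 subunits = subunits),
            class = "pilus_assembly")
}

# Write a minimal valid PDB ATOM line set for a list of atom rows.
write_toy_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$serial, a$name, a$resname, a$chain, a$resno,
            a$x, a$y, a$z, a$element)
  }, character(1L))
  writeLines(c(lines, "END"), path)
  path
}

# A complete PHE residue's atom table (ring planted via make_ring).
toy_phe_atoms <- function(center = c(0, 0, 0), resno = 1L, chain = "A") {
  ring <- make_ring(center, c(0, 0, 1), "F", chain = chain, resno = resno)
  piliconduct:::ring_atom_rows(ring, chain, resno, "PHE", 1L)
}
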