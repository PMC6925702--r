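# Aromatic pathway analysis: ring graph, interaromatic / proximal C-C
# distances, Dijkstra shortest path and the smallest symmetric unit.

#' Interaromatic distance between two rings
#'
#' Euclidean distance between the ring centroids.
#'
#' @param ring_a,ring_b [aromatic_ring()] objects.
#' @return Distance in Angstrom.
#' @export
interaromatic_distance <- function(ring_a, ring_b) {
  sqrt(sum((ring_a$centroid - ring_b$centroid)^2))
}

#' Proximal carbon-carbon distance between two rings
#'
#' Minimum over all 36 ring-carbon pairs of the Euclidean distance.
#'
#' @param ring_a,ring_b [aromatic_ring()] objects.
#' @return Distance in Angstrom.
#' @export
proximal_cc_distance <- function(ring_a, ring_b) {
  A <- ring_a$coords; B <- ring_b$coords
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# All rings of an assembly, stamped with 1-based subunit indices.
assembly_rings <- function(assembly) {
  rings <- list()
  for (i in seq_along(assembly$subunits)) {
    rs <- extract_aromatic_rings(assembly$subunits[[i]], subunit = i)
    rings <- c(rings, rs)
  }
  rings
}

ring_id <- function(ring) sprintf("s%d:r%d", ring$subunit, ring$resno)

#' Build the aromatic-ring graph of an assembly
#'
#' Nodes are the aromatic rings of every subunit; an undirected edge
#' joins each ring pair whose interaromatic (centroid) distance is at
#' most `cutoff`, weighted by that distance. The default 7 Angstrom
#' cutoff covers the largest pathway step observed in the pilus models
#' (6.1 A) while excluding the >= 8.7 A intra-subunit pairs of the
#' isolated pilin.
#'
#' @param assembly A `pilus_assembly` containing aromatic residues.
#' @param cutoff Edge distance cutoff in Angstrom, or `NULL` for a
#'   complete graph.
#' @return List of class `aromatic_graph` with `graph` (igraph),
#'   `rings` (named by node id) and `cutoff`.
#' @export
build_ring_graph <- function(assembly, cutoff = 7) {
  rings <- assembly_rings(assembly)
  if (length(rings) == 0L) stop("assembly contains no aromatic residues")
  ids <- vapply(rings, ring_id, character(1L))
  names(rings) <- ids
  n <- length(rings)
  from <- character(0); to <- character(0); w <- numeric(0)
  if (n > 1L) {
    cents <- t(vapply(rings, `[[`, numeric(3L), "centroid"))
    dmat <- as.matrix(stats::dist(cents))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      dij <- dmat[i, j]
      if (is.null(cutoff) || dij <= cutoff) {
        from <- c(from, ids[i]); to <- c(to, ids[j]); w <- c(w, dij)
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (length(from) > 0L)
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  structure(list(graph = g, rings = rings, cutoff = cutoff),
            class = "aromatic_graph")
}

# (subunit, resno) key matrix for a vector of node ids, for lexicographic
# tie-breaking.
path_key <- function(ids) {
  m <- do.call(rbind, lapply(strsplit(sub("^s", "", ids), ":r"), as.integer))
  as.vector(t(m))
}

#' Shortest electron-transfer path between two rings
#'
#' Dijkstra shortest path on the aromatic-ring graph, with edge weights
#' equal to interaromatic distances. Among equal-length shortest paths
#' the one whose (subunit, residue) sequence is lexicographically
#' smallest is returned, so the result is deterministic.
#'
#' @param ring_graph An `aromatic_graph` from [build_ring_graph()].
#' @param from,to Node ids (`"s<subunit>:r<resno>"`).
#' @return List with `found` (logical), `path` (node id vector),
#'   `subunits`, `resnos`, and `length` (total Angstrom; `Inf` when
#'   disconnected).
#' @export
shortest_ring_path <- function(ring_graph, from, to) {
  g <- ring_graph$graph
  if (!from %in% igraph::V(g)$name) stop("unknown source ring: ", from)
  if (!to %in% igraph::V(g)$name) stop("unknown target ring: ", to)
  if (from == to)
    return(list(found = TRUE, path = from,
                subunits = ring_graph$rings[[from]]$subunit,
                resnos = ring_graph$rings[[from]]$resno, length = 0))
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to,
                               weights = igraph::E(g)$weight))
  if (length(res$vpaths) == 0L)
    return(list(found = FALSE, path = character(0),
                subunits = integer(0), resnos = integer(0), length = Inf))
  paths <- lapply(res$vpaths, function(v) igraph::V(g)$name[as.integer(v)])
  if (length(paths) > 1L) {
    keys <- lapply(paths, path_key)
    best <- 1L
    for (i in seq_along(paths)[-1L]) {
      a <- keys[[i]]; b <- keys[[best]]
      len <- min(length(a), length(b))
      cmp <- 0L
      for (k in seq_len(len)) {
        if (a[k] != b[k]) { cmp <- sign(a[k] - b[k]); break }
      }
      if (cmp < 0L || (cmp == 0L && length(a) < length(b))) best <- i
    }
    chosen <- paths[[best]]
  } else chosen <- paths[[1L]]
  total <- as.numeric(igraph::distances(g, v = from, to = to,
                                        weights = igraph::E(g)$weight))
  list(found = TRUE, path = chosen,
       subunits = vapply(ring_graph$rings[chosen], `[[`, integer(1L),
                         "subunit"),
       resnos = vapply(ring_graph$rings[chosen], `[[`, integer(1L),
                       "resno"),
       length = total)
}

#' Extract the smallest symmetric pathway unit
#'
#' The segment of a transfer path running from F1 of subunit `p - 1` to
#' F1 of subunit `p`: under helical symmetry this unit repeats along the
#' pilus, and in the pilus models it consists of four rings
#' (F1, F24, Y27, F1'). Its three consecutive interaromatic distances
#' are reported as d1 (F1, F24), d2 (F24, Y27) and d3 (Y27, F1').
#' `p` defaults to 7, the first subunit of the second helical turn.
#'
#' If the segment does not contain exactly four rings a structural
#' warning reports the actual membership and the object carries the
#' consecutive distances that do exist.
#'
#' @param ring_graph An `aromatic_graph`.
#' @param path Result of [shortest_ring_path()] visiting F1 of subunits
#'   `p - 1` and `p`.
#' @param subunit_p Index of the closing subunit (default 7).
#' @return Object of class `symmetric_unit` with `rings`, `resnos`,
#'   `subunits`, `distances` (consecutive interaromatic distances) and,
#'   for the canonical 4-ring unit, `d1`, `d2`, `d3`.
#' @export
extract_symmetric_unit <- function(ring_graph, path, subunit_p = 7L) {
  ids <- path$path
  start <- which(path$subunits == subunit_p - 1L & path$resnos == 1L)
  end <- which(path$subunits == subunit_p & path$resnos == 1L)
  if (length(start) == 0L || length(end) == 0L)
    stop(sprintf("path does not visit F1 of subunits %d and %d",
                 subunit_p - 1L, subunit_p))
  seg <- ids[start[1L]:end[1L]]
  dists <- vapply(seq_len(length(seg) - 1L), function(k)
    interaromatic_distance(ring_graph$rings[[seg[k]]],
                           ring_graph$rings[[seg[k + 1L]]]),
    numeric(1L))
  unit <- structure(list(
    rings = seg,
    subunits = vapply(ring_graph$rings[seg], `[[`, integer(1L), "subunit"),
    resnos = vapply(ring_graph$rings[seg], `[[`, integer(1L), "resno"),
    distances = dists,
    d1 = NA_real_, d2 = NA_real_, d3 = NA_real_),
    class = "symmetric_unit")
  if (length(seg) == 4L) {
    unit$d1 <- dists[1L]; unit$d2 <- dists[2L]; unit$d3 <- dists[3L]
  } else {
    warning(sprintf(
      "symmetric unit has %d rings, expected 4; members: %s",
      length(seg), paste(seg, collapse = " -> ")))
  }
  unit
}

#' @export
print.symmetric_unit <- function(x, ...) {
  cat("<symmetric_unit>", paste(x$rings, collapse = " -> "), "\n")
  cat(sprintf("  distances: %s A\n",
              paste(sprintf("%.3f", x$distances), collapse = ", ")))
  invisible(x)
}

#' Bottleneck distance of a symmetric unit
#'
#' The largest interaromatic step in the unit; this distance limits the
#' electron transfer rate along the pilus, so the associated (slowest)
#' rate governs the transport chain.
#'
#' @param unit A `symmetric_unit`.
#' @return Maximum consecutive interaromatic distance, Angstrom.
#' @export
bottleneck_distance <- function(unit) {
  max(unit$distances)
}

#' Write a pathway report
#'
#' Emits a TSV table of the path (ring id, subunit, residue, cumulative
#' length) and a JSON block with d1-d3 and the bottleneck.
#'
#' @param ring_graph An `aromatic_graph`.
#' @param path Result of [shortest_ring_path()].
#' @param unit A `symmetric_unit` (optional).
#' @param tsv_path,json_path Output file paths (either may be `NULL`).
#' @return Invisibly, the report list.
#' @export
write_pathway_report <- function(ring_graph, path, unit = NULL,
                                 tsv_path = NULL, json_path = NULL) {
  steps <- c(0, vapply(seq_len(length(path$path) - 1L), function(k)
    interaromatic_distance(ring_graph$rings[[path$path[k]]],
                           ring_graph$rings[[path$path[k + 1L]]]),
    numeric(1L)))
  tab <- data.frame(ring = path$path, subunit = path$subunits,
                    residue = path$resnos,
                    cumulative_A = cumsum(steps))
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  rep <- list(path = tab)
  if (!is.null(unit)) {
    rep$unit <- list(rings = unit$rings, d1_A = unit$d1, d2_A = unit$d2,
                     d3_A = unit$d3,
                     bottleneck_A = bottleneck_distance(unit))
  }
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(rep)
}
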