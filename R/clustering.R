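# Clustering of candidate models: k-means and DBSCAN on rotation
# angles, greedy leader clustering on structural similarity (RMSD).

# Run an expression under a local, restorable RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' k-means clustering of rotation angles
#'
#' Lloyd's algorithm on 1-D angle values (treated as plain scalars; the
#' observed angle ranges never straddle the 0/360 wrap), best of
#' `restarts` seeded random initializations by within-cluster sum of
#' squares. Deterministic given `seed`; cluster labels are renumbered
#' by ascending center.
#'
#' @param angles Numeric vector of rotation angles, degrees.
#' @param k Number of clusters, `<=` number of distinct values.
#' @param seed RNG seed for the restarts (default 1234).
#' @param restarts Number of random initializations (default 25).
#' @return List with `labels` (integer vector), `centers` (ascending)
#'   and `wcss` (total within-cluster sum of squares).
#' @export
kmeans_angles <- function(angles, k, seed = 1234L, restarts = 25L) {
  if (length(angles) == 0L) stop("empty angle vector")
  if (k <= 0L) stop("k must be positive")
  if (k > length(unique(angles)))
    stop("k exceeds the number of distinct angle values")
  fit <- with_local_seed(seed,
    stats::kmeans(matrix(angles, ncol = 1L), centers = k,
                  nstart = restarts, iter.max = 100L,
                  algorithm = "Lloyd"))
  ord <- order(fit$centers[, 1L])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(labels = relabel[fit$cluster],
       centers = sort(fit$centers[, 1L]),
       wcss = fit$tot.withinss)
}

#' DBSCAN clustering of rotation angles
#'
#' Density-based clustering on the 1-D Euclidean metric. A core point
#' has at least `min_pts` neighbors within `epsilon` (itself included);
#' clusters grow from core points in ascending index order, so labels
#' are deterministic. Non-core, non-reachable points are noise
#' (label -1). The defaults follow the model-ensemble analysis
#' (epsilon = 3, minPts = 10).
#'
#' @param angles Numeric vector of rotation angles, degrees.
#' @param epsilon Neighborhood radius (> 0), default 3.
#' @param min_pts Minimum neighborhood size for a core point, default 10.
#' @return Integer label vector: 1, 2, ... for clusters, -1 for noise.
#' @export
dbscan_angles <- function(angles, epsilon = 3, min_pts = 10L) {
  n <- length(angles)
  if (n == 0L) stop("empty angle vector")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (min_pts < 1L) stop("min_pts must be >= 1")
  neighbors <- lapply(seq_len(n), function(i)
    which(abs(angles - angles[i]) <= epsilon))
  core <- vapply(neighbors, length, integer(1L)) >= min_pts
  labels <- rep(0L, n)  # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neighbors[[i]]
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cl          # border, reclaimed
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- c(queue, neighbors[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Greedy leader clustering of models by pairwise RMSD
#'
#' Iterates models by ascending energy; a model joins the first
#' existing cluster whose leader lies within `cutoff` RMSD (Kabsch
#' superposition), otherwise it founds a new cluster. Clusters are
#' returned sorted by member count, descending (ties broken by leader
#' energy rank). The default cutoff of 1.75 Angstrom matches the
#' structural-similarity clustering used to pick the converged basin of
#' full-atom models.
#'
#' @param coords List of n x 3 coordinate matrices, one per model, all
#'   with the same atom count.
#' @param energies Numeric vector of energy scores (lower = better);
#'   defaults to input order.
#' @param cutoff RMSD cutoff in Angstrom (default 1.75). `Inf` gives a
#'   single cluster.
#' @return List with `clusters` (list of integer index vectors, leader
#'   first) and `labels` (cluster id per model, in input order).
#' @export
leader_cluster_rmsd <- function(coords, energies = NULL, cutoff = 1.75) {
  m <- length(coords)
  if (m == 0L) stop("no models")
  counts <- vapply(coords, nrow, integer(1L))
  if (length(unique(counts)) != 1L) stop("model atom counts differ")
  if (is.null(energies)) energies <- seq_len(m)
  ord <- order(energies)
  leaders <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (kabsch_rmsd(coords[[leaders[ci]]], coords[[i]]) <= cutoff) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      members[[length(leaders)]] <- i
    }
  }
  size_ord <- order(-vapply(members, length, integer(1L)),
                    seq_along(members))
  members <- members[size_ord]
  labels <- integer(m)
  for (ci in seq_along(members)) labels[members[[ci]]] <- ci
  list(clusters = members, labels = labels)
}

#' Write / read a model table
#'
#' Model ensembles are exchanged as TSV with columns `id`,
#' `rotation_angle`, `energy_score` and optionally `pdb_path`.
#'
#' @param models Data frame with those columns.
#' @param path TSV path.
#' @return `path` invisibly (write); data frame (read).
#' @export
write_model_table <- function(models, path) {
  utils::write.table(models, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_model_table
#' @export
read_model_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
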