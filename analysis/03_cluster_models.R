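#!/usr/bin/env Rscript
# Cluster a synthetic docking-model ensemble: k-means and DBSCAN on
# rotation angles (three planted basins), then RMSD leader clustering
# of perturbed assemblies at the 1.75 A cutoff.

suppressMessages(library(piliconduct))
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = 1234L)
ens <- make_angle_ensemble(spec)

km <- kmeans_angles(ens$rotation_angle, k = 3L, seed = 1234L)
db <- dbscan_angles(ens$rotation_angle, epsilon = 3, min_pts = 10L)
ens$kmeans <- km$labels
ens$dbscan <- db
write_model_table(ens, "results/angle_clusters.tsv")
cat(sprintf("k-means centers: %s deg; DBSCAN found %d clusters, %d noise\n",
            paste(sprintf("%.1f", km$centers), collapse = ", "),
            length(setdiff(unique(db), -1L)), sum(db == -1L)))

# leader clustering: replicas of two distinct assemblies
ref1 <- make_pathway_pilus(synthetic_spec())
ref2 <- make_pathway_pilus(synthetic_spec(d1 = 5.2, d2 = 5.9, d3 = 3.9,
                                          rotation = 150))
perturb <- function(asm, seed) {
  xyz <- do.call(rbind, lapply(asm$subunits[1:3], pilin_coords))
  set.seed(seed)
  xyz + matrix(rnorm(length(xyz), sd = 0.2), ncol = 3L)
}
coords <- c(lapply(1:6, function(s) perturb(ref1, s)),
            lapply(7:10, function(s) perturb(ref2, s)))
cl <- leader_cluster_rmsd(coords, cutoff = 1.75)
sizes <- vapply(cl$clusters, length, integer(1L))
cat(sprintf("leader clustering: %d clusters with sizes %s\n",
            length(cl$clusters), paste(sizes, collapse = ", ")))
write.table(data.frame(model = seq_along(cl$labels),
                       cluster = cl$labels),
            "results/rmsd_clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
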