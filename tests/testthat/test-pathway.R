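# Ring graph construction, distances, Dijkstra pathway and the
# smallest symmetric unit.

test_that("interaromatic distance is the centroid separation", {
  r1 <- make_ring(c(0, 0, 0))
  expect_equal(interaromatic_distance(r1, r1), 0)
  r2 <- make_ring(c(0, 0, 3.9))
  expect_equal(interaromatic_distance(r1, r2), 3.9, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    a <- make_ring(rnorm(3), normal = rnorm(3) + c(0, 0, 2))
    b <- make_ring(rnorm(3), normal = rnorm(3) + c(0, 0, 2))
    expect_equal(interaromatic_distance(a, b),
                 sqrt(sum((a$centroid - b$centroid)^2)),
                 tolerance = 1e-12)
  }
})

test_that("proximal C-C distance is the exhaustive 36-pair minimum", {
  # eclipsed coaxial hexagons: plane separation is the minimum
  r1 <- make_ring(c(0, 0, 0))
  r2 <- make_ring(c(0, 0, 3.5))
  expect_equal(proximal_cc_distance(r1, r2), 3.5, tolerance = 1e-12)
  # staggered by 30 degrees: check against an explicit pair scan
  r3 <- make_ring(c(0, 0, 3.5), in_plane_rotation = 30)
  brute <- min(apply(r1$coords, 1L, function(p)
    apply(r3$coords, 1L, function(q) sqrt(sum((p - q)^2)))))
  expect_equal(proximal_cc_distance(r1, r3), brute, tolerance = 1e-12)
  # rings sharing an atom position touch at zero
  r4 <- make_ring(c(2 * 1.39, 0, 0), in_plane_rotation = 180)
  expect_equal(proximal_cc_distance(r1, r4), 0, tolerance = 1e-9)
})

test_that("proximal C-C distance brackets the centroid distance", {
  set.seed(22)
  for (i in 1:20) {
    a <- make_ring(rnorm(3, sd = 2), normal = rnorm(3) + c(0, 0, 2),
                   in_plane_rotation = runif(1, 0, 60))
    b <- make_ring(rnorm(3, sd = 2), normal = rnorm(3) + c(0, 0, 2),
                   in_plane_rotation = runif(1, 0, 60))
    d <- interaromatic_distance(a, b)
    pcc <- proximal_cc_distance(a, b)
    expect_lte(pcc, d + 2 * 1.39 + 1e-9)
    expect_gte(pcc, d - 2 * 1.39 - 1e-9)
  }
})

test_that("graph edges equal the exhaustive pair scan at the cutoff", {
  asm <- make_pathway_pilus(synthetic_spec())
  g <- build_ring_graph(asm, cutoff = 7)
  rings <- piliconduct:::assembly_rings(asm)
  ids <- vapply(rings, piliconduct:::ring_id, character(1L))
  expected <- 0L
  for (i in seq_along(rings)) for (j in seq_along(rings)) {
    if (j <= i) next
    if (interaromatic_distance(rings[[i]], rings[[j]]) <= 7)
      expected <- expected + 1L
  }
  expect_equal(igraph::ecount(g$graph), expected)
  expect_equal(igraph::vcount(g$graph), length(rings))
  # a zero cutoff keeps the nodes but no edges
  g0 <- build_ring_graph(asm, cutoff = 0)
  expect_equal(igraph::ecount(g0$graph), 0L)
  # two rings, one pair
  g2 <- build_ring_graph(assembly_from_centroids(
    rbind(c(0, 0, 0), c(0, 0, 4))), cutoff = NULL)
  expect_equal(igraph::ecount(g2$graph), 1L)
  expect_equal(igraph::E(g2$graph)$weight, 4, tolerance = 1e-12)
})

test_that("an assembly without aromatics is rejected", {
  pil <- pilin_structure(data.frame(
    serial = 1L, name = "CA", resname = "ALA", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, element = "C"))
  asm <- apply_helical_symmetry(pil, helical_params(10, 90, 3L))
  expect_error(build_ring_graph(asm), "no aromatic")
})

test_that("dijkstra prefers the two-edge route when the direct edge is cut", {
  # bent three-ring chain: with the long pair excluded by the cutoff
  # the only route is via the middle ring; with a complete graph the
  # direct edge wins
  asm <- assembly_from_centroids(rbind(c(0, 0, 0), c(0.95, 0.4, 0),
                                       c(1.9, 0, 0)))
  cutg <- build_ring_graph(asm, cutoff = 1.5)
  p <- shortest_ring_path(cutg, "s1:r1", "s3:r1")
  expect_equal(p$path, c("s1:r1", "s2:r1", "s3:r1"))
  expect_equal(p$length, 2 * sqrt(0.95^2 + 0.4^2), tolerance = 1e-9)
  fullg <- build_ring_graph(asm, cutoff = NULL)
  expect_equal(shortest_ring_path(fullg, "s1:r1", "s3:r1")$length, 1.9,
               tolerance = 1e-9)
})

test_that("dijkstra equals exhaustive simple-path enumeration", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(4:8, 1L)
    centroids <- matrix(runif(3L * n, 0, 10), ncol = 3L)
    asm <- assembly_from_centroids(centroids)
    dmat <- as.matrix(stats::dist(centroids))
    cutoff <- stats::quantile(dmat[upper.tri(dmat)], 0.6)
    g <- build_ring_graph(asm, cutoff = cutoff)
    W <- dmat
    W[W > cutoff] <- NA
    diag(W) <- NA
    from <- 1L; to <- n
    expected <- oracle_shortest_path_length(W, from, to)
    got <- shortest_ring_path(g, sprintf("s%d:r1", from),
                              sprintf("s%d:r1", to))
    if (is.infinite(expected)) {
      expect_false(got$found)
    } else {
      expect_equal(got$length, expected, tolerance = 1e-9)
    }
  }
})

test_that("source equal to target gives the trivial path", {
  asm <- assembly_from_centroids(rbind(c(0, 0, 0), c(0, 0, 4)))
  g <- build_ring_graph(asm, NULL)
  p <- shortest_ring_path(g, "s1:r1", "s1:r1")
  expect_true(p$found)
  expect_equal(p$path, "s1:r1")
  expect_equal(p$length, 0)
})

test_that("removing an off-path edge leaves the shortest path unchanged", {
  set.seed(24)
  centroids <- matrix(runif(24, 0, 8), ncol = 3L)
  asm <- assembly_from_centroids(centroids)
  g <- build_ring_graph(asm, cutoff = NULL)
  p <- shortest_ring_path(g, "s1:r1", "s8:r1")
  on_path <- p$path
  es <- igraph::as_edgelist(g$graph)
  off <- which(!(es[, 1L] %in% on_path & es[, 2L] %in% on_path))
  if (length(off) > 0L) {
    g2 <- g
    g2$graph <- igraph::delete_edges(g$graph, off[1L])
    p2 <- shortest_ring_path(g2, "s1:r1", "s8:r1")
    expect_equal(p2$length, p$length, tolerance = 1e-12)
    expect_equal(p2$path, p$path)
  }
})

test_that("planted pathway distances are recovered through the graph", {
  cases <- list(list(d = c(3.9, 6.1, 5.1), bn = 6.1),
                list(d = c(5.2, 5.9, 3.9), bn = 5.9),
                list(d = c(5, 5, 5), bn = 5))
  for (cs in cases) {
    spec <- synthetic_spec(d1 = cs$d[1L], d2 = cs$d[2L], d3 = cs$d[3L])
    asm <- make_pathway_pilus(spec)
    g <- build_ring_graph(asm, cutoff = 7)
    p <- shortest_ring_path(g, "s1:r1",
                            sprintf("s%d:r1", spec$n_subunits))
    expect_true(p$found)
    expect_equal(sort(unique(p$resnos)), c(1L, 24L, 27L))
    u <- extract_symmetric_unit(g, p, subunit_p = 7L)
    expect_length(u$rings, 4L)
    expect_equal(c(u$d1, u$d2, u$d3), cs$d, tolerance = 1e-6)
    expect_equal(bottleneck_distance(u), cs$bn, tolerance = 1e-6)
  }
})

test_that("pathway distances repeat with the helical period", {
  spec <- synthetic_spec()
  asm <- make_pathway_pilus(spec)
  g <- build_ring_graph(asm, cutoff = 7)
  p <- shortest_ring_path(g, "s1:r1", sprintf("s%d:r1", spec$n_subunits))
  dvals <- lapply(3:8, function(pp)
    unlist(extract_symmetric_unit(g, p, subunit_p = pp)$distances))
  for (i in 2:length(dvals))
    expect_equal(dvals[[i]], dvals[[1L]], tolerance = 1e-6)
})

test_that("a degenerate unit warns and reports its membership", {
  asm <- assembly_from_centroids(rbind(c(0, 0, 0), c(0, 0, 5)))
  # relabel so both rings look like F1 of consecutive subunits
  g <- build_ring_graph(asm, cutoff = NULL)
  p <- shortest_ring_path(g, "s1:r1", "s2:r1")
  expect_warning(u <- extract_symmetric_unit(g, p, subunit_p = 2L),
                 "expected 4")
  expect_length(u$rings, 2L)
  expect_equal(u$distances, 5, tolerance = 1e-12)
  expect_true(is.na(u$d1))
})

test_that("bottleneck picks the largest unit distance", {
  u1 <- structure(list(distances = c(3.9, 6.1, 5.1)),
                  class = "symmetric_unit")
  expect_equal(bottleneck_distance(u1), 6.1)
  u2 <- structure(list(distances = c(5.2, 5.9, 3.9)),
                  class = "symmetric_unit")
  expect_equal(bottleneck_distance(u2), 5.9)
  u3 <- structure(list(distances = c(4, 4, 4)),
                  class = "symmetric_unit")
  expect_equal(bottleneck_distance(u3), 4)
})

test_that("pathway reports serialize to TSV and JSON", {
  spec <- synthetic_spec()
  asm <- make_pathway_pilus(spec)
  g <- build_ring_graph(asm, cutoff = 7)
  p <- shortest_ring_path(g, "s1:r1", sprintf("s%d:r1", spec$n_subunits))
  u <- extract_symmetric_unit(g, p, 7L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_pathway_report(g, p, u, tsv, js)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(p$path))
  expect_equal(tab$cumulative_A[nrow(tab)], p$length, tolerance = 1e-6)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$unit$bottleneck_A, bottleneck_distance(u),
               tolerance = 1e-9)
})
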