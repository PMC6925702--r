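# Flat-harmonic restraints, ambiguous min-over-pairs scoring and the
# restraint file round-trip.

test_that("flat harmonic matches its closed form at the stated defaults", {
  # low-resolution defaults x0 = 10, sd = 0.5, tolerance = 5
  expect_equal(flat_harmonic(12, 10, 0.5, 5), 0)
  expect_equal(flat_harmonic(16, 10, 0.5, 5), 4.0)
  expect_equal(flat_harmonic(15, 10, 0.5, 5), 0)   # upper band edge
  expect_equal(flat_harmonic(5, 10, 0.5, 5), 0)    # lower band edge
  expect_error(flat_harmonic(5, 10, 0, 5), "sd")
})

test_that("flat harmonic is continuous, symmetric and monotone outside", {
  x0 <- 10; sd <- 0.5; tol <- 5
  eps <- 1e-8
  expect_lt(flat_harmonic(x0 + tol + eps, x0, sd, tol), 1e-10)
  expect_lt(flat_harmonic(x0 - tol - eps, x0, sd, tol), 1e-10)
  d <- seq(x0 + tol, x0 + tol + 10, by = 0.25)
  expect_true(all(diff(flat_harmonic(d, x0, sd, tol)) >= 0))
  d2 <- seq(x0 - tol, x0 - tol - 10, by = -0.25)
  expect_true(all(diff(flat_harmonic(d2, x0, sd, tol)) >= 0))
  expect_true(all(flat_harmonic(runif(50, 0, 40), x0, sd, tol) >= 0))
  # scaling sd by c scales the out-of-band penalty by 1/c^2
  expect_equal(flat_harmonic(20, x0, 2 * sd, tol),
               flat_harmonic(20, x0, sd, tol) / 4, tolerance = 1e-12)
})

two_ring_assembly <- function(gap = 12) {
  assembly_from_centroids(rbind(c(0, 0, 0), c(0, 0, gap)))
}

test_that("plain constraint penalties add and resolve real distances", {
  asm <- two_ring_assembly(gap = 12)
  # rings centered 12 A apart; CG atoms sit at centroid + 1.39 x
  c1 <- constraint_spec(atom_selector("A", 1, "CG"),
                        atom_selector("B", 1, "CG"),
                        x0 = 10, sd = 0.5, tolerance = 5)
  sc1 <- score_constraints(asm, list(c1))
  expect_equal(sc1$breakdown$distance, 12, tolerance = 1e-9)
  expect_equal(sc1$total, 0)
  c2 <- constraint_spec(atom_selector("A", 1, "CG"),
                        atom_selector("B", 1, "CG"),
                        x0 = 6, sd = 0.5, tolerance = 5)   # penalty 4
  c3 <- constraint_spec(atom_selector("A", 1, "CG"),
                        atom_selector("B", 1, "CG"),
                        x0 = 6.5, sd = 0.5, tolerance = 5) # penalty 1
  sc <- score_constraints(asm, list(c2, c3))
  expect_equal(sc$breakdown$penalty, c(4, 1), tolerance = 1e-9)
  expect_equal(sc$total, 5, tolerance = 1e-9)
})

test_that("ambiguous constraints score as the exhaustive candidate minimum", {
  asm <- two_ring_assembly(gap = 12)
  x0s <- c(2, 4, 6, 11, 30)
  cands <- lapply(x0s, function(x0)
    constraint_spec(atom_selector("A", 1, "CG"),
                    atom_selector("B", 1, "CG"),
                    x0 = x0, sd = 0.5, tolerance = 5))
  amb <- ambiguous_constraint(cands)
  sc <- score_constraints(asm, list(amb))
  each <- vapply(cands, function(cc)
    score_constraints(asm, list(cc))$total, numeric(1L))
  expect_equal(sc$total, min(each), tolerance = 1e-12)
  expect_equal(sc$total, 0)  # x0 = 11 candidate is in its flat region
  # adding a candidate never increases the score
  for (extra in c(0.5, 11.9, 40)) {
    bigger <- ambiguous_constraint(c(cands, list(
      constraint_spec(atom_selector("A", 1, "CG"),
                      atom_selector("B", 1, "CG"),
                      x0 = extra, sd = 0.5, tolerance = 5))))
    expect_lte(score_constraints(asm, list(bigger))$total, sc$total)
  }
})

test_that("unresolvable selectors are named in the error", {
  asm <- two_ring_assembly()
  bad <- constraint_spec(atom_selector("A", 1, "CG"),
                         atom_selector("Z", 9, "CA"))
  expect_error(score_constraints(asm, list(bad)), "Z:9:CA")
})

test_that("restraint files round-trip plain and ambiguous constraints", {
  cons <- list(
    constraint_spec(atom_selector("A", 5, "CA"),
                    atom_selector("B", 7, "CA"), 10, 0.5, 5),
    ambiguous_constraint(list(
      constraint_spec(atom_selector("K", 1, "N"),
                      atom_selector("L", 24, "O"), 4, 2, 0.5),
      constraint_spec(atom_selector("K", 2, "N"),
                      atom_selector("L", 25, "O"), 4, 2, 0.5))))
  path <- withr::local_tempfile(fileext = ".cst")
  write_constraints(cons, path)
  back <- read_constraints(path)
  expect_length(back, 2L)
  expect_s3_class(back[[1L]], "constraint_spec")
  expect_s3_class(back[[2L]], "ambiguous_constraint")
  expect_equal(back[[1L]]$x0, 10)
  expect_equal(back[[2L]]$candidates[[2L]]$sel_b$resno, 25L)
  expect_equal(back[[2L]]$candidates[[1L]]$tolerance, 0.5)
})

test_that("middle-upper ambiguous contacts link floor(n/2) to ten chains above", {
  asm <- make_pathway_pilus(synthetic_spec(n_subunits = 21L))
  cons <- middle_upper_contacts(asm, residues_mid = c(1L, 24L),
                                residues_other = c(1L, 24L),
                                atom = "CG")
  expect_length(cons, 10L)
  chains_b <- vapply(cons, function(con)
    con$candidates[[1L]]$sel_b$chain, character(1L))
  expect_equal(chains_b, LETTERS[12:21])  # chains above the middle (K)
  expect_length(cons[[1L]]$candidates, 4L)
  sc <- score_constraints(asm, cons)
  expect_equal(nrow(sc$breakdown), 10L)
  expect_true(all(sc$breakdown$type == "ambiguous"))
})
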