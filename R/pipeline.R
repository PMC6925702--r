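# End-to-end pipeline: structure -> assembly -> constraint scoring ->
# pathway -> transport, with per-stage reports.

#' Pipeline configuration
#'
#' Validated bundle of every stage's inputs. Unknown arguments are
#' rejected up front so misspelled settings never run half a pipeline.
#'
#' @param input_mode `"synthetic"` (planted-geometry assembly from
#'   `spec`) or `"pdb"` (subunit read from `pdb_path`, aligned and
#'   assembled with `helical`).
#' @param spec A [synthetic_spec()] (synthetic mode).
#' @param pdb_path Path to a subunit PDB file (pdb mode).
#' @param helical A [helical_params()] (pdb mode).
#' @param constraints_path Optional restraint file for
#'   [score_constraints()].
#' @param cutoff Pathway graph cutoff, Angstrom (> 0); default 7.
#' @param subunit_p Closing subunit of the symmetric unit; default 7.
#' @param transport Optional [transport_inputs()] object or path to a
#'   transport-input JSON file; `NULL` gives a geometry-only run.
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "pdb"),
                            spec = synthetic_spec(),
                            pdb_path = NULL, helical = NULL,
                            constraints_path = NULL,
                            cutoff = 7, subunit_p = 7L,
                            transport = NULL,
                            out_dir = tempfile("pilus_run_"),
                            seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("invalid cutoff: must be a positive distance in Angstrom")
  if (subunit_p < 2L) stop("subunit_p must be >= 2")
  if (input_mode == "pdb") {
    if (is.null(pdb_path)) stop("pdb mode needs pdb_path")
    if (is.null(helical)) stop("pdb mode needs helical parameters")
  }
  if (is.character(transport)) transport <- read_transport_inputs(transport)
  if (!is.null(transport) && !inherits(transport, "transport_inputs"))
    stop("transport must be transport_inputs, a JSON path, or NULL")
  spec$seed <- as.integer(seed)
  structure(list(input_mode = input_mode, spec = spec,
                 pdb_path = pdb_path, helical = helical,
                 constraints_path = constraints_path, cutoff = cutoff,
                 subunit_p = as.integer(subunit_p),
                 transport = transport, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes assembly construction, geometry measurement, optional
#' constraint scoring, aromatic-pathway extraction and (if transport
#' inputs are configured) the Marcus transport chain. Writes per-stage
#' TSV/JSON files plus a machine-readable `summary.json` under
#' `config$out_dir`; two runs with identical config and seed produce
#' identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `assembly`, `geometry`,
#'   `constraint_score`, `graph`, `path`, `unit`, `transport` and the
#'   written `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  assembly <- stage("assembly", {
    if (config$input_mode == "synthetic") {
      make_pathway_pilus(config$spec)
    } else {
      chains <- read_pdb(config$pdb_path)
      sub <- align_to_axis(chains[[1L]],
                           radius_to_com = config$helical$radius_to_com)
      apply_helical_symmetry(sub, config$helical)
    }
  })
  pdb_out <- file.path(config$out_dir, "assembly.pdb")
  write_pdb(assembly, pdb_out)
  files <- c(files, pdb_out)

  geometry <- stage("geometry", list(
    params = estimate_helical_params(assembly),
    diameter_A = measure_diameter(assembly)))

  constraint_score <- NULL
  if (!is.null(config$constraints_path)) {
    constraint_score <- stage("constraints", {
      cons <- read_constraints(config$constraints_path)
      sc <- score_constraints(assembly, cons)
      tsv <- file.path(config$out_dir, "constraints.tsv")
      utils::write.table(sc$breakdown, tsv, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <<- c(files, tsv)
      sc
    })
  }

  pathway <- stage("pathway", {
    graph <- build_ring_graph(assembly, cutoff = config$cutoff)
    n_sub <- length(assembly$subunits)
    path <- shortest_ring_path(graph, from = "s1:r1",
                               to = sprintf("s%d:r1", n_sub))
    if (!path$found)
      stop("no transfer path between the terminal F1 rings; ",
           "consider raising the cutoff")
    # the symmetric unit is the geodesic between F1 of consecutive
    # subunits around the chosen turn
    unit_path <- shortest_ring_path(
      graph, from = sprintf("s%d:r1", config$subunit_p - 1L),
      to = sprintf("s%d:r1", config$subunit_p))
    if (!unit_path$found)
      stop("no transfer path across the symmetric unit; ",
           "consider raising the cutoff")
    unit <- extract_symmetric_unit(graph, unit_path, config$subunit_p)
    rep_files <- c(file.path(config$out_dir, "pathway.tsv"),
                   file.path(config$out_dir, "pathway.json"))
    write_pathway_report(graph, path, unit, rep_files[1L], rep_files[2L])
    files <<- c(files, rep_files)
    list(graph = graph, path = path, unit = unit)
  })

  transport <- NULL
  if (!is.null(config$transport)) {
    transport <- stage("transport", {
      res <- transport_report(pathway$unit, config$transport)
      tsv <- file.path(config$out_dir, "transport.tsv")
      utils::write.table(transport_table(res), tsv, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <<- c(files, tsv)
      res
    })
  } else {
    warning("no transport inputs configured: geometry-only report")
  }

  summary <- list(
    input_mode = config$input_mode,
    seed = config$seed,
    n_subunits = length(assembly$subunits),
    rise_A = geometry$params$rise,
    rotation_deg = geometry$params$rotation,
    diameter_A = geometry$diameter_A,
    constraint_total = if (!is.null(constraint_score))
      constraint_score$total else NULL,
    pathway = list(
      cutoff_A = config$cutoff,
      residues_visited = sort(unique(pathway$path$resnos)),
      d1_A = pathway$unit$d1, d2_A = pathway$unit$d2,
      d3_A = pathway$unit$d3,
      bottleneck_A = bottleneck_distance(pathway$unit)),
    transport = if (!is.null(transport)) list(
      t_hole_eV = transport$inputs$t_hole,
      t_elec_eV = transport$inputs$t_elec,
      lambda_eV = transport$inputs$lambda,
      temperature_K = transport$inputs$temperature,
      w_hole_per_s = transport$w_hole, w_elec_per_s = transport$w_elec,
      D_hole_m2_s = transport$D_hole, D_elec_m2_s = transport$D_elec,
      mu_hole_m2_Vs = transport$mu_hole,
      mu_elec_m2_Vs = transport$mu_elec,
      rho_per_m3 = transport$rho, sigma_S_m = transport$sigma,
      G_S = transport$G) else NULL)
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, summary_path)

  invisible(list(assembly = assembly, geometry = geometry,
                 constraint_score = constraint_score,
                 graph = pathway$graph, path = pathway$path,
                 unit = pathway$unit, transport = transport,
                 summary = summary, files = files))
}
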