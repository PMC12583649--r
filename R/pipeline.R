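#' Pipeline configuration
#'
#' Builds and validates the nested configuration driving
#' [run_pipeline()].  Unknown sections or keys are rejected.  Every value
#' has a documented default; the effective configuration is echoed into
#' the output directory of each run.
#'
#' @param config A named list (possibly partial) or a path to a YAML file
#'   with the same structure.  Sections: `simulation` (see
#'   [sim_config()]; presence triggers simulation), `io` (paths
#'   `expression`, `design`, `regulators`, `tf_target_evidence`,
#'   `ppi_evidence` for pre-existing inputs), `inference`, `integration`,
#'   `influence`, `differential` (including `contrasts`, a list of
#'   2-element `(condition_a, condition_b)` pairs), `enrichment`
#'   (`gmt` path), `report`, and a top-level `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    simulation = NULL,
    io = list(expression = NULL, design = NULL, regulators = NULL,
              tf_target_evidence = NULL, ppi_evidence = NULL),
    inference = list(min_support = 0.05, max_set_size = 4, z_threshold = 1.0,
                     max_programs_per_gene = 10, fit_cutoff = 0.8,
                     size_penalty = 0.05, score_method = "hybrid",
                     min_score = 0, subset_shortlist = 10,
                     max_program_size = 5, bic_penalty = 1,
                     max_coact = 10, max_corep = 10,
                     allow_regulator_targets = FALSE),
    integration = list(lambda = 1.0, keep_top = Inf),
    influence = list(min_targets = 5, rule = "combined",
                     one_sided = "fallback", standardize = TRUE),
    differential = list(max_adj_p = 0.05, min_delta = 0.5,
                        min_fold_change = 1.5, moderate = FALSE,
                        contrasts = NULL),
    enrichment = list(gmt = NULL),
    report = list(min_shared_targets = 1, node_direction = "up",
                  target_top_n = 50)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")),
          class = "coregulon_config_error")
  }
  merged <- defaults
  for (sec in names(config)) {
    if (sec %in% c("seed", "simulation")) {
      merged[[sec]] <- config[[sec]]
      next
    }
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in section %s: %s", sec,
                    paste(bad, collapse = ", ")),
            class = "coregulon_config_error")
    }
    merged[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (!is.null(merged$simulation) && !inherits(merged$simulation, "sim_config")) {
    merged$simulation <- do.call(sim_config, merged$simulation)
  }
  structure(merged, class = "pipeline_config")
}

pipeline_log <- function(stage, msg, level = "info") {
  message(sprintf("[coregulon:%s] %s %s", level, stage, msg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> infer -> integrate -> influence ->
#' differential -> enrichment -> report, writing every artifact into
#' `outdir`: the integrated network program table, influence matrix with
#' eligibility sidecar, DIR and DEG tables per contrast, over-
#' representation table (when a gene-set collection is configured), the
#' co-regulatory graph as GraphML and SIF, the extracted regulatory-node
#' summary, the target-direction table, the echoed configuration and a
#' machine-readable run manifest.  Identical configuration and seed give
#' byte-identical output directories.
#'
#' @param config A [pipeline_config()], raw list, or YAML path.
#' @param outdir Output directory (created; must be empty or absent).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the in-memory stage results
#'   (`expression`, `evidence`, `truth`, `network`, `influence`, `dirs`,
#'   `degs`, `graph`, `node`, `manifest`).
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  cfg <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (dir.exists(outdir) && length(list.files(outdir)) > 0) {
    abort("outdir exists and is not empty", class = "coregulon_io_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)),
            class = "coregulon_stage_error", parent = e)
    })
  }

  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    pipeline_log("simulate", "generating synthetic dataset")
    sim_cfg <- cfg$simulation
    sim_cfg$seed <- cfg$seed
    sim <- stage("simulate", simulate_dataset(sim_cfg))
    expr <- sim$expression
    evidence <- sim$evidence
    truth <- sim$truth
    regulators <- rownames(truth$true_activity)
    stage("simulate", {
      write_expression(expr, file.path(outdir, "expression.tsv"),
                       file.path(outdir, "design.tsv"))
      write_evidence(evidence, file.path(outdir, "evidence_tf_target.tsv"),
                     file.path(outdir, "evidence_ppi.tsv"))
      write_ground_truth(truth, file.path(outdir, "ground_truth.json"))
    })
  } else {
    pipeline_log("load", "reading input files")
    io <- cfg$io
    if (is.null(io$expression) || is.null(io$regulators)) {
      abort("without a simulation section, io$expression and io$regulators are required",
            class = "coregulon_config_error")
    }
    expr <- stage("load", read_expression(io$expression, io$design,
                                          missing = "gene-mean"))
    regulators <- stage("load", read_regulators(io$regulators))
    evidence <- stage("load", read_evidence(io$tf_target_evidence,
                                            io$ppi_evidence))
  }

  # --- inference + integration ---------------------------------------------
  pipeline_log("infer", "inferring regulatory network")
  inf <- cfg$inference
  network <- stage("infer", infer_network(
    expr, regulators,
    min_support = inf$min_support, max_set_size = inf$max_set_size,
    z_threshold = inf$z_threshold,
    max_programs_per_gene = inf$max_programs_per_gene,
    fit_cutoff = inf$fit_cutoff, size_penalty = inf$size_penalty,
    score_method = inf$score_method, min_score = inf$min_score,
    subset_shortlist = inf$subset_shortlist,
    max_program_size = inf$max_program_size, bic_penalty = inf$bic_penalty,
    max_coact = inf$max_coact, max_corep = inf$max_corep,
    allow_regulator_targets = inf$allow_regulator_targets
  ))
  pipeline_log("integrate", "re-scoring programs with evidence")
  network <- stage("integrate", integrate_evidence(
    network, evidence, lambda = cfg$integration$lambda,
    keep_top = cfg$integration$keep_top
  ))
  write_network(network, file.path(outdir, "network.tsv"))

  # --- influence ------------------------------------------------------------
  pipeline_log("influence", "computing influence matrix")
  infl <- stage("influence", influence_matrix(
    expr, network, min_targets = cfg$influence$min_targets,
    rule = cfg$influence$rule, one_sided = cfg$influence$one_sided,
    standardize = cfg$influence$standardize
  ))
  write_influence(infl, file.path(outdir, "influence.tsv"),
                  file.path(outdir, "influence_eligibility.tsv"))

  # --- differential ---------------------------------------------------------
  contrasts <- cfg$differential$contrasts
  if (is.null(contrasts)) {
    conds <- unique(expr$design$condition)
    if (length(conds) < 2) {
      abort("no contrast available", class = "coregulon_config_error")
    }
    contrasts <- list(c(conds[1], conds[2]))
  }
  dir_tables <- list()
  deg_tables <- list()
  for (ct in contrasts) {
    a <- ct[[1]]; b <- ct[[2]]
    tag <- paste0(b, "_vs_", a)
    pipeline_log("diff", paste("contrast", tag))
    dirs <- stage("diff", identify_dirs(
      infl, a, b, max_adj_p = cfg$differential$max_adj_p,
      min_delta = cfg$differential$min_delta,
      moderate = cfg$differential$moderate
    ))
    degs <- stage("diff", identify_degs(
      expr, a, b, max_adj_p = cfg$differential$max_adj_p,
      min_fold_change = cfg$differential$min_fold_change,
      moderate = cfg$differential$moderate
    ))
    write_result_table(dirs, file.path(outdir, paste0("dir_", tag, ".tsv")))
    write_result_table(degs, file.path(outdir, paste0("deg_", tag, ".tsv")))
    dir_tables[[tag]] <- dirs
    deg_tables[[tag]] <- degs
  }

  # --- enrichment -----------------------------------------------------------
  if (!is.null(cfg$enrichment$gmt)) {
    pipeline_log("enrich", "over-representation analysis")
    collection <- stage("enrich", read_gmt(cfg$enrichment$gmt))
    for (tag in names(deg_tables)) {
      degs <- deg_tables[[tag]]
      q <- degs$feature_id[degs$class != "ns"]
      if (length(q) == 0) next
      enr <- stage("enrich", enrich_gene_sets(q, collection,
                                              degs$feature_id))
      write_result_table(enr, file.path(outdir,
                                        paste0("enrichment_", tag, ".tsv")))
    }
  }

  # --- report ---------------------------------------------------------------
  pipeline_log("report", "building co-regulatory graph")
  first <- names(dir_tables)[1]
  graph <- stage("report", build_coreg_graph(
    network, dir_tables[[first]], evidence,
    min_shared_targets = cfg$report$min_shared_targets
  ))
  export_graph(graph, file.path(outdir, "coreg_graph.graphml"), "graphml")
  export_graph(graph, file.path(outdir, "coreg_graph.sif"), "sif")
  node <- stage("report", extract_regulatory_node(
    graph, direction = cfg$report$node_direction
  ))
  node_summary <- tibble::tibble(
    members = paste(node$members, collapse = ";"),
    size = node$size,
    mean_group_influence = if (node$size > 0)
      mean_group_influence(node$members, dir_tables[[first]]) else NA_real_
  )
  write_result_table(node_summary, file.path(outdir, "node_summary.tsv"))
  if (node$size > 0) {
    tm <- stage("report", target_matrix(
      network, deg_tables[[first]], node$members, expr = expr,
      top_n = cfg$report$target_top_n
    ))
    write_result_table(tm$directions,
                       file.path(outdir, "target_directions.tsv"))
  }

  # --- manifest -------------------------------------------------------------
  echo <- unclass(cfg)
  echo$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  echo$integration$keep_top <-
    if (is.finite(cfg$integration$keep_top)) cfg$integration$keep_top else "all"
  yaml::write_yaml(echo, file.path(outdir, "config_echo.yaml"))
  manifest <- list(
    package = "coregulon",
    version = as.character(utils::packageVersion("coregulon")),
    seed = cfg$seed,
    contrasts = lapply(contrasts, as.character),
    files = sort(setdiff(list.files(outdir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log("done", sprintf("artifacts in %s", outdir))
  invisible(list(expression = expr, evidence = evidence, truth = truth,
                 network = network, influence = infl, dirs = dir_tables,
                 degs = deg_tables, graph = graph, node = node,
                 manifest = manifest))
}

# Result tables are written with fixed significant-digit formatting so that
# reruns are byte-identical across platforms.
write_result_table <- function(tab, path) {
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.double), ~ num_chr(.x, digits = 10)
  ))
  write_tsv_plain(tab, path)
}
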