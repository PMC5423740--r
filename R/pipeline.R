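# End-to-end orchestration: read -> preprocess -> activity/seed -> PIN ->
# reduce -> greedy selection, with per-stage counts logged via message() and
# optional artifact files.

#' Run the full dysregulated-pathway pipeline
#'
#' Accepts in-memory objects or file paths for the three inputs. Executes
#' standardization and filtering, pathway activity scoring and seed
#' selection, PIN construction and top-fraction reduction, and greedy
#' SVM/AUC selection. Stage counts (genes kept, pathways kept, DEGs, edges,
#' kept edges, selected pathways) are logged; intermediate artifacts are
#' written when `out_dir` is given.
#'
#' @param study an [expression_study()] or a path to an expression TSV.
#' @param pathways a [pathway_collection()] or a path to a GMT file.
#' @param ppi a [ppi_network()] or a path to a PPI TSV.
#' @param labels required when `study` is a path: label sidecar path or
#'   named vector (see [read_expression_tsv()]).
#' @param min_genes pathway size filter (default 5 measured genes).
#' @param confidence_threshold PPI confidence filter (default 0.2, strict).
#' @param deg_alpha DEG significance level (default 0.05).
#' @param pcc_threshold co-expression qualification threshold (default 0.8).
#' @param top_fraction fraction of PIN edges kept (default 0.05).
#' @param weight_condition condition feeding edge weights (default
#'   `"max_abs"`; see [build_pin()]).
#' @param cv a [cv_config()].
#' @param score_scale passed to [read_ppi_tsv()] when `ppi` is a path.
#' @param out_dir optional directory for artifacts (DEG table, activity
#'   statistics, full and reduced PIN edge lists, selected pathways,
#'   result JSON).
#' @return a list of class `pipeline_run` with elements `result`
#'   (a [selection_result()]), `inputs`, `activity`, `seed`, `degs`,
#'   `corr`, `pin`, `pin_reduced`.
#' @export
run_pipeline <- function(study, pathways, ppi, labels = NULL,
                         min_genes = 5L, confidence_threshold = 0.2,
                         deg_alpha = 0.05, pcc_threshold = 0.8,
                         top_fraction = 0.05,
                         weight_condition = "max_abs",
                         cv = cv_config(),
                         score_scale = "string1000",
                         out_dir = NULL) {
  if (is.character(study)) {
    study <- read_expression_tsv(study, labels = labels)
  }
  if (is.character(pathways)) pathways <- read_gmt(pathways)
  if (is.character(ppi)) ppi <- read_ppi_tsv(ppi, score_scale = score_scale)

  inputs <- prepare_inputs(study, pathways, ppi, min_genes = min_genes,
                           confidence_threshold = confidence_threshold)
  message(sprintf(
    "pipeline: %d genes standardized; %d informative pathways; %d targeted PPI edges",
    nrow(inputs$study$standardized), length(inputs$pathways),
    nrow(inputs$ppi)))
  if (length(inputs$pathways) == 0L) {
    stopf("stage preprocess: no pathway passed the size filter")
  }

  activity <- compute_activity_matrix(inputs)
  seed <- select_seed(activity, inputs$study$labels)
  message(sprintf("pipeline: seed pathway ID %d (|t| = %.4f)",
                  seed$seed_id, seed$statistic))

  degs <- differential_expression(inputs$study, alpha = deg_alpha)
  message(sprintf("pipeline: %d DEGs at alpha = %g", sum(degs$is_deg),
                  deg_alpha))

  corr <- pairwise_pcc(inputs$study, inputs$ppi)
  pin <- build_pin(inputs, degs, corr, pcc_threshold = pcc_threshold,
                   weight_condition = weight_condition)
  pin_reduced <- reduce_top_fraction(pin, fraction = top_fraction)
  message(sprintf("pipeline: PIN %d edges; reduced to top %g%% = %d edges",
                  nrow(pin$edges), 100 * top_fraction,
                  nrow(pin_reduced$edges)))

  result <- greedy_select(seed, pin_reduced, activity,
                          inputs$study$labels, cv = cv)
  message(sprintf("pipeline: selected %d pathway(s), final AUC %.4f",
                  result$n_pathways, result$final_auc))

  run <- structure(
    list(result = result, inputs = inputs, activity = activity, seed = seed,
         degs = degs, corr = corr, pin = pin, pin_reduced = pin_reduced),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(run, out_dir, cv = cv)
  run
}

write_pipeline_artifacts <- function(run, out_dir, cv = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$degs, file.path(out_dir, "deg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$seed$per_pathway_statistics,
                     file.path(out_dir, "activity_statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_tsv(run$pin, file.path(out_dir, "pin_full.tsv"))
  write_network_tsv(run$pin_reduced, file.path(out_dir, "pin_reduced.tsv"))
  sel <- run$result$selected_ids
  pc <- run$inputs$pathways
  utils::write.table(
    data.frame(
      id = sel,
      name = pathway_name(pc, sel),
      n_genes = lengths(pc$genesets[sel + 1L]),
      order_added = seq_along(sel),
      auc_after_adding = run$result$auc_trace
    ),
    file.path(out_dir, "selected_pathways.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cfg <- if (is.null(cv)) NULL else unclass(cv)
  write_results_json(run$result, file.path(out_dir, "result.json"),
                     config = cfg)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' Generate a synthetic study and write its input files
#'
#' Writes the three standard inputs plus ground truth: `expression.tsv`,
#' `labels.tsv`, `pathways.gmt`, `ppi.tsv` (unit-scale scores) and
#' `ground_truth.json`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the five file paths.
#' @export
run_synth <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  synth <- generate_study(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    labels = file.path(out_dir, "labels.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    ppi = file.path(out_dir, "ppi.tsv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_expression_tsv(synth$study, paths[["expression"]],
                       labels_path = paths[["labels"]])
  write_gmt(synth$pathways, paths[["gmt"]])
  write_ppi_tsv(synth$ppi, paths[["ppi"]])
  jsonlite::write_json(
    list(planted_pathway_ids = I(synth$truth$planted_pathway_ids),
         affected_genes = I(synth$truth$affected_genes),
         config = unclass(config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
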