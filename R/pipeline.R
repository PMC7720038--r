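## End-to-end orchestration: simulate (or read) -> cluster -> characterize
## -> model -> differential expression -> report bundle. All randomness
## flows from the configured seeds; rerunning a config is byte-identical.

#' Pipeline configuration
#'
#' Exactly one of `simulation` or `paths` must be supplied. `paths` is a
#' named list with `expression` (TSV), `clinical` (CSV) and `events`
#' (CSV). Characterization and modeling always use the *discovered*
#' labels, never simulation truth.
#'
#' @param simulation Optional [simulation_config()].
#' @param paths Optional named list of input paths.
#' @param clustering List of clustering options: `k_max`, `B`, `n_init`,
#'   `min_cluster_size`, `seed`.
#' @param modeling List with `adjust` (preset names, see
#'   [adjustment_presets()]).
#' @param de List with `min_value`, `min_samples`, `fc_threshold`,
#'   `q_threshold`.
#' @param output_dir Directory for the report bundle.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            clustering = list(), modeling = list(),
                            de = list(), output_dir = tempfile("pardsub_")) {
  if (is.null(simulation) == is.null(paths)) {
    stop_domain("config error: exactly one of 'simulation' or 'paths' must be given")
  }
  if (!is.null(paths)) {
    need <- c("expression", "clinical", "events")
    if (!all(need %in% names(paths))) {
      stop_domain("config error: paths needs ", paste(need, collapse = ", "))
    }
  }
  cl_def <- list(k_max = 10, B = 50, n_init = 10, min_cluster_size = 11,
                 max_iter = 300, seed = 1L)
  clustering <- utils::modifyList(cl_def, clustering)
  if (clustering$k_max < 1 || clustering$B < 2 || clustering$n_init < 1 ||
      clustering$min_cluster_size < 1) {
    stop_domain("config error: clustering thresholds out of range")
  }
  mo_def <- list(adjust = names(adjustment_presets()))
  modeling <- utils::modifyList(mo_def, modeling)
  de_def <- list(min_value = 10, min_samples = 10,
                 fc_threshold = 2, q_threshold = 0.1)
  de <- utils::modifyList(de_def, de)
  if (de$fc_threshold < 1 || de$q_threshold <= 0 || de$q_threshold > 1) {
    stop_domain("config error: de thresholds out of range")
  }
  cfg <- list(simulation = simulation, paths = paths, clustering = clustering,
              modeling = modeling, de = de, output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full sub-phenotyping pipeline
#'
#' Simulates or reads the cohort, clusters subjects on gene expression
#' with gap-statistic selection of k, characterizes the discovered
#' subtypes against clinical variables, fits the mortality and extubation
#' models under the configured adjustment presets, extracts per-subtype
#' gene signatures, and writes the report bundle (labels CSV, gap-curve
#' TSV, characterization TSV, model TSV, DE TSVs, JSON manifest with
#' seeds and the k-selection audit trail).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects (`cohort`,
#'   `gap_curve`, `selection`, `labels`, `table1`, `table2`, `de`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    expression <- cohort$expression
    clinical <- cohort$clinical
    events <- cohort$events
  } else {
    cohort <- NULL
    expression <- read_expression(config$paths$expression)
    clinical <- read_clinical(config$paths$clinical)
    events <- read_events(config$paths$events)
  }
  align_subjects(expression, clinical, events)

  cl <- config$clustering
  curve <- gap_statistic(t(expression), k_max = cl$k_max, B = cl$B,
                         n_init = cl$n_init, max_iter = cl$max_iter,
                         seed = sub_seed(cl$seed, "clustering"))
  selection <- select_k(curve, min_cluster_size = cl$min_cluster_size)
  labels <- attr(curve, "clusterings")[[selection$k]]

  table1 <- characterize_subtypes(clinical, labels, events)
  table2 <- fit_outcome_models(clinical, labels, events,
                               adjust = config$modeling$adjust)

  de_cfg <- config$de
  kept <- filter_expressed(expression, de_cfg$min_value, de_cfg$min_samples)
  de_res <- list()
  if (length(kept) >= 2) {
    xf <- expression[kept, , drop = FALSE]
    for (j in sort(unique(labels))) {
      res <- de_one_vs_rest(xf, labels, j)
      degs <- select_degs(res, de_cfg$fc_threshold, de_cfg$q_threshold)
      res$direction <- ifelse(res$gene_id %in% degs$up, "up",
                              ifelse(res$gene_id %in% degs$down, "down", "ns"))
      de_res[[paste0("subtype", j)]] <- res
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("pardsub")),
    config = serialize_config(config),
    seeds = list(
      clustering = sub_seed(cl$seed, "clustering"),
      simulation = if (!is.null(config$simulation)) config$simulation$seed),
    selected_k = selection$k,
    select_k_audit = selection$audit,
    n_subjects = ncol(expression),
    n_genes = nrow(expression),
    n_genes_filtered = length(kept))

  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(data.frame(subject_id = names(labels),
                       subtype = as.integer(labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  write.table(as.data.frame(curve), file.path(dir, "gap_curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table1, file.path(dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(table2, file.path(dir, "table2.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(de_res)) {
    write.table(de_res[[nm]], file.path(dir, paste0("de_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(cohort = cohort, gap_curve = curve, selection = selection,
                 labels = labels, table1 = table1, table2 = table2,
                 de = de_res, manifest = manifest, output_dir = dir))
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out$output_dir <- NULL  # location is not part of the analysis identity
  out
}
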