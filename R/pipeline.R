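#' Run configuration for the end-to-end pipeline
#'
#' Collects everything one pipeline run needs: where the graph lives (or a
#' synthetic spec to generate one), the disease concept ids, the node-type
#' role mapping, and the estimation/evaluation settings. All randomness in
#' a run flows from `seed`.
#'
#' @param out_dir Output directory for artifacts.
#' @param edge_table,node_table Paths to a typed graph (ignored if
#'   `simulate` is given).
#' @param simulate Optional [synthetic_spec()]; when present the graph is
#'   generated rather than loaded and the disease ids default to the
#'   generated disease nodes.
#' @param disease_cuis Character vector of disease concept ids.
#' @param roles A [kg_roles()] mapping.
#' @param n_iterations,n_folds,decision_threshold,top_k Estimation and
#'   evaluation settings (defaults 40, 5, 0.5, 15).
#' @param seed Base seed for every stochastic step.
#' @param learner_config Partial override of [default_learner_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, edge_table = NULL, node_table = NULL,
                       simulate = NULL, disease_cuis = NULL,
                       roles = kg_roles(), n_iterations = 40L, n_folds = 5L,
                       decision_threshold = 0.5, top_k = 15L, seed = 1L,
                       learner_config = list()) {
  if (is.null(simulate)) {
    if (is.null(edge_table)) stop("either edge_table or simulate must be given")
    if (!file.exists(edge_table)) stop("edge table not found: ", edge_table)
    if (!is.null(node_table) && !file.exists(node_table)) {
      stop("node table not found: ", node_table)
    }
    if (is.null(disease_cuis) || !length(disease_cuis)) {
      stop("disease_cuis required when loading a graph")
    }
  } else {
    stopifnot(inherits(simulate, "synthetic_spec"))
  }
  if (!inherits(roles, "kg_roles")) stop("roles must be built with kg_roles()")
  structure(list(out_dir = out_dir, edge_table = edge_table,
                 node_table = node_table, simulate = simulate,
                 disease_cuis = disease_cuis, roles = roles,
                 n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds),
                 decision_threshold = decision_threshold,
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 learner_config = learner_config),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields map 1:1 to [run_config()] arguments; `roles` is a mapping
#' with keys disease/compound/gene/term, and `simulate` a mapping of
#' [synthetic_spec()] fields.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  roles <- if (is.null(cfg$roles)) kg_roles() else do.call(kg_roles, cfg$roles)
  simulate <- if (is.null(cfg$simulate)) NULL else
    do.call(synthetic_spec, cfg$simulate)
  run_config(
    out_dir = if (is.null(out_dir)) cfg$out_dir else out_dir,
    edge_table = cfg$edge_table, node_table = cfg$node_table,
    simulate = simulate, disease_cuis = cfg$disease_cuis, roles = roles,
    n_iterations = cfg$n_iterations %||% 40L,
    n_folds = cfg$n_folds %||% 5L,
    decision_threshold = cfg$decision_threshold %||% 0.5,
    top_k = cfg$top_k %||% 15L,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

report_to_list <- function(r) {
  list(model_name = r$model_name,
       recall_mean = r$recall_mean,
       recall_ci95 = as.numeric(r$recall_ci95),
       per_iteration_recall = as.numeric(r$per_iteration_recall),
       precision_mean = r$precision_mean,
       precision_ci95 = as.numeric(r$precision_ci95),
       auroc_mean = r$auroc_mean,
       auroc_ci95 = as.numeric(r$auroc_ci95),
       threshold = r$threshold)
}

#' Run the full pipeline: label, estimate, evaluate, report
#'
#' Executes the whole workflow — graph acquisition (load or simulate),
#' metapath labeling, feature building, repeated SCAR prior estimation
#' with calibration and imputation, baseline vs PU-augmented evaluation,
#' and the top-k gene report — and writes every artifact plus a manifest
#' of content hashes to `config$out_dir`.
#'
#' Artifacts: `labels.tsv`, `dataset.mtx` (+ row/col registries),
#' `alpha.json`, `calibrated.tsv`, `metrics_model1.json`,
#' `metrics_model2.json`, `topk.tsv`, `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`sets`,
#'   `dataset`, `alpha`, `scores`, `model1`, `model2`, `topk`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    spec <- config$simulate
    spec$seed <- config$seed
    sim <- generate_synthetic_kg(spec)
    kg <- sim$kg
    cuis <- config$disease_cuis %||% sim$truth$disease_cuis
  } else {
    kg <- kg_load(config$edge_table, config$node_table)
    cuis <- config$disease_cuis
  }

  sets <- label_genes(kg, cuis, config$roles)
  labels <- data.frame(
    gene_id = c(sets$positive_genes, sets$unlabeled_genes),
    label = c(rep("positive", length(sets$positive_genes)),
              rep("unlabeled", length(sets$unlabeled_genes))))
  write.table(labels, file.path(config$out_dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dataset <- build_pu_dataset(kg, sets)
  write_pu_dataset(dataset, file.path(config$out_dir, "dataset"))

  pu <- run_pu_iterations(dataset, n_iterations = config$n_iterations,
                          n_folds = config$n_folds, base_seed = config$seed,
                          learner_config = config$learner_config)
  message(sprintf("estimated alpha = %.4f (95%% CI %.4f, %.4f)",
                  pu$alpha$alpha, pu$alpha$ci95[1L], pu$alpha$ci95[2L]))
  write_json(list(alpha = pu$alpha$alpha,
                  ci95 = as.numeric(pu$alpha$ci95),
                  per_iteration = as.numeric(pu$alpha$per_iteration_alphas)),
             file.path(config$out_dir, "alpha.json"))
  calib <- data.frame(gene_id = pu$scores$gene_ids,
                      mean_probability = pu$scores$mean_calibrated,
                      imputed_flag = as.integer(
                        pu$scores$gene_ids %in% pu$scores$imputed_positives))
  write.table(calib, file.path(config$out_dir, "calibrated.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ecfg <- eval_config(n_folds = config$n_folds,
                      n_iterations = config$n_iterations,
                      decision_threshold = config$decision_threshold,
                      base_seed = config$seed,
                      learner_config = config$learner_config)
  m1 <- run_model1(dataset, ecfg)
  m2 <- run_model2(dataset, pu$scores$imputed_positives, ecfg)
  write_json(report_to_list(m1), file.path(config$out_dir, "metrics_model1.json"))
  write_json(report_to_list(m2), file.path(config$out_dir, "metrics_model2.json"))

  topk <- top_k_report(pu$scores, min(config$top_k, length(pu$scores$gene_ids)))
  write.table(topk, file.path(config$out_dir, "topk.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  files <- c("labels.tsv", "dataset.mtx", "dataset_rows.tsv", "dataset_cols.tsv",
             "alpha.json", "calibrated.tsv", "metrics_model1.json",
             "metrics_model2.json", "topk.tsv")
  manifest <- list(
    seed = config$seed,
    n_positive = length(sets$positive_genes),
    n_unlabeled = length(sets$unlabeled_genes),
    n_features = length(sets$feature_terms),
    alpha = pu$alpha$alpha,
    files = lapply(setNames(files, files), function(f) {
      list(path = f,
           md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
  )
  write_json(manifest, file.path(config$out_dir, "manifest.json"))

  invisible(list(sets = sets, dataset = dataset, alpha = pu$alpha,
                 scores = pu$scores, model1 = m1, model2 = m2, topk = topk,
                 manifest = manifest))
}
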