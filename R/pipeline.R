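# End-to-end pipelines wiring the stages together, with JSON/YAML config
# support and machine-readable provenance so any run can be reproduced
# bit-identically.

#' Read a pipeline configuration file
#'
#' Configuration files mirror the arguments of [run_chill_pipeline()] and
#' [run_network_pipeline()] as a flat mapping; JSON is always supported and
#' YAML when the `yaml` package is available.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_provenance <- function(out_dir, params) {
  params$package_version <- as.character(utils::packageVersion("dormabreak"))
  jsonlite::write_json(params, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
}

#' Run the chilling-model pipeline
#'
#' Sprouting CSV -> chill-unit table -> quadratic chill-unit model ->
#' stage-wise CAS models -> in-sample verification. Writes
#' `cu_table.csv`, `cu_model.json`, `cas_stage_<day>.json` per stage,
#' `verification.json` and `provenance.json` into `out_dir`.
#'
#' @param sprouting Path to a sprouting CSV (see [read_sprouting_csv()]) or
#'   a [sprouting_experiment()].
#' @param out_dir Output directory (created if needed).
#' @param reference_temperature Reference for the chill-unit ratio
#'   (default 0 deg C).
#' @param stages Warming days for the CAS models (default 37, 40, 44, 50).
#' @return Invisibly, a list with the fitted `cu_model`, the `cu_table`,
#'   the list of `cas_models`, the per-stage `verification` stats, and the
#'   artifact paths.
#' @export
run_chill_pipeline <- function(sprouting, out_dir,
                               reference_temperature = 0,
                               stages = c(37, 40, 44, 50)) {
  experiment <- if (inherits(sprouting, "sprouting_experiment")) sprouting
  else read_sprouting_csv(sprouting)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  table <- step("chill_unit_table",
                chill_unit_table(experiment, reference_temperature))
  utils::write.csv(as.data.frame(table), file.path(out_dir, "cu_table.csv"),
                   row.names = FALSE, quote = FALSE)
  cu_model <- step("fit_cu_model", fit_cu_model(table))
  write_model_json(cu_model, file.path(out_dir, "cu_model.json"))
  cas_models <- list()
  verification <- list()
  for (day in stages) {
    key <- sprintf("stage_%d", day)
    pts <- step(key, stage_observations(experiment, cu_model, day))
    cas <- step(key, fit_cas(pts, stage_day = day))
    write_model_json(cas, file.path(out_dir, sprintf("cas_stage_%d.json", day)))
    v <- verify_predictions(predict_sprouting(cas, pts$ca), pts$sprouting_pct)
    cas_models[[key]] <- cas
    verification[[key]] <- unclass(v)
  }
  jsonlite::write_json(verification, file.path(out_dir, "verification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, list(
    pipeline = "chill",
    reference_temperature = reference_temperature, stages = stages))
  invisible(list(cu_model = cu_model, cu_table = table,
                 cas_models = cas_models, verification = verification,
                 out_dir = out_dir))
}

#' Run the coexpression-network pipeline
#'
#' Expression + trait CSVs -> soft threshold -> adjacency -> TOM -> modules
#' -> eigengenes -> module-trait correlation -> GS/MM -> hub screen. Writes
#' `soft_threshold.csv`, `labels.csv`, `eigengenes.csv`, `module_trait.csv`,
#' `gene_stats.csv`, `hubs.csv`, one `edges_<module>.tsv` per significant
#' module, and `provenance.json` into `out_dir`.
#'
#' @param expr Path to an expression CSV or an [expression_matrix()].
#' @param trait_path Trait CSV path (required when `expr` is a path).
#' @param out_dir Output directory (created if needed).
#' @param powers Candidate soft-threshold powers.
#' @param beta Soft threshold override; `NULL` (default) picks it via
#'   [pick_soft_threshold()]. An override is honoured and recorded in the
#'   provenance.
#' @param min_module_size,merge_height Module detection parameters.
#' @param transform Expression transform, `"log1p"` (default) or `"none"`.
#' @param criteria A [hub_criteria()].
#' @return Invisibly, a list with `beta`, `soft_threshold` table, `labels`,
#'   `eigengenes`, `module_trait`, `stats`, `hubs` and the output dir.
#' @export
run_network_pipeline <- function(expr, trait_path = NULL, out_dir,
                                 powers = 1:20, beta = NULL,
                                 min_module_size = 30, merge_height = 0.98,
                                 transform = "log1p",
                                 criteria = hub_criteria()) {
  if (!inherits(expr, "expression_matrix")) {
    if (is.null(trait_path)) stop("trait_path is required with a CSV input")
    expr <- read_expression_csv(expr, trait_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sft <- pick_soft_threshold(expr, powers = powers, transform = transform)
  utils::write.csv(sft$table, file.path(out_dir, "soft_threshold.csv"),
                   row.names = FALSE, quote = FALSE)
  beta_used <- if (is.null(beta)) sft$beta else beta
  adj <- adjacency(expr, beta_used, transform = transform)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom, min_module_size = min_module_size,
                           merge_height = merge_height)
  utils::write.csv(data.frame(gene_id = names(labels),
                              module = unname(labels)),
                   file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  me <- module_eigengene(expr, labels, transform = transform)
  utils::write.csv(data.frame(sample_id = rownames(me), me,
                              check.names = FALSE),
                   file.path(out_dir, "eigengenes.csv"),
                   row.names = FALSE, quote = FALSE)
  mt <- module_trait_correlation(me, expr$trait)
  utils::write.csv(mt, file.path(out_dir, "module_trait.csv"),
                   row.names = FALSE, quote = FALSE)
  st <- gene_trait_statistics(expr, expr$trait, labels, me,
                              transform = transform)
  utils::write.csv(st, file.path(out_dir, "gene_stats.csv"),
                   row.names = FALSE, quote = FALSE)
  hubs <- real_hub_genes(tom, labels, st, mt, criteria)
  utils::write.csv(as.data.frame(hubs), file.path(out_dir, "hubs.csv"),
                   row.names = FALSE, quote = FALSE)
  for (mod in significant_modules(mt, criteria$module_trait_min)) {
    edges <- module_edge_list(tom, labels, mod,
                              edge_threshold_for(criteria, mod))
    export_edges_tsv(edges, file.path(out_dir,
                                      sprintf("edges_%s.tsv", mod)))
  }
  write_provenance(out_dir, list(
    pipeline = "network", powers = powers, beta = beta_used,
    beta_overridden = !is.null(beta), min_module_size = min_module_size,
    merge_height = merge_height, transform = transform,
    criteria = unclass(criteria)))
  invisible(list(beta = beta_used, soft_threshold = sft$table,
                 labels = labels, eigengenes = me, module_trait = mt,
                 stats = st, hubs = hubs, out_dir = out_dir))
}
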