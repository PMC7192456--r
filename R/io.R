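#' Read and write sprouting time-course CSV files
#'
#' Long-format CSV with header
#' `temperature,chilling_days,replicate,n_buds,day,sprouted`: one row per
#' tray and warming day, `sprouted` the cumulative count. Replicates are
#' kept explicit so slopes and their spread can be computed per tray.
#'
#' @param path CSV file path.
#' @return `read_sprouting_csv()` returns a validated
#'   [sprouting_experiment()]; `write_sprouting_csv()` writes one and
#'   returns `path` invisibly. Writing then reading reproduces the
#'   experiment exactly.
#' @export
read_sprouting_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  sprouting_experiment(df)
}

#' @rdname read_sprouting_csv
#' @param experiment A [sprouting_experiment()].
#' @export
write_sprouting_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "sprouting_experiment"))
  utils::write.csv(as.data.frame(experiment), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write expression + trait CSV files
#'
#' The expression CSV has a first column `gene_id` and one numeric column
#' per sample (FPKM). The trait CSV has columns
#' `sample_id,sprouting_percentage`. The two files must describe the same
#' samples; the trait is re-ordered to match the expression columns.
#'
#' @param path Expression CSV path.
#' @param trait_path Trait CSV path.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path, trait_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(trait_path)) stop("file not found: ", trait_path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "gene_id") {
    stop("expression schema error: first column must be 'gene_id'")
  }
  mat <- as.matrix(df[-1])
  if (!is.numeric(mat)) stop("expression schema error: non-numeric FPKM values")
  rownames(mat) <- as.character(df$gene_id)
  tr <- utils::read.csv(trait_path, check.names = FALSE)
  if (!all(c("sample_id", "sprouting_percentage") %in% names(tr))) {
    stop("trait schema error: need columns sample_id,sprouting_percentage")
  }
  missing <- setdiff(colnames(mat), as.character(tr$sample_id))
  if (length(missing) > 0) {
    stop("alignment error: trait file missing sample(s) ",
         paste(missing, collapse = ", "))
  }
  trait <- stats::setNames(tr$sprouting_percentage, as.character(tr$sample_id))
  expression_matrix(mat, trait[colnames(mat)])
}

#' @rdname read_expression_csv
#' @param expr An [expression_matrix()].
#' @export
write_expression_csv <- function(expr, path, trait_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = names(expr$trait),
                              sprouting_percentage = unname(expr$trait)),
                   trait_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted models to JSON
#'
#' Models are written with their coefficients, derived constants and fit
#' diagnostics. On reading, derived constants are recomputed from the
#' coefficients and checked against the stored values, so a JSON file whose
#' derived block was edited by hand is rejected with an integrity error.
#'
#' @param model A [chill_unit_model()] or [cas_stage_model()].
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the reconstructed model.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "chill_unit_model")) {
    obj <- list(type = "chill_unit_quadratic",
                coefficients = list(a = model$a, b = model$b, c = model$c),
                derived = list(t_opt = model$t_opt, cu_max = model$cu_max,
                               t_upper = model$t_upper),
                fit = list(r_squared = model$r_squared))
  } else if (inherits(model, "cas_stage_model")) {
    obj <- list(type = "cas_stage_quadratic",
                stage_day = model$stage_day,
                coefficients = list(alpha = model$alpha, beta = model$beta,
                                    gamma = model$gamma),
                derived = list(
                  optimum_ca = if (model$has_optimum) optimum_ca(model) else NA),
                fit = list(r_squared = model$r_squared))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel_ok <- function(stored, recomputed) {
    if (is.null(stored) || length(stored) == 0 || is.na(stored)) {
      return(is.na(recomputed))
    }
    abs(stored - recomputed) <= 1e-6 * max(1, abs(recomputed))
  }
  if (identical(obj$type, "chill_unit_quadratic")) {
    cf <- obj$coefficients
    model <- chill_unit_model(cf$a, cf$b, cf$c,
                              r_squared = obj$fit$r_squared %||% NA_real_)
    if (!rel_ok(obj$derived$t_opt, model$t_opt) ||
        !rel_ok(obj$derived$cu_max, model$cu_max) ||
        !rel_ok(obj$derived$t_upper, model$t_upper)) {
      stop("integrity error: stored derived constants are inconsistent with coefficients")
    }
    model
  } else if (identical(obj$type, "cas_stage_quadratic")) {
    cf <- obj$coefficients
    model <- cas_stage_model(obj$stage_day, cf$alpha, cf$beta, cf$gamma,
                             r_squared = obj$fit$r_squared %||% NA_real_)
    stored_opt <- obj$derived$optimum_ca
    recomputed <- if (model$has_optimum) optimum_ca(model) else NA_real_
    if (!rel_ok(stored_opt, recomputed)) {
      stop("integrity error: stored derived constants are inconsistent with coefficients")
    }
    model
  } else {
    stop("unknown model type in ", path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
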