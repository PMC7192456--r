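#' Expression matrix with a per-sample trait
#'
#' Container for an FPKM expression matrix (genes x samples) together with a
#' per-sample quantitative trait, here the sprouting percentage of the bud
#' samples. Genes with zero variance across samples are flagged on
#' construction; they are retained in the matrix but excluded from
#' correlation-based operations downstream.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids, no
#'   missing ids) and samples in columns (colnames = sample ids). All values
#'   must be >= 0 (FPKM).
#' @param trait Numeric vector of per-sample trait values, either named by
#'   sample id or in column order; length must equal the number of samples.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `trait` (named, aligned to columns) and `zero_variance`
#'   (named logical per gene).
#' @export
expression_matrix <- function(values, trait) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(rownames(values) == "")) {
    stop("validation error: every gene must have a non-missing id")
  }
  if (anyDuplicated(rownames(values))) {
    stop("validation error: duplicated gene ids")
  }
  if (is.null(colnames(values))) {
    stop("'values' must have sample ids as column names")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("validation error: FPKM values must be non-negative and non-missing")
  }
  if (length(trait) != ncol(values)) {
    stop(sprintf("alignment error: trait has %d values for %d samples",
                 length(trait), ncol(values)))
  }
  if (!is.null(names(trait))) {
    missing <- setdiff(colnames(values), names(trait))
    if (length(missing) > 0) {
      stop("alignment error: trait missing sample(s) ",
           paste(missing, collapse = ", "))
    }
    trait <- trait[colnames(values)]
  } else {
    names(trait) <- colnames(values)
  }
  sds <- apply(values, 1, stats::sd)
  structure(list(values = values, trait = trait,
                 zero_variance = stats::setNames(sds == 0, rownames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d zero-variance)\n",
              nrow(x$values), ncol(x$values), sum(x$zero_variance)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Log-transformed expression used by all correlation-based operations.
# log1p keeps zeros finite and tames the decades-wide FPKM scale.
expr_log_matrix <- function(expr, transform = c("log1p", "none")) {
  stopifnot(inherits(expr, "expression_matrix"))
  transform <- match.arg(transform)
  if (transform == "log1p") log1p(expr$values) else expr$values
}

# Gene ids usable for correlation work (positive variance), with a warning
# when constant genes are dropped.
usable_genes <- function(expr) {
  zv <- expr$zero_variance
  if (any(zv)) {
    warning(sprintf("excluding %d zero-variance gene(s) from correlation operations",
                    sum(zv)))
  }
  names(zv)[!zv]
}
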