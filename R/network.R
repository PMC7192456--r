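# Weighted coexpression network construction, written from scratch:
# soft-threshold selection against scale-free topology, unsigned adjacency,
# topological overlap, static-cut module detection, eigengenes, and
# module/gene trait statistics.

# Pearson correlation matrix between gene profiles on the log scale,
# restricted to genes with positive variance.
gene_cor_matrix <- function(expr, transform = "log1p") {
  keep <- usable_genes(expr)
  if (length(keep) < 2) stop("too few genes with positive variance")
  logm <- expr_log_matrix(expr, transform)[keep, , drop = FALSE]
  stats::cor(t(logm))
}

# Scale-free topology fit for a connectivity vector: bin k, regress
# log10(frequency) on log10(mean k per bin), and sign the R^2 negatively
# when the slope is positive (scale-free networks require a falling tail).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2 || max(k) <= 0) {
    return(list(r_squared = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 3) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-thresholding power for a scale-free network
#'
#' For each candidate power beta, builds the unsigned weighted network
#' a_ij = |cor(i,j)|^beta on log-scale expression and evaluates how well the
#' connectivity distribution k_i = sum_j a_ij conforms to scale-free
#' topology: the signed R^2 of the regression of log10(frequency) on
#' log10(connectivity) over binned connectivities (negative slopes count
#' positively; rising degree distributions are penalised). The chosen beta
#' is the smallest power whose signed R^2 reaches `r2_threshold`, falling
#' back to the power with the largest signed R^2 when none does.
#'
#' @param expr An [expression_matrix()] (>= 4 samples, >= 30 genes).
#' @param powers Candidate integer powers.
#' @param r2_threshold Scale-free fit target (default 0.85).
#' @param n_bins Number of connectivity bins (>= 10 recommended).
#' @param transform Expression transform, `"log1p"` (default) or `"none"`.
#' @return A list with `beta` (chosen power) and `table`, a data frame with
#'   one row per power: `power`, `scale_free_r2` (signed), and
#'   `mean_connectivity`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_threshold = 0.85,
                                n_bins = 10, transform = "log1p") {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 4) stop("too few samples: need >= 4")
  if (sum(!expr$zero_variance) < 30) stop("too few genes: need >= 30")
  cm <- abs(gene_cor_matrix(expr, transform))
  diag(cm) <- 0
  rows <- lapply(powers, function(p) {
    k <- colSums(cm^p)
    sf <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = p, scale_free_r2 = sf$r_squared,
               mean_connectivity = mean(k))
  })
  table <- do.call(rbind, rows)
  hit <- which(!is.na(table$scale_free_r2) &
                 table$scale_free_r2 >= r2_threshold)
  beta <- if (length(hit) > 0) {
    table$power[hit[1]]
  } else {
    table$power[which.max(table$scale_free_r2)]
  }
  list(beta = beta, table = table)
}

#' Unsigned weighted adjacency matrix
#'
#' a_ij = |pearson cor(log1p FPKM_i, log1p FPKM_j)|^beta with a_ii = 0.
#' Zero-variance genes are excluded (with a warning naming how many).
#'
#' @param expr An [expression_matrix()].
#' @param beta Soft-thresholding power (>= 1).
#' @param transform Expression transform, `"log1p"` (default) or `"none"`.
#' @return Symmetric gene x gene matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @export
adjacency <- function(expr, beta, transform = "log1p") {
  stopifnot(inherits(expr, "expression_matrix"))
  check_number(beta, "beta")
  if (beta < 1) stop("'beta' must be >= 1")
  a <- abs(gene_cor_matrix(expr, transform))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix (TOM)
#'
#' Similarity between genes combining their direct connection and shared
#' neighbourhood: TOM_ij = (sum_u a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij) with TOM_ii = 1, where k_i is the
#' connectivity of gene i. Symmetric with entries in \[0, 1\].
#'
#' @param adjacency_matrix Symmetric adjacency with zero diagonal, entries
#'   in \[0, 1\].
#' @return The TOM matrix.
#' @export
topological_overlap <- function(adjacency_matrix) {
  a <- adjacency_matrix
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("adjacency must be square")
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom
}

# Fixed module colour sequence (largest module first), following the
# conventional naming of coexpression tools.
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq.int(length(base) + 1, n)))
}

#' Detect coexpression modules by clustering the TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut statically at `merge_height`. Clusters smaller than
#' `min_module_size` are labelled `"unassigned"`. Modules are named from a
#' fixed colour sequence in decreasing size order (ties broken by the
#' lexicographically smallest member gene id), and genes are processed in
#' lexicographic id order so the result is invariant to input order.
#'
#' @param tom Square TOM (or other similarity) matrix with gene ids as
#'   dimnames.
#' @param min_module_size Minimum genes per module (>= 2).
#' @param merge_height Static cut height on 1 - TOM (default 0.98).
#' @return Named character vector: gene id -> module name (or
#'   `"unassigned"`), with the `hclust` tree attached as attribute
#'   `"dendrogram"`.
#' @export
detect_modules <- function(tom, min_module_size = 30, merge_height = 0.98) {
  if (!is.matrix(tom) || nrow(tom) != ncol(tom)) stop("TOM must be square")
  if (is.null(rownames(tom))) stop("TOM must carry gene ids as dimnames")
  if (min_module_size < 2) stop("config error: min_module_size must be >= 2")
  ord <- order(rownames(tom))
  tom <- tom[ord, ord]
  diss <- stats::as.dist(1 - tom)
  tree <- stats::hclust(diss, method = "average")
  # average linkage is monotone; floating-point ties can still leave heights
  # microscopically out of order, which cutree rejects
  tree$height <- cummax(tree$height)
  cl <- stats::cutree(tree, h = merge_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order retained clusters by size (desc), tie-break by smallest gene id
  first_gene <- vapply(keep, function(id)
    min(rownames(tom)[cl == as.integer(id)]), "")
  keep <- keep[order(-as.integer(sizes[keep]), first_gene)]
  labels <- rep("unassigned", nrow(tom))
  cols <- module_colors(length(keep))
  for (i in seq_along(keep)) {
    labels[cl == as.integer(keep[i])] <- cols[i]
  }
  names(labels) <- rownames(tom)
  attr(labels, "dendrogram") <- tree
  labels
}

#' Module eigengenes
#'
#' The eigengene (ME) of a module is the first principal component of its
#' standardized log-expression profiles: the per-sample score vector of unit
#' Euclidean norm explaining the most variance across the module's genes.
#' Each ME is sign-oriented so its mean correlation with the module's gene
#' profiles is non-negative.
#'
#' @param expr An [expression_matrix()].
#' @param labels Named gene -> module labels from [detect_modules()];
#'   `"unassigned"` genes are skipped.
#' @param transform Expression transform, `"log1p"` (default) or `"none"`.
#' @return Numeric matrix, samples x modules.
#' @export
module_eigengene <- function(expr, labels, transform = "log1p") {
  stopifnot(inherits(expr, "expression_matrix"))
  logm <- expr_log_matrix(expr, transform)
  modules <- setdiff(unique(labels), "unassigned")
  if (length(modules) == 0) stop("no modules to summarise")
  me <- sapply(modules, function(mod) {
    genes <- names(labels)[labels == mod]
    genes <- genes[!expr$zero_variance[genes]]
    if (length(genes) < 2) stop("singular module '", mod,
                                "': fewer than 2 variable genes")
    z <- t(scale(t(logm[genes, , drop = FALSE])))  # standardize each gene
    sv <- svd(z)
    v1 <- sv$v[, 1]
    orient <- mean(stats::cor(v1, t(logm[genes, , drop = FALSE])))
    if (orient < 0) v1 <- -v1
    v1
  })
  rownames(me) <- colnames(expr$values)
  me
}

#' Module-trait correlation and significant modules
#'
#' Pearson correlation of each module eigengene with the per-sample trait,
#' with two-sided p-values from the correlation t-test
#' (t = r sqrt(n-2)/sqrt(1-r^2)). Modules whose correlation magnitude
#' exceeds `min_abs_cor` (strictly) are the significant, trait-linked
#' modules.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengene()].
#' @param trait Per-sample trait vector (constant traits are an error).
#' @return Data frame with columns `module`, `cor` and `p_value`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (length(trait) != nrow(eigengenes)) {
    stop("trait must have one value per sample")
  }
  if (stats::sd(trait) == 0) stop("constant trait: correlation undefined")
  r <- as.numeric(stats::cor(eigengenes, trait))
  data.frame(module = colnames(eigengenes), cor = r,
             p_value = cor_test_pvalue(r, length(trait)),
             row.names = NULL)
}

#' @rdname module_trait_correlation
#' @param module_trait Data frame from `module_trait_correlation()`.
#' @param min_abs_cor Significance threshold on |cor| (default 0.9).
#' @return `significant_modules()`: character vector of module names with
#'   `|cor| > min_abs_cor`.
#' @export
significant_modules <- function(module_trait, min_abs_cor = 0.9) {
  module_trait$module[abs(module_trait$cor) > min_abs_cor]
}

#' Gene significance and module membership
#'
#' Per-gene trait statistics: gene significance GS_i is the correlation
#' between gene i's (log-scale) expression and the trait; module membership
#' MM_i is the correlation between gene i's expression and the eigengene of
#' its own module. Both are reported signed (`gs_signed`, `mm_signed`) and
#' as magnitudes (`gs`, `mm`), with two-sided correlation-t-test p-values.
#' Zero-variance genes are excluded; unassigned genes have `NA` module
#' membership.
#'
#' @param expr An [expression_matrix()].
#' @param trait Per-sample trait vector.
#' @param labels Named gene -> module labels.
#' @param eigengenes Samples x modules matrix.
#' @param transform Expression transform, `"log1p"` (default) or `"none"`.
#' @return Data frame with one row per (variable) gene: `gene_id`, `module`,
#'   `gs_signed`, `gs`, `p_gs`, `mm_signed`, `mm`, `p_mm`.
#' @export
gene_trait_statistics <- function(expr, trait, labels, eigengenes,
                                  transform = "log1p") {
  stopifnot(inherits(expr, "expression_matrix"))
  if (stats::sd(trait) == 0) stop("constant trait: correlation undefined")
  genes <- usable_genes(expr)
  logm <- expr_log_matrix(expr, transform)[genes, , drop = FALSE]
  n <- ncol(logm)
  gs_signed <- as.numeric(stats::cor(t(logm), trait))
  mm_signed <- rep(NA_real_, length(genes))
  for (mod in colnames(eigengenes)) {
    idx <- which(labels[genes] == mod)
    if (length(idx) > 0) {
      mm_signed[idx] <- as.numeric(
        stats::cor(t(logm[idx, , drop = FALSE]), eigengenes[, mod]))
    }
  }
  data.frame(gene_id = genes,
             module = unname(labels[genes]),
             gs_signed = gs_signed, gs = abs(gs_signed),
             p_gs = cor_test_pvalue(gs_signed, n),
             mm_signed = mm_signed, mm = abs(mm_signed),
             p_mm = ifelse(is.na(mm_signed), NA_real_,
                           cor_test_pvalue(mm_signed, n)),
             row.names = NULL)
}
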