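# Hub-gene screening: per-module edge lists at printed weight thresholds,
# degree computation, 1-D k-means clustering of degree, and the GS/MM filter
# yielding "real" hub genes.

#' Criteria for real-hub-gene screening
#'
#' Bundles the thresholds of the hub screen: per-module edge-weight cutoffs
#' (strict `>`, as printed for each module), the cluster count for the
#' degree k-means, and the inclusive gene significance / module membership
#' cutoffs (`>=`). The defaults are the study's: GS >= 0.95, MM >= 0.98,
#' module-trait |cor| > 0.9.
#'
#' @param edge_weight_threshold Either a single number in \[0, 1\] applied
#'   to every module, or a named numeric vector giving per-module cutoffs
#'   (e.g. `c(tan = 0.4, darkred = 0.3)`); modules without an entry fall
#'   back to the unnamed default of 0.2.
#' @param kmeans_k Cluster count for the degree k-means (>= 2, default 3:
#'   high/medium/low degree).
#' @param gs_min,mm_min Inclusive magnitude cutoffs in \[0, 1\].
#' @param module_trait_min Significant-module threshold on |cor|.
#' @param seed Seed for the k-means restarts.
#' @return An object of class `hub_criteria`.
#' @export
hub_criteria <- function(edge_weight_threshold = 0.2, kmeans_k = 3,
                         gs_min = 0.95, mm_min = 0.98,
                         module_trait_min = 0.9, seed = 1) {
  if (any(edge_weight_threshold < 0 | edge_weight_threshold > 1)) {
    stop("edge weight thresholds must be in [0, 1]")
  }
  if (kmeans_k < 2) stop("kmeans_k must be >= 2")
  for (v in c(gs_min, mm_min, module_trait_min)) {
    if (v < 0 || v > 1) stop("GS/MM/module-trait thresholds must be in [0, 1]")
  }
  structure(list(edge_weight_threshold = edge_weight_threshold,
                 kmeans_k = kmeans_k, gs_min = gs_min, mm_min = mm_min,
                 module_trait_min = module_trait_min, seed = seed),
            class = "hub_criteria")
}

# Per-module edge threshold lookup with unnamed-default fallback.
edge_threshold_for <- function(criteria, module) {
  th <- criteria$edge_weight_threshold
  if (is.null(names(th))) return(th[[1]])
  if (module %in% names(th)) th[[module]] else 0.2
}

#' Within-module edge list above a weight threshold
#'
#' Undirected edges between genes of one module whose network weight is
#' strictly greater than `weight_threshold`, each unordered pair listed
#' once, in lexicographic (gene_a, gene_b) order.
#'
#' @param network Symmetric gene x gene weight matrix (TOM by default
#'   convention, adjacency also valid) with gene ids as dimnames.
#' @param labels Named gene -> module labels.
#' @param module Module name (must exist in `labels`).
#' @param weight_threshold Threshold in \[0, 1\].
#' @return Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
module_edge_list <- function(network, labels, module, weight_threshold) {
  if (!module %in% labels) stop("unknown module: ", module)
  if (weight_threshold < 0 || weight_threshold > 1) {
    stop("weight_threshold must be in [0, 1]")
  }
  genes <- sort(names(labels)[labels == module])
  w <- network[genes, genes, drop = FALSE]
  idx <- which(upper.tri(w) & w > weight_threshold, arr.ind = TRUE)
  out <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                    weight = w[idx])
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree of each module gene in an edge list
#'
#' Number of incident edges per gene; genes isolated at the chosen
#' threshold have degree 0.
#'
#' @param edges Edge list from [module_edge_list()].
#' @param module_genes Character vector of all genes in the module.
#' @return Named integer vector, one entry per module gene.
#' @export
node_degree <- function(edges, module_genes) {
  counts <- table(factor(c(edges$gene_a, edges$gene_b),
                         levels = module_genes))
  stats::setNames(as.integer(counts), module_genes)
}

#' First (highest-degree) cluster of a 1-D k-means on degrees
#'
#' Clusters gene degrees with one-dimensional k-means (seeded, multiple
#' restarts) and returns the genes in the first cluster, defined as the
#' cluster with the highest mean degree. When there are fewer distinct
#' degree values than `k`, `k` is reduced with a warning; with a single
#' distinct value all genes are returned.
#'
#' @param degrees Named numeric vector of degrees.
#' @param k Number of clusters (default 3).
#' @param seed Seed controlling the restarts.
#' @param nstart Number of random restarts (default 10).
#' @return A list with `genes` (sorted ids in the first cluster), `k`
#'   (clusters actually used), `tot_withinss` (k-means objective),
#'   `centers` and `cluster` (full assignment).
#' @export
degree_first_cluster <- function(degrees, k = 3, seed = 1, nstart = 10) {
  if (is.null(names(degrees))) stop("'degrees' must be named by gene")
  n_distinct <- length(unique(degrees))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct degree value(s); reducing k from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  if (k == 1) {
    return(list(genes = sort(names(degrees)), k = 1L,
                tot_withinss = sum((degrees - mean(degrees))^2),
                centers = mean(degrees),
                cluster = stats::setNames(rep(1L, length(degrees)),
                                          names(degrees))))
  }
  km <- with_seed(seed,
                  stats::kmeans(matrix(degrees, ncol = 1), centers = k,
                                nstart = nstart))
  first <- which.max(km$centers)
  list(genes = sort(names(degrees)[km$cluster == first]),
       k = as.integer(k),
       tot_withinss = km$tot.withinss,
       centers = as.numeric(km$centers),
       cluster = stats::setNames(km$cluster, names(degrees)))
}

#' Screen significant modules for real hub genes
#'
#' Applies the full hub screen to every significant module (module-trait
#' correlation magnitude above `criteria$module_trait_min`): build the
#' module's edge list at its weight threshold, compute degrees, cluster the
#' degrees with 1-D k-means and keep the first (highest-degree) cluster,
#' then require gene significance `|GS| >= gs_min` and module membership
#' `|MM| >= mm_min`. Genes passing all three are the real hub genes; the
#' report records each criterion separately so alternative readings of the
#' screen can be recovered.
#'
#' @param network Symmetric gene x gene weight matrix (TOM recommended).
#' @param labels Named gene -> module labels.
#' @param stats_df Gene statistics from [gene_trait_statistics()].
#' @param module_trait Data frame from [module_trait_correlation()].
#' @param criteria A [hub_criteria()].
#' @return Data frame of class `hub_report`, one row per gene of each
#'   significant module: `gene_id`, `module`, `degree`, `gs`, `mm`,
#'   `in_first_cluster`, `pass_gs`, `pass_mm`, `is_hub`.
#' @export
real_hub_genes <- function(network, labels, stats_df, module_trait,
                           criteria = hub_criteria()) {
  stopifnot(inherits(criteria, "hub_criteria"))
  sig <- significant_modules(module_trait, criteria$module_trait_min)
  reports <- lapply(sig, function(mod) {
    thr <- edge_threshold_for(criteria, mod)
    genes <- sort(names(labels)[labels == mod])
    edges <- module_edge_list(network, labels, mod, thr)
    if (nrow(edges) == 0) {
      warning("module '", mod, "' has no edges above its weight threshold ",
              thr, "; empty hub set")
    }
    deg <- node_degree(edges, genes)
    fc <- if (nrow(edges) == 0) character(0) else {
      degree_first_cluster(deg, k = criteria$kmeans_k,
                           seed = criteria$seed)$genes
    }
    st <- stats_df[match(genes, stats_df$gene_id), , drop = FALSE]
    data.frame(gene_id = genes, module = mod, degree = as.integer(deg),
               gs = st$gs, mm = st$mm,
               in_first_cluster = genes %in% fc,
               pass_gs = !is.na(st$gs) & st$gs >= criteria$gs_min,
               pass_mm = !is.na(st$mm) & st$mm >= criteria$mm_min,
               row.names = NULL)
  })
  out <- do.call(rbind, reports)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), module = character(0),
                      degree = integer(0), gs = numeric(0), mm = numeric(0),
                      in_first_cluster = logical(0), pass_gs = logical(0),
                      pass_mm = logical(0))
  }
  out$is_hub <- out$in_first_cluster & out$pass_gs & out$pass_mm
  structure(out, class = c("hub_report", "data.frame"))
}

#' Export an edge list as a 3-column TSV
#'
#' Writes `source`, `target`, `weight` columns, loadable by generic network
#' visualisation tools; rows keep the edge list's stable ordering and an
#' empty edge list produces a header-only file.
#'
#' @param edges Edge list from [module_edge_list()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_edges_tsv <- function(edges, path) {
  out <- data.frame(source = edges$gene_a, target = edges$gene_b,
                    weight = edges$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
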