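make_network <- function(n, fill = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  w
}

test_that("module edge lists are thresholded, deduplicated and ordered", {
  w <- make_network(6)
  labels <- setNames(c(rep("tan", 4), "blue", "blue"), rownames(w))
  all_edges <- module_edge_list(w, labels, "tan", 0)
  expect_equal(nrow(all_edges), 6)  # complete graph on 4 genes
  expect_true(all(all_edges$gene_a < all_edges$gene_b))
  expect_equal(nrow(module_edge_list(w, labels, "tan", 1)), 0)
  expect_error(module_edge_list(w, labels, "violet", 0.2), "unknown module")

  # brute-force pair scan on a random 20-gene module
  w20 <- make_network(20, seed = 9)
  lab20 <- setNames(rep("m", 20), rownames(w20))
  thr <- 0.6
  edges <- module_edge_list(w20, lab20, "m", thr)
  count <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    if (w20[i, j] > thr) count <- count + 1
  }
  expect_equal(nrow(edges), count)
  expect_true(all(edges$weight > thr))  # strictly greater, as printed
})

test_that("degrees count incident edges, satisfying the handshake lemma", {
  star <- data.frame(gene_a = rep("hub", 4),
                     gene_b = paste0("leaf", 1:4),
                     weight = 0.9)
  deg <- node_degree(star, c("hub", paste0("leaf", 1:4)))
  expect_equal(unname(deg["hub"]), 4)
  expect_true(all(deg[paste0("leaf", 1:4)] == 1))

  none <- module_edge_list(make_network(5),
                           setNames(rep("m", 5), sprintf("g%03d", 1:5)),
                           "m", 1)
  expect_true(all(node_degree(none, sprintf("g%03d", 1:5)) == 0))

  for (s in 1:5) {
    w <- make_network(15, seed = s)
    lab <- setNames(rep("m", 15), rownames(w))
    edges <- module_edge_list(w, lab, "m", 0.5)
    expect_equal(sum(node_degree(edges, rownames(w))), 2 * nrow(edges))
  }
})

test_that("the first degree cluster is the highest-degree group", {
  deg <- setNames(c(10, 10, 9, 1, 1, 0), paste0("g", 1:6))
  fc <- degree_first_cluster(deg, k = 2, seed = 1)
  expect_setequal(fc$genes, c("g1", "g2", "g3"))

  expect_warning(all_eq <- degree_first_cluster(
    setNames(rep(3, 5), paste0("g", 1:5)), k = 2, seed = 1),
    "reducing k")
  expect_setequal(all_eq$genes, paste0("g", 1:5))
  expect_equal(all_eq$k, 1L)
})

test_that("seeded 1-D k-means attains the exhaustive-partition optimum", {
  set.seed(11)
  for (case in 1:5) {
    x <- setNames(round(c(rnorm(5, 50, 5), rnorm(6, 20, 4), rnorm(4, 3, 2))),
                  sprintf("g%02d", 1:15))
    km <- degree_first_cluster(x, k = 3, seed = case)
    expect_equal(km$tot_withinss, kmeans_1d_optimal(x, 3), tolerance = 1e-9)
    # reproducible for a fixed seed
    km2 <- degree_first_cluster(x, k = 3, seed = case)
    expect_identical(km$genes, km2$genes)
  }
})

test_that("hub screen combines degree cluster with GS/MM cutoffs monotonely", {
  x <- simulate_expression(expression_sim_config(seed = 2))
  tom <- topological_overlap(adjacency(x, 26))
  labels <- detect_modules(tom, 30, 0.9)
  me <- module_eigengene(x, labels)
  mt <- module_trait_correlation(me, x$trait)
  st <- gene_trait_statistics(x, x$trait, labels, me)
  sig <- significant_modules(mt, 0.9)
  thr <- sapply(sig, function(m) {
    w <- tom[names(labels)[labels == m], names(labels)[labels == m]]
    as.numeric(stats::quantile(w[upper.tri(w)], 0.9))
  })
  base <- hub_criteria(thr, kmeans_k = 3, gs_min = 0.85, mm_min = 0.985,
                       module_trait_min = 0.9, seed = 2)
  rep1 <- real_hub_genes(tom, labels, st, mt, base)
  expect_true(any(rep1$is_hub))
  expect_true(all(rep1$is_hub ==
                    (rep1$in_first_cluster & rep1$pass_gs & rep1$pass_mm)))
  # raising any cutoff never enlarges the hub set
  for (crit2 in list(hub_criteria(thr, 3, gs_min = 0.99, mm_min = 0.985,
                                  module_trait_min = 0.9, seed = 2),
                     hub_criteria(thr, 3, gs_min = 0.85, mm_min = 0.999,
                                  module_trait_min = 0.9, seed = 2),
                     hub_criteria(pmin(thr + 0.1, 1), 3, gs_min = 0.85,
                                  mm_min = 0.985, module_trait_min = 0.9,
                                  seed = 2))) {
    rep2 <- suppressWarnings(real_hub_genes(tom, labels, st, mt, crit2))
    expect_true(all(rep2$gene_id[rep2$is_hub] %in% rep1$gene_id[rep1$is_hub]))
  }
  # hub expression correlates with the trait by construction
  expect_true(all(rep1$gs[rep1$is_hub] >= 0.85))

  # module with no edges above threshold: empty hub set with a warning
  starved <- hub_criteria(1, 3, 0, 0, 0.9, seed = 2)
  msgs <- testthat::capture_warnings(
    rep3 <- real_hub_genes(tom, labels, st, mt, starved))
  expect_true(any(grepl("no edges", msgs)))  # one warning per starved module
  expect_false(any(rep3$is_hub))
})

test_that("edge TSV export writes stable three-column files", {
  w <- make_network(6)
  labels <- setNames(rep("m", 6), rownames(w))
  edges <- module_edge_list(w, labels, "m", 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_edges_tsv(edges, path)
  lines <- readLines(path)
  expect_equal(lines[1], "source\ttarget\tweight")
  expect_equal(length(lines), nrow(edges) + 1)
  back <- utils::read.delim(path)
  expect_equal(back$weight, edges$weight, tolerance = 1e-6)

  empty <- module_edge_list(w, labels, "m", 1)
  export_edges_tsv(empty, path)
  expect_equal(readLines(path), "source\ttarget\tweight")
})

test_that("hub criteria validate their thresholds", {
  expect_error(hub_criteria(edge_weight_threshold = 1.2), "\\[0, 1\\]")
  expect_error(hub_criteria(kmeans_k = 1), "kmeans_k")
  expect_error(hub_criteria(gs_min = -0.1), "\\[0, 1\\]")
})
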