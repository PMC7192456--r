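test_that("soft-threshold selection reaches scale-free fit on planted data", {
  # heavy-tailed connectivity: module sizes decaying roughly geometrically
  # and wide loading spread give an approximately power-law degree profile
  cfg <- expression_sim_config(
    n_genes = 1000, module_sizes = c(200, 100, 70, 50, 40, 35, 30, 30),
    module_trait_r = rep(0, 8), n_hubs = 2,
    loading_range = c(0.3, 0.95), noise_sd = 0.3, seed = 1)
  x <- simulate_expression(cfg)
  sft <- pick_soft_threshold(x, powers = 1:20)
  chosen <- sft$table[sft$table$power == sft$beta, ]
  expect_gte(chosen$scale_free_r2, 0.85)
  # connectivity shrinks monotonically with the power
  expect_true(all(diff(sft$table$mean_connectivity) < 0))

  tiny <- make_expr(matrix(runif(10), nrow = 2), trait = 1:5)
  expect_error(pick_soft_threshold(tiny), "too few genes")
})

test_that("adjacency is |cor|^beta with unit weights for identical profiles", {
  set.seed(3)
  base <- matrix(exp(rnorm(5 * 9, 2)), nrow = 5)
  vals <- rbind(base, base[1, , drop = FALSE] * 2)  # gene 6 tracks gene 1
  x <- make_expr(vals, trait = rep(1:3, each = 3))
  for (beta in c(1, 6, 26)) {
    a <- adjacency(x, beta, transform = "none")
    expect_equal(unname(a["g001", "g006"]), 1, tolerance = 1e-12)
    expect_true(all(diag(a) == 0))
    expect_true(isSymmetric(a))
    expect_true(all(a >= 0 & a <= 1))
  }
  # independent noise at beta = 26: off-diagonal weights crushed
  set.seed(4)
  noise <- make_expr(matrix(exp(rnorm(40 * 9)), nrow = 40),
                     trait = rep(1:3, each = 3))
  a26 <- adjacency(noise, 26)
  off <- a26[upper.tri(a26)]
  # with 9 samples occasional chance correlations survive, but the bulk of
  # the network is annihilated by the high power
  expect_lt(stats::median(off), 1e-6)
  expect_lt(mean(off), 0.005)
})

test_that("topological overlap equals the brute-force triple loop", {
  set.seed(7)
  a <- matrix(runif(144), 12, 12)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  tom <- topological_overlap(a)
  expect_lt(max(abs(tom - tom_brute_force(a))), 1e-9)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("block-diagonal similarity yields exact module recovery", {
  n <- 100
  a <- matrix(0, n, n)
  a[1:50, 1:50] <- 0.6
  a[51:100, 51:100] <- 0.6
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tom <- topological_overlap(a)
  labels <- detect_modules(tom, min_module_size = 30, merge_height = 0.5)
  expect_equal(sort(unique(labels)), c("blue", "turquoise"))
  expect_length(unique(labels[1:50]), 1)
  expect_length(unique(labels[51:100]), 1)

  # a 10-gene block below the minimum size stays unassigned
  b <- matrix(0, 60, 60)
  b[1:50, 1:50] <- 0.6
  b[51:60, 51:60] <- 0.6
  diag(b) <- 0
  dimnames(b) <- list(sprintf("g%03d", 1:60), sprintf("g%03d", 1:60))
  lab2 <- detect_modules(topological_overlap(b), 30, 0.5)
  expect_true(all(lab2[51:60] == "unassigned"))
  expect_true(all(lab2[1:50] == "turquoise"))
})

test_that("module detection is invariant to gene input order", {
  x <- simulate_expression(expression_sim_config(
    n_genes = 120, module_sizes = c(40, 30), module_trait_r = c(0.95, 0),
    n_hubs = 3, seed = 21))
  tom <- topological_overlap(adjacency(x, 12))
  lab1 <- detect_modules(tom, 10, 0.95)
  set.seed(1)
  perm <- sample(nrow(tom))
  lab2 <- detect_modules(tom[perm, perm], 10, 0.95)
  expect_identical(lab1[sort(names(lab1))],
                   lab2[sort(names(lab2))])
  expect_error(detect_modules(tom, min_module_size = 1), "config error")
})

test_that("eigengenes are unit-norm dominant components, sign-oriented", {
  x <- simulate_expression(expression_sim_config(
    n_genes = 120, module_sizes = c(40, 30), module_trait_r = c(0.95, 0),
    n_hubs = 3, seed = 31))
  me <- module_eigengene(x, x$true_modules)
  logm <- log1p(x$values)
  for (mod in colnames(me)) {
    v <- me[, mod]
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    genes <- names(x$true_modules)[x$true_modules == mod]
    expect_gte(mean(stats::cor(v, t(logm[genes, ]))), 0)
    # Rayleigh check: the ME explains at least as much standardized module
    # variance as any of 1000 random unit vectors
    z <- t(scale(t(logm[genes, ])))
    me_var <- sum((z %*% v)^2)
    set.seed(5)
    for (i in 1:1000) {
      u <- rnorm(length(v)); u <- u / sqrt(sum(u^2))
      expect_lte(sum((z %*% u)^2), me_var + 1e-8)
    }
  }
  # rank-1 module: ME carries the shared profile (up to affine scaling),
  # and the orientation convention makes the correlation +1, not -1
  prof <- exp(c(1, 5, 2, 4, 3, 6, 2.5, 4.5, 3.5))
  vals <- matrix(c(prof, 2 * prof, 3 * prof), nrow = 3, byrow = TRUE)
  x1 <- make_expr(vals, trait = 1:9)
  me1 <- module_eigengene(x1, setNames(rep("m", 3), rownames(x1$values)),
                          transform = "none")
  expect_equal(as.numeric(stats::cor(me1[, 1], prof)), 1, tolerance = 1e-9)
})

test_that("module-trait correlation flags exactly the strong modules", {
  trait <- c(5, 7, 9, 55, 60, 65, 92, 95, 98)
  me <- cbind(hit = scale(trait)[, 1] / sqrt(8),
              null = rep(c(-1, 1), length.out = 9) / 3)
  mt <- module_trait_correlation(me, trait)
  expect_equal(mt$cor[mt$module == "hit"], 1, tolerance = 1e-12)
  expect_identical(significant_modules(mt, 0.9), "hit")
  expect_length(significant_modules(mt, 1), 0)
  expect_error(module_trait_correlation(me, rep(1, 9)), "constant trait")
  # p-values match the closed-form correlation t-test (7 df at n = 9)
  ct <- stats::cor.test(me[, "null"], trait)
  expect_equal(mt$p_value[mt$module == "null"], ct$p.value, tolerance = 1e-12)
})

test_that("gene significance and module membership are plain correlations", {
  x <- simulate_expression(expression_sim_config(
    n_genes = 100, module_sizes = c(30, 30), module_trait_r = c(0.95, 0),
    n_hubs = 3, seed = 41))
  labels <- replace(x$true_modules, x$true_modules == "background",
                    "unassigned")
  me <- module_eigengene(x, labels)
  st <- gene_trait_statistics(x, x$trait, labels, me)
  logm <- log1p(x$values)
  set.seed(6)
  for (g in sample(st$gene_id, 50)) {
    row <- st[st$gene_id == g, ]
    expect_equal(row$gs_signed, stats::cor(logm[g, ], x$trait),
                 tolerance = 1e-12)
    if (row$module != "unassigned") {
      expect_equal(row$mm_signed, stats::cor(logm[g, ], me[, row$module]),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(row$mm))
    }
    expect_equal(row$p_gs,
                 stats::cor.test(logm[g, ], x$trait)$p.value,
                 tolerance = 1e-9)
  }
  expect_true(all(st$gs >= 0 & st$gs <= 1))
})
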