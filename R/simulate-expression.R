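#' Configuration for the expression-matrix simulator
#'
#' Defines a planted-module generating process for synthetic FPKM matrices
#' emulating the study layout: 9 samples (3 dormancy states x 3 replicates)
#' scored by a sprouting-percentage trait, a few thousand genes, a handful of
#' block-correlated modules, some of them strongly trait-linked.
#'
#' Each module m has a latent per-sample profile constructed to have an
#' exact sample Pearson correlation `module_trait_r[m]` with the trait
#' (modules with r = 0 get a latent exactly orthogonal to the trait). Module
#' genes are generated on the log scale as
#' `baseline + loading x latent + noise` and exponentiated to FPKM, so
#' values are non-negative and within-module correlation structure is
#' approximately linear on the log scale. The first `n_hubs` genes of each
#' module are engineered hubs: maximal loading and reduced noise, giving
#' them the highest connectivity, module membership and trait correlation in
#' their module. Background genes are independent noise.
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Planted module sizes; their sum must not exceed
#'   `n_genes` (the remainder are background genes).
#' @param trait Per-sample trait (sprouting percentage). The default mimics
#'   endo-, eco- and nondormant buds in triplicate.
#' @param module_trait_r Latent-trait correlation per module, in \[-1, 1\].
#' @param n_hubs Engineered hub genes per module.
#' @param hub_loading,hub_noise_sd Loading and log-scale noise sd for hubs.
#' @param hub_min_baseline Floor on hub baseline log-FPKM. Planted hubs are
#'   kept well-expressed: near-zero FPKM values are compressed by the log1p
#'   transform used downstream, which would blur a low-expressed hub's
#'   profile and make the planted truth ambiguous.
#' @param loading_range Range of uniform loadings for non-hub module genes.
#' @param noise_sd Log-scale noise sd for non-hub and background genes.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log-FPKM
#'   distribution.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(
    n_genes = 1000,
    module_sizes = c(80, 70, 60, 50, 45, 40),
    trait = stats::setNames(c(5, 7, 9, 55, 60, 65, 92, 95, 98),
                            paste0(rep(c("endo", "eco", "non"), each = 3),
                                   "_", 1:3)),
    module_trait_r = c(0.95, -0.95, 0, 0, 0, 0),
    n_hubs = 5, hub_loading = 1, hub_noise_sd = 0.02, hub_min_baseline = 3,
    loading_range = c(0.6, 0.78), noise_sd = 0.22,
    baseline_log_mean = 3, baseline_log_sd = 1.5,
    seed = 1) {
  if (sum(module_sizes) > n_genes) {
    stop("config error: module sizes exceed the number of genes")
  }
  if (length(module_trait_r) != length(module_sizes)) {
    stop("config error: one trait correlation needed per module")
  }
  if (any(abs(module_trait_r) > 1)) stop("config error: |r| must be <= 1")
  if (any(module_sizes < n_hubs)) {
    stop("config error: modules must hold at least n_hubs genes")
  }
  if (length(trait) < 4) stop("config error: need at least 4 samples")
  if (stats::sd(trait) == 0) stop("config error: trait must vary")
  structure(list(n_genes = n_genes, module_sizes = module_sizes,
                 trait = trait, module_trait_r = module_trait_r,
                 n_hubs = n_hubs, hub_loading = hub_loading,
                 hub_noise_sd = hub_noise_sd,
                 hub_min_baseline = hub_min_baseline,
                 loading_range = loading_range, noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, seed = seed),
            class = "expression_sim_config")
}

# Centered unit vector orthogonal to the centered unit vector u.
rand_orthogonal <- function(u) {
  n <- length(u)
  repeat {
    e <- stats::rnorm(n)
    e <- e - mean(e)
    e <- e - u * sum(e * u)
    if (sum(e^2) > 1e-12) break
  }
  e / sqrt(sum(e^2))
}

# Latent per-sample profile with exact sample correlation r to trait.
# u = centered unit trait direction, v = centered unit vector orthogonal to
# u; latent = r u + sqrt(1 - r^2) v has empirical cor(latent, trait) == r.
# v may be supplied (with sign) so that distinct trait-linked modules can
# share an anti-aligned residual direction: two latents with |r| = 0.95 to
# the same trait are never less correlated than 2 r^2 - 1 in magnitude, and
# sharing v attains that lower bound, keeping planted modules maximally
# distinguishable.
make_latent <- function(trait, r, v = NULL) {
  u <- trait - mean(trait)
  u <- u / sqrt(sum(u^2))
  if (is.null(v)) v <- rand_orthogonal(u)
  z <- r * u + sqrt(1 - r^2) * v
  z / stats::sd(z)  # unit sample sd; rescaling preserves correlations
}

#' Simulate an expression matrix with planted trait-linked modules
#'
#' Draws one FPKM matrix under the process described in
#' [expression_sim_config()]. The returned object carries the simulation
#' ground truth: `true_modules` (named gene -> "M1".."Mk" or "background")
#' and `true_hubs` (character vector of engineered hub gene ids), for use in
#' recovery tests.
#'
#' @param config An [expression_sim_config()].
#' @return An [expression_matrix()] with extra fields `true_modules` and
#'   `true_hubs`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    n <- length(config$trait)
    g <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    baseline <- stats::rnorm(g, config$baseline_log_mean, config$baseline_log_sd)
    logx <- matrix(stats::rnorm(g * n, 0, config$noise_sd), nrow = g)
    true_modules <- rep("background", g)
    true_hubs <- character(0)
    offset <- 0L
    # trait-linked modules share one residual direction with alternating
    # sign chosen to minimise their pairwise latent correlations (see
    # make_latent); null modules get independent random directions
    u <- config$trait - mean(config$trait)
    u <- u / sqrt(sum(u^2))
    w <- rand_orthogonal(u)
    linked <- which(config$module_trait_r != 0)
    v_sign <- stats::setNames(numeric(0), character(0))
    for (m in linked) {
      if (length(v_sign) == 0) {
        v_sign[as.character(m)] <- 1
      } else {
        r_m <- config$module_trait_r[m]
        s_m <- sqrt(1 - r_m^2)
        worst <- sapply(c(1, -1), function(cc) {
          prev <- as.integer(names(v_sign))
          max(abs(config$module_trait_r[prev] * r_m +
                    sqrt(1 - config$module_trait_r[prev]^2) * s_m *
                    v_sign[as.character(prev)] * cc))
        })
        v_sign[as.character(m)] <- c(1, -1)[which.min(worst)]
      }
    }
    for (m in seq_along(config$module_sizes)) {
      size <- config$module_sizes[m]
      idx <- offset + seq_len(size)
      offset <- offset + size
      v_m <- if (m %in% linked) v_sign[as.character(m)] * w else NULL
      latent <- make_latent(config$trait, config$module_trait_r[m], v_m)
      loading <- stats::runif(size, config$loading_range[1],
                              config$loading_range[2])
      hub_idx <- seq_len(config$n_hubs)
      loading[hub_idx] <- config$hub_loading
      baseline[idx[hub_idx]] <- pmax(baseline[idx[hub_idx]],
                                     config$hub_min_baseline)
      noise <- matrix(stats::rnorm(size * n, 0, config$noise_sd), nrow = size)
      noise[hub_idx, ] <- matrix(
        stats::rnorm(config$n_hubs * n, 0, config$hub_noise_sd),
        nrow = config$n_hubs)
      logx[idx, ] <- loading %o% latent + noise
      true_modules[idx] <- paste0("M", m)
      true_hubs <- c(true_hubs, gene_ids[idx[hub_idx]])
    }
    values <- exp(sweep(logx, 1, baseline, `+`))
    dimnames(values) <- list(gene_ids, names(config$trait))
    out <- expression_matrix(values, config$trait)
    out$true_modules <- stats::setNames(true_modules, gene_ids)
    out$true_hubs <- true_hubs
    out
  })
}
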