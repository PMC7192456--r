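# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force, exhaustive enumeration, closed form) kept
# separate from the package's own code paths.

# O(n^3) triple-loop topological overlap.
tom_brute_force <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
      } else {
        l <- 0
        for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
    }
  }
  tom
}

# Exact 1-D k-means via dynamic programming over contiguous partitions of
# the sorted values (contiguity is optimal in one dimension). Returns the
# minimal total within-cluster sum of squares.
kmeans_1d_optimal <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in seq_len(n)) dp[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        for (i in m:j) {
          cand <- dp[m - 1, i - 1] + seg_cost(i, j)
          if (cand < best) best <- cand
        }
        dp[m, j] <- best
      }
    }
  }
  dp[k, n]
}

# Build a sprouting experiment whose curves are exact straight lines:
# pct(day) = slope * day over days 1..n_days, one replicate.
linear_experiment <- function(slopes_by_temp, n_days = 5, n_buds = 25000) {
  rows <- lapply(names(slopes_by_temp), function(tt) {
    slope <- slopes_by_temp[[tt]]
    data.frame(temperature = as.numeric(tt), chilling_days = 30,
               replicate = 1, n_buds = n_buds, day = seq_len(n_days),
               sprouted = round(n_buds * slope * seq_len(n_days) / 100))
  })
  sprouting_experiment(do.call(rbind, rows))
}

# Single response curve object from raw percentages.
make_curve <- function(pct, day = seq_along(pct), temperature = 0,
                       chilling_days = 30) {
  structure(list(temperature = temperature, chilling_days = chilling_days,
                 day = day, sprouting_pct = pct),
            class = "chill_response_curve")
}

# Small expression matrix from an explicit numeric matrix.
make_expr <- function(values, trait) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  expression_matrix(values, trait)
}

paper_cu_model <- function() chill_unit_model(-0.0154, 0.0916, 0.9926)
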