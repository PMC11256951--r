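# Shared fixtures and independent oracles used across test files.

# Brute-force oracle for the weighted simplex projection: enumerate every
# support set, solve the equality-constrained problem on it, keep the
# feasible candidates, and return the one with the smallest objective
# 1/2 * sum(d x^2) - sum(n x). Independent of the sort-based route.
oracle_project <- function(n, d) {
  m <- length(n)
  best_x <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    beta <- (sum(n[S] / d[S]) - 1) / sum(1 / d[S])
    x <- numeric(m)
    x[S] <- (n[S] - beta) / d[S]
    if (any(x[S] < -1e-12)) next
    x <- pmax(0, x)
    obj <- 0.5 * sum(d * x^2) - sum(n * x)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best_x <- x / sum(x)
    }
  }
  best_x
}

# Term-by-term oracle for the augmented Lagrangian, written with scalar
# loops rather than matrix algebra.
oracle_lagrangian <- function(state, problem, rho) {
  N <- problem$N
  Kp1 <- problem$K + 1L
  fit <- 0
  for (i in seq_len(N)) {
    wh <- 0
    for (j in seq_len(Kp1)) wh <- wh + state$W[i, j] * state$H[j]
    fit <- fit + (problem$X[i] - wh)^2
  }
  anchor <- 0
  inner_W <- 0
  quad_W <- 0
  for (i in seq_len(N)) for (j in seq_len(Kp1)) {
    anchor <- anchor +
      (problem$A[i, j] * (state$W_plus[i, j] - problem$Y[i, j]))^2
    dw <- state$W[i, j] - state$W_plus[i, j]
    inner_W <- inner_W + state$alpha_W[i, j] * dw
    quad_W <- quad_W + dw^2
  }
  inner_H <- 0
  quad_H <- 0
  for (j in seq_len(Kp1)) {
    dh <- state$H[j] - state$H_plus[j]
    inner_H <- inner_H + state$alpha_H[j] * dh
    quad_H <- quad_H + dh^2
  }
  0.5 * fit + 0.5 * anchor + inner_W + rho / 2 * quad_W +
    inner_H + rho / 2 * quad_H
}

# A small pool of sparse, well-separated profiles plus an exact mixture
# sink; used by solver and recovery tests.
make_mixture <- function(seed, n_taxa = 500L, K = 10L, sparsity = 0.1) {
  pool <- synth_source_pool(n_taxa = n_taxa, n_sources = K + 2L,
                            sparsity = sparsity, seed = seed)
  S <- pool$profiles[, seq_len(K), drop = FALSE]
  set.seed(seed + 10000L)
  g <- runif(K)
  h <- g / sum(g)
  list(S = S, h = h, x = drop(S %*% h))
}

# Write a taxa-by-sample matrix as the TSV dialect the readers expect.
write_fixture_tsv <- function(m, path, id_col = "TaxonID") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random point on the k-simplex.
rsimplex <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}
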