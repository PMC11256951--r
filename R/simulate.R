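#' Synthesize a pool of sparse source profiles
#'
#' Generates a pool of column-normalized taxa profiles emulating
#' environmental survey data (Earth-Microbiome-Project-like): each
#' source occupies a small random subset of the global taxon set
#' (`sparsity` fraction), with relative abundances on that support drawn
#' from a symmetric Dirichlet. Small supports with low overlap give the
#' high pairwise Jensen-Shannon divergences typical of unrelated
#' environmental communities; larger `sparsity` or `concentration`
#' yields more similar, more even profiles.
#'
#' @param n_taxa Total number of taxa (default 2000).
#' @param n_sources Number of sources in the pool (default 200).
#' @param sparsity Fraction of taxa present per source, in (0, 1]
#'   (default 0.05, i.e. about 100 of 2000 taxa, mirroring the roughly
#'   700-in-53000 occupancy of large environmental surveys).
#' @param concentration Symmetric Dirichlet concentration for the
#'   nonzero abundances (default 1).
#' @param seed Integer seed; the pool is deterministic given it.
#' @return List of class `source_pool`: `profiles` (taxa x sources,
#'   unit column sums), `taxon_ids`, `source_ids`.
#' @export
synth_source_pool <- function(n_taxa = 2000L, n_sources = 200L,
                              sparsity = 0.05, concentration = 1,
                              seed = 1L) {
  stopifnot(n_taxa >= 1L, n_sources >= 2L, sparsity > 0, sparsity <= 1,
            concentration > 0)
  support <- max(1L, round(sparsity * n_taxa))
  if (sparsity * n_taxa < 1) stop("sparsity * n_taxa < 1", call. = FALSE)
  set.seed(seed)
  profiles <- matrix(0, n_taxa, n_sources)
  for (j in seq_len(n_sources)) {
    idx <- sample.int(n_taxa, support)
    g <- stats::rgamma(support, shape = concentration)
    profiles[idx, j] <- g / sum(g)
  }
  taxon_ids <- sprintf("taxon%04d", seq_len(n_taxa))
  source_ids <- sprintf("pool%03d", seq_len(n_sources))
  dimnames(profiles) <- list(taxon_ids, source_ids)
  structure(list(profiles = profiles, taxon_ids = taxon_ids,
                 source_ids = source_ids),
            class = "source_pool")
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' @param profiles Column-normalized taxa-by-source matrix.
#' @param ... Passed to [jsd()].
#' @return Symmetric matrix of pairwise JSD values with zero diagonal.
#' @export
pairwise_jsd <- function(profiles, ...) {
  m <- ncol(profiles)
  out <- matrix(0, m, m, dimnames = list(colnames(profiles),
                                         colnames(profiles)))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      out[i, j] <- out[j, i] <- jsd(profiles[, i], profiles[, j], ...)
    }
  }
  out
}

#' Greedily select a source set with a target inter-source divergence
#'
#' Reproduces the heuristic used to build benchmark source sets of a
#' prescribed average pairwise divergence: among all source pairs whose
#' JSD falls inside the window `target_jsd +/- jsd_window`, the source
#' participating in the most in-window pairs seeds the set; the set then
#' grows by repeatedly adding the most pair-frequent source whose JSD to
#' every selected source is in-window. When no candidate remains, the
#' window is relaxed by 0.05 on both sides and the scan resumes, up to
#' the full JSD range.
#'
#' @param pool A `source_pool` (or any list with a column-normalized
#'   `profiles` matrix).
#' @param target_jsd Desired mean pairwise JSD.
#' @param jsd_window Half-width of the acceptance window (default 0.05).
#' @param set_size Number of sources to select.
#' @return Character vector of `set_size` source ids; the achieved
#'   window half-width is attached as attribute `window`.
#' @export
select_source_set <- function(pool, target_jsd, jsd_window = 0.05,
                              set_size = 20L) {
  profiles <- pool$profiles
  m <- ncol(profiles)
  if (m < set_size) stop("pool smaller than requested set", call. = FALSE)
  J <- pairwise_jsd(profiles)
  full <- max(J) - min(J[upper.tri(J)])
  w <- jsd_window
  repeat {
    inw <- abs(J - target_jsd) <= w
    diag(inw) <- FALSE
    freq <- rowSums(inw)
    selected <- which.max(freq)
    while (length(selected) < set_size) {
      ok <- which(apply(inw[, selected, drop = FALSE], 1L, all))
      ok <- setdiff(ok, selected)
      if (!length(ok)) break
      selected <- c(selected, ok[which.max(freq[ok])])
    }
    if (length(selected) >= set_size) break
    if (w >= max(1, full)) {
      stop("no source set attains the requested divergence even after ",
           "window relaxation", call. = FALSE)
    }
    w <- w + 0.05
  }
  ids <- colnames(profiles)[selected]
  attr(ids, "window") <- w
  ids
}

#' Benchmark mixture design
#'
#' Bundles the parameters of the simulated source-tracking benchmarks.
#'
#' @param K Number of reference (observed) sources.
#' @param U Number of unknown sources (unobserved contributors).
#' @param F Number of irrelevant sources (references with true
#'   proportion zero); in the noise-free design these are a subset of
#'   the K references, in the noisy design extra singleton references.
#' @param unknown_total Total true proportion of the U unknown sources,
#'   in \[0, 1\] (default 0.5).
#' @param pareto_shape Shape of the Pareto distribution generating the
#'   random mixing proportions (default 3; moderately skewed).
#' @param depth Multinomial sequencing depth for observed reference
#'   profiles (default 10000 counts).
#' @param exact_profile If `TRUE`, skip multinomial observation noise
#'   and expose the true profiles as observed (infinite-depth
#'   surrogate for closed-loop checks).
#' @param seed Integer seed.
#' @return List of class `mixture_design`.
#' @export
mixture_design <- function(K = 15L, U = 5L, F = 5L, unknown_total = 0.5,
                           pareto_shape = 3, depth = 10000L,
                           exact_profile = FALSE, seed = 1L) {
  stopifnot(K >= 1L, U >= 0L, F >= 0L, F <= K,
            unknown_total >= 0, unknown_total <= 1,
            pareto_shape > 0, depth >= 1)
  if (U == 0L && unknown_total > 0) {
    stop("unknown_total > 0 requires U >= 1", call. = FALSE)
  }
  structure(list(K = as.integer(K), U = as.integer(U), F = as.integer(F),
                 unknown_total = unknown_total,
                 pareto_shape = pareto_shape, depth = as.integer(depth),
                 exact_profile = exact_profile, seed = seed),
            class = "mixture_design")
}

# Pareto(1, shape) draws by inverse CDF.
rpareto <- function(n, shape) stats::runif(n)^(-1 / shape)

# Multinomial observation of a profile at given depth, renormalized.
observe_profile <- function(profile, depth, exact = FALSE) {
  if (exact) return(profile / sum(profile))
  counts <- stats::rmultinom(1L, depth, profile)[, 1L]
  counts / sum(counts)
}

# Draw the true mixing proportions: zeros for irrelevant entries,
# Pareto-normalized masses for contributing references (to
# 1 - unknown_total) and unknown sources (to unknown_total).
draw_proportions <- function(K, U, irrelevant, unknown_total, shape) {
  p <- numeric(K + U)
  contrib <- setdiff(seq_len(K), irrelevant)
  if (length(contrib) == 0L && unknown_total < 1) {
    stop("all references irrelevant but unknown_total < 1", call. = FALSE)
  }
  if (length(contrib)) {
    g <- rpareto(length(contrib), shape)
    p[contrib] <- g / sum(g) * (1 - unknown_total)
  }
  if (U > 0L) {
    g <- rpareto(U, shape)
    p[K + seq_len(U)] <- g / sum(g) * unknown_total
  }
  p
}

#' Generate a noise-free benchmark instance
#'
#' The first benchmark design: K + U true source profiles are taken
#' from the pool subset; F randomly chosen references are designated
#' irrelevant (zero proportion); the remaining proportions are Pareto
#' draws normalized so the U unknown entries total `unknown_total`; the
#' sink is the exact mixture of the true profiles; the observed
#' reference profiles are multinomial resamples of the true profiles at
#' the design depth (the unknown sources are never observed).
#'
#' @param pool_subset A `source_pool` (or compatible list) whose
#'   `profiles` has exactly `K + U` columns: the first K are the
#'   references, the final U the unknown sources.
#' @param design A [mixture_design()].
#' @return List of class `simulation_truth`: `true_profiles` (N x
#'   (K+U)), `observed_profiles` (N x K), `sink`, `proportions` (length
#'   K+U, named), `irrelevant_ids`, `unknown_ids`, `unknown_total`,
#'   `design`.
#' @export
generate_noise_free <- function(pool_subset, design) {
  S <- pool_subset$profiles
  K <- design$K
  U <- design$U
  if (ncol(S) != K + U) {
    stop("pool subset must have K + U = ", K + U, " columns",
         call. = FALSE)
  }
  set.seed(design$seed)
  S <- normalize_columns(S)
  irrelevant <- sort(sample.int(K, design$F))
  p <- draw_proportions(K, U, irrelevant, design$unknown_total,
                        design$pareto_shape)
  names(p) <- colnames(S)
  sink <- drop(S %*% p)
  sink <- sink / sum(sink)
  Y <- vapply(seq_len(K), function(j)
    observe_profile(S[, j], design$depth, design$exact_profile),
    numeric(nrow(S)))
  dimnames(Y) <- list(rownames(S), colnames(S)[seq_len(K)])
  structure(list(true_profiles = S, observed_profiles = Y, sink = sink,
                 proportions = p,
                 irrelevant_ids = colnames(S)[irrelevant],
                 unknown_ids = if (U) colnames(S)[K + seq_len(U)]
                               else character(),
                 unknown_total = design$unknown_total, design = design),
            class = "simulation_truth")
}

#' Generate a noisy benchmark instance
#'
#' The second benchmark design amplifies the disparity between the true
#' mixing sources and the observed references: each of the K true
#' reference profiles is the normalized sum of G distinct pool samples,
#' while its observed counterpart is a multinomial resample of the
#' normalized sum of only V (<= G) of those samples. Smaller V means
#' larger mixing/observed divergence. U unknown and F irrelevant
#' sources are single pool samples used directly; the irrelevant ones
#' are appended to the observed references (with true proportion zero),
#' the unknown ones stay unobserved.
#'
#' @param pool A `source_pool` with at least `K*G + U + F` sources.
#' @param G Samples combined into each true reference source
#'   (default 10).
#' @param V Samples (of the G) combined into each observed reference,
#'   `1 <= V <= G`.
#' @param design A [mixture_design()].
#' @return A `simulation_truth` as in [generate_noise_free()], with
#'   `observed_profiles` having `K + F` columns (references then
#'   irrelevant singletons) and an extra element `mixing_observed_jsd`,
#'   the mean JSD between true and observed reference profiles.
#' @export
generate_noisy <- function(pool, G = 10L, V, design) {
  K <- design$K
  U <- design$U
  F <- design$F
  if (V < 1L || V > G) stop("V must satisfy 1 <= V <= G", call. = FALSE)
  P <- pool$profiles
  need <- K * G + U + F
  if (ncol(P) < need) {
    stop("pool too small: need ", need, " samples", call. = FALSE)
  }
  set.seed(design$seed)
  picked <- sample.int(ncol(P), need)
  groups <- matrix(picked[seq_len(K * G)], nrow = G)
  singles <- picked[K * G + seq_len(U + F)]
  unk_idx <- singles[seq_len(U)]
  irr_idx <- singles[U + seq_len(F)]
  N <- nrow(P)
  mix_cols <- function(idx) {
    v <- rowSums(P[, idx, drop = FALSE])
    v / sum(v)
  }
  S_ref <- vapply(seq_len(K), function(j) mix_cols(groups[, j]),
                  numeric(N))
  colnames(S_ref) <- sprintf("mix%02d", seq_len(K))
  Y_ref <- vapply(seq_len(K), function(j) {
    sub <- sample(groups[, j], V)
    observe_profile(mix_cols(sub), design$depth, design$exact_profile)
  }, numeric(N))
  colnames(Y_ref) <- colnames(S_ref)
  S_irr <- P[, irr_idx, drop = FALSE]
  Y_irr <- vapply(seq_len(F), function(j)
    observe_profile(S_irr[, j], design$depth, design$exact_profile),
    numeric(N))
  if (F) colnames(Y_irr) <- colnames(S_irr)
  S_unk <- P[, unk_idx, drop = FALSE]
  # references = K mixed sources + F irrelevant singletons; unknowns last
  S <- cbind(S_ref, S_irr, S_unk)
  Y <- cbind(Y_ref, if (F) Y_irr)
  rownames(S) <- rownames(Y) <- rownames(P)
  K_ref <- K + F
  irrelevant <- K + seq_len(F)
  p <- draw_proportions(K_ref, U, irrelevant, design$unknown_total,
                        design$pareto_shape)
  names(p) <- colnames(S)
  sink <- drop(S %*% p)
  sink <- sink / sum(sink)
  mix_obs <- mean(vapply(seq_len(K), function(j)
    jsd(S_ref[, j], Y_ref[, j]), numeric(1)))
  structure(list(true_profiles = S, observed_profiles = Y, sink = sink,
                 proportions = p,
                 irrelevant_ids = colnames(S)[irrelevant],
                 unknown_ids = if (U) colnames(S_unk) else character(),
                 unknown_total = design$unknown_total,
                 mixing_observed_jsd = mix_obs, design = design),
            class = "simulation_truth")
}

#' True proportion vector over the observed references plus unknown
#'
#' Collapses a `simulation_truth` to the vector a tracking fit
#' estimates: one entry per observed reference source (zeros for
#' irrelevant ones) and a final `Unknown` entry aggregating the
#' unobserved sources.
#'
#' @param truth A `simulation_truth`.
#' @return Named vector on the simplex, last entry `Unknown`.
#' @export
truth_reference_vector <- function(truth) {
  ref_ids <- colnames(truth$observed_profiles)
  p <- truth$proportions[ref_ids]
  c(p, Unknown = unname(sum(truth$proportions) - sum(p)))
}

#' Run a simulated benchmark sweep
#'
#' For every combination of `unknown_totals`, `V` (noisy mode only) and
#' replicate, generates a benchmark instance, solves it with
#' [source_track()], and scores the estimate against the truth with
#' [jsd()], [pcc()] and [identified_source_metrics()]. Each design
#' point receives a deterministic sub-seed derived from `seed`, so the
#' whole sweep is reproducible.
#'
#' @param pool A `source_pool`.
#' @param mode `"noise-free"` or `"noisy"`.
#' @param design A [mixture_design()] providing K, U, F, depth,
#'   `pareto_shape` (its `unknown_total` and `seed` are overridden per
#'   design point).
#' @param unknown_totals Grid of total unknown proportions (default
#'   0.1 to 0.9 by 0.1).
#' @param V Vector of observed-mixture sizes for noisy mode
#'   (default `1:G`).
#' @param G Samples per true source in noisy mode (default 10).
#' @param source_ids Pool columns to use in noise-free mode (e.g. from
#'   [select_source_set()]); defaults to the first K + U columns.
#' @param replicates Replicates per design point (default 3).
#' @param threshold Identification threshold for precision/recall.
#' @param seed Master seed for the sweep.
#' @param rho,tol,max_iter Solver settings passed to [source_track()].
#' @return data.frame with one row per (design point, replicate):
#'   design coordinates, sub-seed, proportion-space `jsd` and `pcc`,
#'   `precision`, `recall`, true and estimated unknown totals,
#'   median/max estimated irrelevant proportion, mixing/observed JSD
#'   (noisy mode), iterations and convergence flag. All estimated
#'   irrelevant proportions are attached as attribute
#'   `irrelevant_estimates`.
#' @export
run_benchmark_sweep <- function(pool, mode = c("noise-free", "noisy"),
                                design = mixture_design(),
                                unknown_totals = seq(0.1, 0.9, by = 0.1),
                                V = NULL, G = 10L, source_ids = NULL,
                                replicates = 3L, threshold = 0.01,
                                seed = 1L, rho = 1, tol = 1e-6,
                                max_iter = 2000L) {
  mode <- match.arg(mode)
  if (mode == "noisy" && is.null(V)) V <- seq_len(G)
  if (mode == "noise-free") {
    V <- NA_integer_
    if (is.null(source_ids)) {
      source_ids <- pool$source_ids[seq_len(design$K + design$U)]
    }
    subset_pool <- list(
      profiles = pool$profiles[, source_ids, drop = FALSE])
  }
  grid <- expand.grid(unknown_total = unknown_totals, V = V,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  irr_all <- numeric(0)
  for (i in seq_len(nrow(grid))) {
    sub_seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                             2147483647) + 1L
    d <- design
    d$unknown_total <- grid$unknown_total[i]
    d$seed <- sub_seed
    truth <- if (mode == "noise-free") {
      generate_noise_free(subset_pool, d)
    } else {
      generate_noisy(pool, G = G, V = grid$V[i], design = d)
    }
    fit <- source_track(truth$observed_profiles, truth$sink,
                        rho = rho, tol = tol, max_iter = max_iter)
    est <- coef(fit)[1L, ]
    tv <- truth_reference_vector(truth)
    ref <- setdiff(names(tv), "Unknown")
    pr <- identified_source_metrics(tv[ref], est[ref], threshold)
    irr_est <- est[truth$irrelevant_ids]
    irr_all <- c(irr_all, irr_est)
    rows[[i]] <- data.frame(
      mode = mode, unknown_total = grid$unknown_total[i],
      V = grid$V[i], replicate = grid$replicate[i], seed = sub_seed,
      jsd = jsd(tv, est), pcc = pcc(tv, est),
      precision = unname(pr["precision"]), recall = unname(pr["recall"]),
      unknown_true = unname(tv["Unknown"]),
      unknown_est = unname(est["Unknown"]),
      irrelevant_median = if (length(irr_est)) stats::median(irr_est)
                          else NA_real_,
      irrelevant_max = if (length(irr_est)) max(irr_est) else NA_real_,
      mixing_observed_jsd = if (mode == "noisy")
        truth$mixing_observed_jsd else NA_real_,
      iterations = fit$fits[[1L]]$iterations,
      converged = fit$fits[[1L]]$converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "irrelevant_estimates") <- irr_all
  out
}
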