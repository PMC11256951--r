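#' Solver settings for the ADMM iteration
#'
#' @param rho Positive penalty parameter of the augmented Lagrangian
#'   (default 1).
#' @param tol Relative-change convergence threshold on the augmented
#'   Lagrangian (default 1e-6).
#' @param max_iter Maximum number of ADMM iterations (default 2000).
#' @param seed Optional integer seed; the solver itself is deterministic,
#'   the seed is recorded for provenance of any upstream randomness.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(rho = 1, tol = 1e-6, max_iter = 2000L,
                          seed = NULL) {
  stopifnot(rho > 0, tol > 0, max_iter >= 1)
  structure(list(rho = rho, tol = tol, max_iter = as.integer(max_iter),
                 seed = seed), class = "solver_config")
}

#' Build a source-tracking problem
#'
#' Assembles the aligned, column-normalized inputs of the factorization:
#' the sink vector `X` (length N, unit sum), the observed reference
#' matrix `Y` extended by one unknown-source column to N x (K+1), and the
#' binary weight matrix `A` whose first K columns are 1 and last column 0,
#' so the anchoring loss `||A o (W - Y)||` ignores the unobserved column.
#'
#' The unknown column of `Y` is unidentified by the data; since `A` masks
#' it out of the loss it only seeds the initial `W`. It is filled with
#' the sink restricted to taxa absent from every reference source
#' (normalized) -- the part of the sink no reference can explain, which
#' is what the unknown source exists to capture -- falling back to
#' uniform over all taxa when the references cover the whole sink.
#' Seeding the column inside the references' span instead creates a
#' continuum of zero-loss solutions along which the unknown proportion
#' is unidentified.
#'
#' @param sources Non-negative taxa-by-source matrix (K columns), taxa
#'   aligned with the sink.
#' @param sink Non-negative vector of length N (the target sample).
#' @param config A [solver_config()].
#' @return List of class `track_problem` with fields `X`, `Y`, `A`, `N`,
#'   `K`, `taxon_ids`, `source_ids`, `config`.
#' @export
track_problem <- function(sources, sink, config = solver_config()) {
  sources <- as.matrix(sources)
  sink <- as.numeric(sink)
  N <- nrow(sources)
  K <- ncol(sources)
  stopifnot(K >= 1L, length(sink) == N)
  if (any(sources < 0) || any(sink < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (sum(sink) <= 0) stop("all-zero sink", call. = FALSE)
  Yk <- normalize_columns(sources)
  X <- sink / sum(sink)
  unexplained <- X * (apply(Yk, 1L, max) <= 0)
  unk <- if (sum(unexplained) > 0) unexplained / sum(unexplained)
         else rep(1 / N, N)
  Y <- cbind(Yk, Unknown = unk)
  A <- cbind(matrix(1, N, K), 0)
  structure(list(X = X, Y = Y, A = A, N = N, K = K,
                 taxon_ids = rownames(sources),
                 source_ids = colnames(sources),
                 config = config),
            class = "track_problem")
}

# Deterministic starting point: W and W+ at the (extended) observed
# profiles, H and H+ uniform over the K references with the unknown
# entry at zero, duals zero. Starting the unknown at zero lets its
# proportion rise only when the references cannot explain the sink;
# giving it an equal initial share instead pins roughly that share on
# the unknown forever (its column is unanchored, so it reshapes itself
# to fit whatever mixture the initial share implies, a flat direction
# of the objective).
initialize_state <- function(problem) {
  K <- problem$K
  h0 <- c(rep(1 / K, K), 0)
  list(W = problem$Y, W_plus = problem$Y,
       H = h0, H_plus = h0,
       alpha_W = matrix(0, problem$N, K + 1L), alpha_H = rep(0, K + 1L))
}

# H <- (W'W + rho I)^-1 (W'X + rho H+ - alpha_H); exact linear solve,
# positive definite by construction, may leave the simplex.
update_H <- function(state, problem, rho) {
  W <- state$W
  G <- crossprod(W) + diag(rho, ncol(W))
  drop(solve(G, crossprod(W, problem$X) + rho * state$H_plus -
               state$alpha_H))
}

# W <- (rho W+ - alpha_W + X H') (H H' + rho I)^-1; entries may go
# negative here, the W+ projection restores feasibility.
update_W <- function(state, problem, rho, H) {
  M <- rho * state$W_plus - state$alpha_W + tcrossprod(problem$X, H)
  G <- tcrossprod(H) + diag(rho, length(H))
  out <- t(solve(G, t(M)))
  dimnames(out) <- dimnames(state$W_plus)
  out
}

# Rescale so W has unit column sums, moving the scale into H; WH is
# unchanged. Column sums can be tiny or negative before projection, so
# they are clamped at a positive floor rather than inverted blindly.
rescale <- function(W, H, floor = 1e-12) {
  d <- colSums(W)
  clamped <- d < floor
  if (any(clamped)) d[clamped] <- floor
  list(W = sweep(W, 2L, d, "/"), H = H * d, clamped = any(clamped))
}

# Augmented Lagrangian, term by term as defined for the split problem.
lagrangian <- function(state, problem, rho) {
  r_fit <- problem$X - drop(state$W %*% state$H)
  r_anchor <- problem$A * (state$W_plus - problem$Y)
  dW <- state$W - state$W_plus
  dH <- state$H - state$H_plus
  0.5 * sum(r_fit^2) + 0.5 * sum(r_anchor^2) +
    sum(state$alpha_W * dW) + rho / 2 * sum(dW^2) +
    sum(state$alpha_H * dH) + rho / 2 * sum(dH^2)
}

# Dual ascent on both split constraints.
update_duals <- function(state, rho) {
  list(alpha_W = state$alpha_W + rho * (state$W - state$W_plus),
       alpha_H = state$alpha_H + rho * (state$H - state$H_plus))
}

# Relative change of the augmented Lagrangian; absolute change when the
# previous value is numerically zero (the relative criterion is
# undefined there).
has_converged <- function(L_prev, L_curr, tol) {
  if (abs(L_prev) < 1e-15) return(abs(L_prev - L_curr) <= tol)
  abs(L_prev - L_curr) / abs(L_prev) <= tol
}

#' Solve a source-tracking problem by ADMM
#'
#' Runs the ADMM iteration: exact linear updates of `H` then `W`,
#' rescaling of `W` to unit column sums (compensated in `H`),
#' water-filling projections of `H+` onto the (K+1)-simplex and of each
#' `W+` column onto the taxon simplex, then dual ascent. Iterates until
#' the relative change of the augmented Lagrangian falls below `tol` or
#' `max_iter` is reached. The estimated source proportions are the final
#' `H+`.
#'
#' @param problem A [track_problem()].
#' @param config A [solver_config()]; defaults to the problem's own.
#' @return List of class `track_fit`: `proportions` (named, length K+1,
#'   last entry `Unknown`), `iterations`, `converged`,
#'   `lagrangian_trace`, `residuals` (final Frobenius split residuals),
#'   `max_simplex_dev` (worst per-iteration deviation of `H+`/`W+`
#'   column sums from 1), `W_plus`, and the `problem`.
#' @export
solve_track <- function(problem, config = problem$config) {
  stopifnot(inherits(problem, "track_problem"))
  rho <- config$rho
  state <- initialize_state(problem)
  L_prev <- lagrangian(state, problem, rho)
  trace <- numeric(config$max_iter)
  converged <- FALSE
  iter <- 0L
  max_dev <- 0
  while (iter < config$max_iter) {
    iter <- iter + 1L
    H <- update_H(state, problem, rho)
    W <- update_W(state, problem, rho, H)
    sc <- rescale(W, H)
    state$W <- sc$W
    state$H <- sc$H
    state$H_plus <- project_H_plus(state$H, state$alpha_H, rho)
    state$W_plus <- project_W_plus(state$W, state$alpha_W, problem$Y,
                                   problem$A, rho)
    duals <- update_duals(state, rho)
    state$alpha_W <- duals$alpha_W
    state$alpha_H <- duals$alpha_H
    dev <- max(abs(sum(state$H_plus) - 1),
               abs(colSums(state$W_plus) - 1),
               -min(0, state$H_plus), -min(0, state$W_plus))
    max_dev <- max(max_dev, dev)
    L <- lagrangian(state, problem, rho)
    trace[iter] <- L
    if (!is.finite(L)) {
      stop("non-finite augmented Lagrangian at iteration ", iter,
           call. = FALSE)
    }
    if (has_converged(L_prev, L, config$tol)) {
      converged <- TRUE
      break
    }
    L_prev <- L
  }
  proportions <- state$H_plus
  names(proportions) <- colnames(problem$Y)
  structure(list(proportions = proportions,
                 iterations = iter,
                 converged = converged,
                 lagrangian_trace = trace[seq_len(iter)],
                 residuals = c(W = sqrt(sum((state$W - state$W_plus)^2)),
                               H = sqrt(sum((state$H - state$H_plus)^2))),
                 max_simplex_dev = max_dev,
                 W_plus = state$W_plus,
                 problem = problem,
                 config = config),
            class = "track_fit")
}
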