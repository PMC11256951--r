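make_state <- function(problem, seed = 1) {
  set.seed(seed)
  Kp1 <- problem$K + 1L
  N <- problem$N
  W <- problem$Y + matrix(rnorm(N * Kp1, sd = 0.1), N)
  list(W = W,
       W_plus = apply(abs(W), 2, function(v) v / sum(v)),
       H = rnorm(Kp1, 1 / Kp1, 0.1),
       H_plus = rsimplex(Kp1),
       alpha_W = matrix(rnorm(N * Kp1, sd = 0.05), N),
       alpha_H = rnorm(Kp1, sd = 0.05))
}

toy_problem <- function() {
  S <- cbind(s1 = c(5, 3, 2, 0), s2 = c(0, 1, 4, 5))
  rownames(S) <- paste0("t", 1:4)
  track_problem(S, c(2, 2, 3, 3))
}

test_that("problem construction follows the model contract", {
  prob <- toy_problem()
  expect_equal(prob$K, 2L)
  expect_equal(sum(prob$X), 1, tolerance = 1e-12)
  expect_equal(colSums(prob$Y)[1:2], c(s1 = 1, s2 = 1), tolerance = 1e-12)
  # weight matrix: ones over the K reference columns, zeros for unknown
  expect_true(all(prob$A[, 1:2] == 1))
  expect_true(all(prob$A[, 3] == 0))
  # sink normalization example
  expect_equal(track_problem(cbind(a = c(1, 1, 1)), c(2, 2, 0))$X,
               c(0.5, 0.5, 0))
  expect_error(track_problem(cbind(a = c(1, 1)), c(0, 0)), "all-zero")
  expect_error(track_problem(cbind(a = c(0, 0)), c(1, 1)), "all-zero")
})

test_that("unknown column seeds on reference-unexplained sink taxa", {
  S <- cbind(s1 = c(1, 0, 0), s2 = c(0, 1, 0))
  rownames(S) <- c("a", "b", "c")
  prob <- track_problem(S, c(a = 0.3, b = 0.3, c = 0.4))
  expect_equal(prob$Y[, 3], c(a = 0, b = 0, c = 1))
  # references covering the sink: fall back to the uniform profile
  prob2 <- track_problem(S, c(a = 0.5, b = 0.5, c = 0))
  expect_equal(unname(prob2$Y[, 3]), rep(1 / 3, 3))
})

test_that("initial state is feasible, deterministic, with idle unknown", {
  prob <- toy_problem()
  st <- mstnmf:::initialize_state(prob)
  expect_equal(st$H, c(0.5, 0.5, 0))
  expect_equal(st$H, st$H_plus)
  expect_equal(colSums(st$W_plus), c(s1 = 1, s2 = 1, Unknown = 1),
               tolerance = 1e-12)
  expect_true(all(st$alpha_W == 0) && all(st$alpha_H == 0))
})

test_that("H update solves its normal equations exactly", {
  # hand-derived: W = I, X = (.6,.4), rho = 1, H+ = (.5,.5), alpha = 0
  prob <- structure(list(X = c(0.6, 0.4), Y = diag(2),
                         A = cbind(1, 0), N = 2L, K = 1L),
                    class = "track_problem")
  st <- list(W = diag(2), H_plus = c(0.5, 0.5), alpha_H = c(0, 0))
  expect_equal(mstnmf:::update_H(st, prob, 1), c(0.55, 0.45),
               tolerance = 1e-12)
  # large rho pins H to H+
  expect_equal(mstnmf:::update_H(st, prob, 1e9), c(0.5, 0.5),
               tolerance = 1e-6)
  # defining equation holds on a random state
  prob2 <- toy_problem()
  st2 <- make_state(prob2, 3)
  H <- mstnmf:::update_H(st2, prob2, 0.8)
  lhs <- (crossprod(st2$W) + diag(0.8, 3)) %*% H
  rhs <- crossprod(st2$W, prob2$X) + 0.8 * st2$H_plus - st2$alpha_H
  expect_equal(drop(lhs), drop(rhs), tolerance = 1e-10)
})

test_that("W update solves its normal equations exactly", {
  prob <- toy_problem()
  st <- make_state(prob, 5)
  H <- mstnmf:::update_H(st, prob, 1.2)
  W <- mstnmf:::update_W(st, prob, 1.2, H)
  lhs <- W %*% (tcrossprod(H) + diag(1.2, 3))
  rhs <- 1.2 * st$W_plus - st$alpha_W + tcrossprod(prob$X, H)
  expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
  # scalar case: W = (rho w+ - alpha + x h) / (h^2 + rho)
  stsc <- list(W_plus = matrix(0.9), alpha_W = matrix(0.2))
  probsc <- list(X = 0.7)
  got <- mstnmf:::update_W(stsc, probsc, 2, 0.5)
  expect_equal(got[1, 1], (2 * 0.9 - 0.2 + 0.7 * 0.5) / (0.5^2 + 2),
               tolerance = 1e-12)
  # large rho pins W to W+ when duals vanish
  st$alpha_W[] <- 0
  expect_equal(mstnmf:::update_W(st, prob, 1e9, H), st$W_plus,
               tolerance = 1e-6)
})

test_that("rescaling preserves the product and normalizes columns", {
  W <- cbind(c(2, 2), c(0.2, 0.6))
  H <- c(0.5, 2)
  sc <- mstnmf:::rescale(W, H)
  expect_equal(colSums(sc$W), c(1, 1), tolerance = 1e-12)
  expect_equal(sc$W[, 1], c(0.5, 0.5))
  expect_equal(sc$H[1], 2)
  expect_equal(sc$W %*% sc$H, W %*% H, tolerance = 1e-12)
  # already normalized columns are untouched
  Wn <- cbind(c(0.3, 0.7), c(0.9, 0.1))
  sc2 <- mstnmf:::rescale(Wn, H)
  expect_equal(sc2$W, Wn)
  expect_equal(sc2$H, H)
  # near-zero column sums are clamped, never divided to Inf
  sc3 <- mstnmf:::rescale(cbind(c(1e-20, -1e-20), c(0.5, 0.5)), H)
  expect_true(all(is.finite(sc3$W)))
  expect_true(sc3$clamped)
})

test_that("augmented Lagrangian matches an independent term-by-term oracle", {
  prob <- toy_problem()
  for (seed in 1:5) {
    st <- make_state(prob, seed)
    for (rho in c(0.5, 1, 2)) {
      expect_equal(mstnmf:::lagrangian(st, prob, rho),
                   oracle_lagrangian(st, prob, rho), tolerance = 1e-10)
    }
  }
})

test_that("Lagrangian vanishes at a perfectly consistent state", {
  prob <- toy_problem()
  H <- c(0.4, 0.6, 0)
  W <- prob$Y
  st <- list(W = W, W_plus = W, H = H, H_plus = H,
             alpha_W = matrix(0, prob$N, 3), alpha_H = rep(0, 3))
  prob$X <- drop(W %*% H)
  expect_equal(mstnmf:::lagrangian(st, prob, 1), 0, tolerance = 1e-15)
  # with zero duals and matched splits only the two data terms remain
  st2 <- make_state(prob, 2)
  st2$W_plus <- st2$W
  st2$H_plus <- st2$H
  st2$alpha_W[] <- 0
  st2$alpha_H[] <- 0
  expect_equal(mstnmf:::lagrangian(st2, prob, 3),
               0.5 * sum((prob$X - st2$W %*% st2$H)^2) +
                 0.5 * sum((prob$A * (st2$W_plus - prob$Y))^2),
               tolerance = 1e-12)
})

test_that("dual ascent is the stated affine map", {
  prob <- toy_problem()
  st <- make_state(prob, 9)
  # zero residual leaves duals unchanged, twice over
  st$W_plus <- st$W
  st$H_plus <- st$H
  d1 <- mstnmf:::update_duals(st, 1)
  expect_equal(d1$alpha_W, st$alpha_W, ignore_attr = TRUE)
  expect_equal(d1$alpha_H, st$alpha_H)
  st$alpha_W <- d1$alpha_W
  st$alpha_H <- d1$alpha_H
  d2 <- mstnmf:::update_duals(st, 1)
  expect_equal(d2$alpha_H, d1$alpha_H)
  # direct numeric case
  st$H <- c(0.6, 0.4, 0)
  st$H_plus <- c(0.5, 0.5, 0)
  st$alpha_H <- c(0, 0, 0)
  expect_equal(mstnmf:::update_duals(st, 1)$alpha_H, c(0.1, -0.1, 0))
})

test_that("convergence criterion is relative with an absolute guard", {
  expect_true(mstnmf:::has_converged(1, 1.0000005, 1e-6))
  expect_false(mstnmf:::has_converged(1, 0.9, 1e-6))
  expect_no_error(mstnmf:::has_converged(0, 1e-9, 1e-6))
  expect_true(mstnmf:::has_converged(0, 5e-7, 1e-6))
  expect_false(mstnmf:::has_converged(0, 1e-3, 1e-6))
})

test_that("orthogonal sources recover an exact mixture", {
  Y <- diag(2)
  rownames(Y) <- c("a", "b")
  colnames(Y) <- c("s1", "s2")
  fit <- solve_track(track_problem(Y, c(a = 0.3, b = 0.7)))
  expect_equal(unname(fit$proportions), c(0.3, 0.7, 0), tolerance = 1e-3)
  # grid search over the mixing weights confirms zero loss is attainable
  # and that the solver attains it
  grid <- seq(0, 1, by = 0.01)
  losses <- vapply(grid, function(a)
    sum((c(0.3, 0.7) - Y %*% c(a, 1 - a))^2), numeric(1))
  Wh <- fit$W_plus %*% fit$proportions
  expect_equal(sum((c(0.3, 0.7) - Wh)^2), min(losses), tolerance = 1e-6)
})

test_that("a sink equal to one source is attributed to it", {
  mix <- make_mixture(21, n_taxa = 200, K = 5)
  fit <- source_track(mix$S, mix$S[, 1])
  expect_equal(unname(coef(fit)[1, ]), c(1, rep(0, 5)), tolerance = 1e-3)
})

test_that("defaults follow the published solver settings", {
  cfg <- solver_config()
  expect_equal(cfg$rho, 1)
  expect_equal(cfg$tol, 1e-6)
  expect_equal(cfg$max_iter, 2000L)
})

test_that("solve respects taxa and source permutation symmetry", {
  mix <- make_mixture(31, n_taxa = 200, K = 4)
  fit <- source_track(mix$S, mix$x)
  # identical permutation of taxa rows in sources and sink
  set.seed(1)
  perm <- sample(nrow(mix$S))
  fit_p <- source_track(mix$S[perm, ], mix$x[perm])
  expect_equal(coef(fit_p), coef(fit), tolerance = 1e-9)
  # permutation of source columns permutes the estimates with them
  cperm <- c(3, 1, 4, 2)
  fit_c <- source_track(mix$S[, cperm], mix$x)
  expect_equal(unname(coef(fit_c)[1, 1:4]),
               unname(coef(fit)[1, cperm]), tolerance = 1e-6)
})

test_that("projected blocks stay feasible at every iteration", {
  mix <- make_mixture(41, n_taxa = 200, K = 4)
  fit <- source_track(mix$S, mix$x)
  expect_lt(fit$fits[[1]]$max_simplex_dev, 1e-9)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
})

test_that("fit methods expose proportions, fit quality and diagnostics", {
  mix <- make_mixture(51, n_taxa = 150, K = 3)
  sinks <- cbind(x1 = mix$x, x2 = mix$S[, 2])
  fit <- source_track(mix$S, sinks)
  expect_s3_class(fit, "source_track")
  expect_equal(dim(coef(fit)), c(2L, 4L))
  expect_equal(rowSums(coef(fit)), c(x1 = 1, x2 = 1), tolerance = 1e-9)
  expect_output(print(fit), "source tracking fit")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.source_track")
  expect_identical(sm$diagnostics$SinkID, c("x1", "x2"))
  r <- residuals(fit)
  expect_equal(dim(r), c(150L, 2L))
  expect_lt(max(abs(r)), 1e-3)
  expect_equal(fitted(fit) + r,
               vapply(fit$fits, function(f) f$problem$X, numeric(150)),
               ignore_attr = TRUE)
})
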