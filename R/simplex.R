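#' Weighted projection onto the probability simplex
#'
#' Solves `min_x 1/2 * sum(d * x^2) - sum(n * x)` subject to `x >= 0` and
#' `sum(x) = 1` in closed form. By the KKT conditions the minimizer is
#' `x_i = max(0, (n_i - beta) / d_i)` for a scalar multiplier `beta` (the
#' "water level") chosen so the entries sum to one. Because every
#' `d_i > 0`, an entry is active exactly when `n_i > beta`, so the support
#' is a top set of the sorted numerators and `beta` has the exact
#' sort-based solution: scan support sizes `k` in decreasing order of
#' `n`, solve the equality-constrained problem
#' `beta_k = (sum_{i<=k} n_i/d_i - 1) / sum_{i<=k} 1/d_i`, and keep the
#' `k` whose `beta_k` leaves all included entries positive. Ties among
#' equal numerators are handled consistently by construction. This is the
#' water-filling update used for both simplex-constrained blocks of the
#' ADMM iteration.
#'
#' @param n Numeric vector of linear coefficients (numerators).
#' @param d Strictly positive numeric vector of quadratic weights
#'   (denominators), same length as `n`.
#' @return List with `x` (the projection, on the simplex) and `beta`
#'   (the multiplier).
#' @examples
#' project_weighted_simplex(c(2, 0), c(1, 1))        # x = (1, 0)
#' project_weighted_simplex(c(0.6, 0.6), c(1, 1))    # x = (0.5, 0.5)
#' @export
project_weighted_simplex <- function(n, d) {
  stopifnot(length(n) == length(d), length(n) >= 1L)
  if (any(d <= 0)) stop("denominators must be strictly positive",
                        call. = FALSE)
  ord <- order(n, decreasing = TRUE)
  ns <- n[ord]
  ds <- d[ord]
  cum_nd <- cumsum(ns / ds)
  cum_id <- cumsum(1 / ds)
  beta_k <- (cum_nd - 1) / cum_id
  m <- length(n)
  # largest k with n_(k) > beta_k; k = 1 always qualifies when x must sum
  # to 1 (beta_1 = n_1 - d_1 < n_1)
  ok <- ns > beta_k
  k <- max(which(ok))
  beta <- beta_k[k]
  x <- pmax(0, (n - beta) / d)
  # exact renormalization guards rounding in the cumulative sums
  x <- x / sum(x)
  list(x = x, beta = beta)
}

# H+ update: arg min over the simplex of the Lagrangian terms in H+,
# i.e. numerators alpha_H + rho * H against uniform weight rho.
project_H_plus <- function(H, alpha_H, rho) {
  project_weighted_simplex(alpha_H + rho * H, rep(rho, length(H)))$x
}

# W+ update, column by column: numerators A^2 * Y + alpha_W + rho * W,
# denominators A^2 + rho. For the unknown column (A = 0) this reduces to
# the same pure proximal form as the H+ update.
project_W_plus <- function(W, alpha_W, Y, A, rho) {
  out <- W
  for (j in seq_len(ncol(W))) {
    a2 <- A[, j]^2
    out[, j] <- project_weighted_simplex(
      a2 * Y[, j] + alpha_W[, j] + rho * W[, j], a2 + rho)$x
  }
  out
}
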