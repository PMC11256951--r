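#' Estimate source proportions in microbiome sink samples
#'
#' Fits the reference-anchored non-negative factorization model of
#' microbial source tracking. Each sink (target) sample is modeled as a
#' convex mixture of K latent source profiles plus one aggregate unknown
#' source; the latent profiles are anchored to the observed reference
#' profiles while the unknown column is free, and the mixture weights
#' are estimated on the (K+1)-simplex. Sinks are independent problems
#' and are solved sequentially.
#'
#' Inputs may be raw counts or relative abundances; columns are
#' normalized internally. Taxa are aligned to the union of the two
#' tables' taxon sets, zero-filling absences, so sink taxa unseen in any
#' reference remain visible to the model (they drive the unknown
#' proportion).
#'
#' @param sources Non-negative taxa-by-source matrix with taxon rownames
#'   and source colnames.
#' @param sinks Non-negative taxa-by-sink matrix (or a single vector,
#'   treated as one sink) with taxon rownames.
#' @param rho Positive ADMM penalty parameter (default 1).
#' @param tol Relative convergence threshold on the augmented Lagrangian
#'   (default 1e-6).
#' @param max_iter Maximum ADMM iterations per sink (default 2000).
#' @param seed Optional integer seed recorded for provenance; the fit is
#'   deterministic.
#' @return An object of class `source_track`: a list with
#'   `proportions` (sinks x (K+1) matrix, final column `Unknown`),
#'   `fits` (per-sink `track_fit` objects), `source_ids`, `sink_ids`,
#'   and `call`.
#' @examples
#' taxa <- paste0("t", 1:6)
#' S <- cbind(a = c(5, 3, 1, 0, 0, 0), b = c(0, 0, 1, 3, 5, 0))
#' rownames(S) <- taxa
#' x <- 0.7 * S[, 1] / sum(S[, 1]) + 0.3 * S[, 2] / sum(S[, 2])
#' fit <- source_track(S, x)
#' coef(fit)
#' @export
source_track <- function(sources, sinks, rho = 1, tol = 1e-6,
                         max_iter = 2000L, seed = NULL) {
  cl <- match.call()
  sources <- as.matrix(sources)
  if (is.null(dim(sinks))) {
    sinks <- matrix(sinks, ncol = 1L,
                    dimnames = list(names(sinks), "sink1"))
  }
  sinks <- as.matrix(sinks)
  validate_abundance(sources, "sources")
  validate_abundance(sinks, "sinks")
  if (!is.null(rownames(sources)) && !is.null(rownames(sinks))) {
    al <- align_taxa(sources, sinks)
    sources <- al$sources
    sinks <- al$sinks
  } else if (nrow(sources) != nrow(sinks)) {
    stop("taxon rownames required unless row counts already match",
         call. = FALSE)
  }
  config <- solver_config(rho = rho, tol = tol, max_iter = max_iter,
                          seed = seed)
  source_ids <- colnames(sources)
  if (is.null(source_ids)) source_ids <- paste0("S", seq_len(ncol(sources)))
  colnames(sources) <- source_ids
  sink_ids <- colnames(sinks)
  if (is.null(sink_ids)) sink_ids <- paste0("sink", seq_len(ncol(sinks)))
  fits <- lapply(seq_len(ncol(sinks)), function(j) {
    solve_track(track_problem(sources, sinks[, j], config))
  })
  names(fits) <- sink_ids
  proportions <- do.call(rbind, lapply(fits, `[[`, "proportions"))
  rownames(proportions) <- sink_ids
  structure(list(proportions = proportions, fits = fits,
                 source_ids = source_ids, sink_ids = sink_ids,
                 call = cl),
            class = "source_track")
}

#' @export
print.source_track <- function(x, digits = 4, ...) {
  cat("Microbial source tracking fit (reference-anchored NMF/ADMM)\n")
  cat(sprintf("  %d sink(s), %d reference source(s) + unknown\n",
              length(x$sink_ids), length(x$source_ids)))
  cat("Estimated proportions:\n")
  print(round(x$proportions, digits), ...)
  conv <- vapply(x$fits, `[[`, logical(1), "converged")
  iters <- vapply(x$fits, `[[`, integer(1), "iterations")
  cat(sprintf("Converged: %d/%d sinks (iterations: %s)\n",
              sum(conv), length(conv), paste(iters, collapse = ", ")))
  invisible(x)
}

#' @export
summary.source_track <- function(object, ...) {
  conv <- vapply(object$fits, `[[`, logical(1), "converged")
  iters <- vapply(object$fits, `[[`, integer(1), "iterations")
  finalL <- vapply(object$fits, function(f)
    utils::tail(f$lagrangian_trace, 1L), numeric(1))
  out <- list(proportions = object$proportions,
              diagnostics = data.frame(
                SinkID = object$sink_ids, converged = conv,
                iterations = iters, final_lagrangian = finalL,
                unknown = object$proportions[, "Unknown"],
                row.names = NULL))
  class(out) <- "summary.source_track"
  out
}

#' @export
print.summary.source_track <- function(x, digits = 4, ...) {
  cat("Estimated source proportions:\n")
  print(round(x$proportions, digits))
  cat("\nPer-sink solver diagnostics:\n")
  print(x$diagnostics, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Extract estimated proportions
#'
#' @param object A `source_track` fit.
#' @param ... Unused.
#' @return Sinks-by-(K+1) matrix of proportions; columns are the
#'   reference sources plus `Unknown`. A single-sink fit returns the
#'   matrix too (drop = FALSE semantics).
#' @export
coef.source_track <- function(object, ...) object$proportions

#' @export
fitted.source_track <- function(object, ...) {
  out <- vapply(object$fits, function(f)
    drop(f$W_plus %*% f$proportions), numeric(object$fits[[1L]]$problem$N))
  rownames(out) <- object$fits[[1L]]$problem$taxon_ids
  out
}

#' @export
residuals.source_track <- function(object, ...) {
  X <- vapply(object$fits, function(f) f$problem$X,
              numeric(object$fits[[1L]]$problem$N))
  X - fitted(object)
}

#' Plot the convergence trace of a fit
#'
#' Draws the augmented-Lagrangian value per ADMM iteration, one line per
#' sink, on a log y-axis.
#'
#' @param x A `source_track` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.source_track <- function(x, ...) {
  traces <- lapply(x$fits, `[[`, "lagrangian_trace")
  len <- max(vapply(traces, length, integer(1)))
  m <- vapply(traces, function(tr) c(tr, rep(NA, len - length(tr))),
              numeric(len))
  graphics::matplot(m, type = "l", lty = 1, log = "y",
                    xlab = "ADMM iteration",
                    ylab = "augmented Lagrangian", ...)
  invisible(x)
}
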