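# MDIIS (modified direct inversion in the iterative subspace)
# Shared convergence engine for the 1D and 3D RISM stages.

#' Iterate a fixed-point map with MDIIS acceleration
#'
#' Solves `F(x) = x` where `residual_fun(x)` returns `F(x) - x`.  With
#' `n_vectors = 1` this reduces to damped Picard iteration
#' `x <- x + damp * r`.  With `n_vectors > 1` the step extrapolates in
#' the subspace of the last few iterates: coefficients `a` minimize
#' `|sum a_i r_i|` subject to `sum a_i = 1`, and
#' `x <- sum a_i x_i + damp * sum a_i r_i`.
#'
#' The subspace is reset (restarted from the best iterate seen) when the
#' residual grows beyond `restart_factor` times the best residual — the
#' standard MDIIS safeguard against a degenerate subspace.
#'
#' @param x0 Initial iterate (numeric vector; callers flatten fields).
#' @param residual_fun Function of x returning the residual `F(x) - x`.
#' @param n_vectors Maximum subspace size (>= 1).
#' @param tol Convergence tolerance on `max(abs(residual))`.
#' @param max_iter Iteration cap.
#' @param damp Mixing parameter in (0, 1].
#' @param restart_factor Residual-growth factor triggering a restart.
#' @param on_fail `"error"` (raise a divergence error carrying the last
#'   residual) or `"return"` (return the unconverged state).
#' @return List: `x`, `residual` (final max-norm), `iterations`,
#'   `converged`, `trace` (residual per iteration).
#' @export
mdiis_solve <- function(x0, residual_fun, n_vectors = 5L, tol = 1e-6,
                        max_iter = 1000L, damp = 0.7,
                        restart_factor = 10, on_fail = c("error", "return")) {
  on_fail <- match.arg(on_fail)
  stopifnot(n_vectors >= 1L, tol > 0, damp > 0, damp <= 1)
  x <- as.numeric(x0)
  xs <- list(); rs <- list()
  trace <- numeric(0)
  best <- Inf; best_x <- x
  for (it in seq_len(max_iter)) {
    r <- residual_fun(x)
    res <- max(abs(r))
    if (!is.finite(res)) {
      # diverged hard: restart from best with heavy damping
      x <- best_x
      xs <- list(); rs <- list()
      r <- residual_fun(x)
      res <- max(abs(r))
      if (!is.finite(res))
        stop(rismhydra_divergence("non-finite residual", res, trace))
    }
    trace <- c(trace, res)
    if (res < best) { best <- res; best_x <- x }
    if (res <= tol)
      return(list(x = x, residual = res, iterations = it,
                  converged = TRUE, trace = trace))
    if (res > restart_factor * best && length(rs) > 1L) {
      # subspace gone bad: restart from the best iterate
      x <- best_x
      xs <- list(); rs <- list()
      r <- residual_fun(x)
      res <- max(abs(r))
      trace <- c(trace, res)
    }
    xs[[length(xs) + 1L]] <- x
    rs[[length(rs) + 1L]] <- r
    if (length(xs) > n_vectors) { xs <- xs[-1L]; rs <- rs[-1L] }
    m <- length(xs)
    if (m == 1L) {
      x <- x + damp * r
    } else {
      S <- matrix(0, m, m)
      for (i in seq_len(m)) for (j in i:m) {
        S[i, j] <- S[j, i] <- sum(rs[[i]] * rs[[j]])
      }
      B <- rbind(cbind(S, 1), c(rep(1, m), 0))
      rhs <- c(rep(0, m), 1)
      a <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (is.null(a) || any(!is.finite(a))) {
        # ill-conditioned subspace: drop history, damped step
        xs <- xs[m]; rs <- rs[m]
        x <- x + damp * r
      } else {
        xn <- a[m] * xs[[m]]; rn <- a[m] * rs[[m]]
        for (i in seq_len(m - 1L)) {
          xn <- xn + a[i] * xs[[i]]
          rn <- rn + a[i] * rs[[i]]
        }
        x <- xn + damp * rn
      }
    }
  }
  if (on_fail == "return")
    return(list(x = best_x, residual = best, iterations = max_iter,
                converged = FALSE, trace = trace))
  stop(rismhydra_divergence(
    sprintf("no convergence after %d iterations (last residual %.3e)",
            max_iter, trace[length(trace)]),
    trace[length(trace)], trace))
}

#' @keywords internal
rismhydra_divergence <- function(msg, residual, trace) {
  structure(
    class = c("rismhydra_divergence", "error", "condition"),
    list(message = msg, call = sys.call(-1),
         residual = residual, trace = trace))
}
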