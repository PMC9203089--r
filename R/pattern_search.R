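#' Bounded generalized pattern search
#'
#' Derivative-free minimization by coordinate polling on a shrinking
#' mesh: each poll perturbs one parameter by plus/minus the mesh step
#' (scaled per coordinate by the box range), accepts the first
#' improvement, doubles the mesh on success and halves it after a full
#' unsuccessful poll, clipping every candidate to the bounds. Polling is
#' deterministic (coordinates in order, `+` before `-`), so the result
#' depends only on the objective and the starting point.
#'
#' @param objective Function of a numeric parameter vector returning a
#'   scalar; may return `Inf` as an infeasibility barrier.
#' @param par Feasible starting vector.
#' @param lower,upper Box bounds.
#' @param budget Maximum number of objective evaluations (>= 1,
#'   including the initial one).
#' @param mesh Initial mesh size as a fraction of each box range.
#' @param mesh_tol Stop when the mesh fraction falls below this.
#' @param expand,contract Mesh multipliers on success / failed poll.
#' @return List with `par`, `value`, `trace` (objective at the start and
#'   after each accepted step; non-increasing), `evals`, `mesh`.
#' @export
pattern_search <- function(objective, par, lower, upper, budget = 500L,
                           mesh = 0.25, mesh_tol = 1e-3,
                           expand = 2, contract = 0.5) {
  stopifnot(length(par) == length(lower), length(par) == length(upper),
            budget >= 1L)
  par <- pmin(pmax(par, lower), upper)
  range <- upper - lower
  f <- objective(par)
  if (!is.finite(f)) stop("initialization error: infeasible starting point")
  evals <- 1L
  trace <- f
  n <- length(par)

  while (evals < budget && mesh >= mesh_tol) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        if (evals >= budget) break
        cand <- par
        cand[i] <- min(max(par[i] + s * mesh * range[i], lower[i]), upper[i])
        if (cand[i] == par[i]) next
        fc <- objective(cand)
        evals <- evals + 1L
        if (fc < f) {
          par <- cand
          f <- fc
          trace <- c(trace, f)
          improved <- TRUE
          break
        }
      }
      if (improved || evals >= budget) break
    }
    if (improved) mesh <- min(mesh * expand, 0.5)
    else mesh <- mesh * contract
  }
  list(par = par, value = f, trace = trace, evals = evals, mesh = mesh)
}
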