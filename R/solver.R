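#' Solve a bounded linear program
#'
#' Minimal LP interface used by all flux computations: optimize `obj %*% v`
#' subject to steady-state mass balance `S v = b` and box bounds
#' `lb <= v <= ub`. Solved by a bounded-variable two-phase primal simplex
#' (compiled); suitable for the small and medium problems produced by the
#' synthetic network generators.
#'
#' @param S constraint matrix (rows = metabolites, columns = reactions);
#'   dense or `Matrix` sparse.
#' @param obj objective coefficient vector, length `ncol(S)`.
#' @param lb,ub bound vectors, length `ncol(S)`; may contain `-Inf`/`Inf`.
#' @param b right-hand side, length `nrow(S)` (default all zero:
#'   steady state).
#' @param direction `"max"` or `"min"`.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   or a solver failure code), `objective` and the primal solution `x`
#'   (both `NA` unless optimal).
#' @export
solve_lp <- function(S, obj, lb, ub, b = NULL,
                     direction = c("max", "min"), tol = 1e-9) {
  direction <- match.arg(direction)
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("infeasible bounds: lb > ub")
  if (is.null(b)) b <- numeric(nrow(S))
  cc <- if (direction == "max") -as.numeric(obj) else as.numeric(obj)
  res <- .simplex_cpp(S, as.numeric(b), cc, as.numeric(lb), as.numeric(ub),
                      tol = tol)
  if (!identical(res$status, "optimal")) {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  objective <- if (direction == "max") -res$objective else res$objective
  x <- as.numeric(res$x)
  names(x) <- colnames(S)
  list(status = "optimal", objective = objective, x = x)
}
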