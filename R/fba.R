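effective_bounds <- function(model, caps = NULL) {
  lb <- stats::setNames(model$reactions$lb, model$reactions$id)
  ub <- stats::setNames(model$reactions$ub, model$reactions$id)
  if (!is.null(caps)) {
    ids <- intersect(names(caps$lb), names(lb))
    lb[ids] <- pmax(lb[ids], caps$lb[ids])
    ub[ids] <- pmin(ub[ids], caps$ub[ids])
    if (any(lb > ub + 1e-12))
      stop("caps conflict with model bounds (lb > ub) for: ",
           paste(utils::head(names(lb)[lb > ub + 1e-12], 5), collapse = ", "))
    lb <- pmin(lb, ub)
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to
#' steady-state mass balance and the model's bounds, optionally intersected
#' with additional flux caps. Infeasible and unbounded problems raise
#' distinct errors naming the objective.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction id to optimize (default: the biomass reaction).
#' @param direction `"max"` or `"min"`.
#' @param caps optional caps from [wildtype_caps()]/[restrict_gene()];
#'   intersected with (never widening) the native bounds.
#' @return list with `objective` (optimal value) and `fluxes` (named
#'   vector over all reactions).
#' @export
fba <- function(model, objective = model$biomass_id,
                direction = c("max", "min"), caps = NULL) {
  direction <- match.arg(direction)
  if (!objective %in% model$reactions$id)
    stop("objective reaction not in model: ", objective)
  bnd <- effective_bounds(model, caps)
  obj <- as.numeric(model$reactions$id == objective)
  sol <- solve_lp(model$S, obj, bnd$lb, bnd$ub, direction = direction)
  if (sol$status == "infeasible")
    stop("FBA infeasible (objective ", objective, ")")
  if (sol$status == "unbounded")
    stop("FBA unbounded (objective ", objective, ")")
  if (sol$status != "optimal")
    stop("LP solver failed with status '", sol$status,
         "' (objective ", objective, ")")
  list(objective = sol$objective, fluxes = sol$x)
}

#' Parsimonious flux balance analysis (pFBA)
#'
#' Two-stage solve: (1) maximize the objective reaction; (2) fix the
#' objective at its optimum (within a small tolerance band) and minimize
#' the sum of absolute fluxes via nonnegative forward/reverse flux
#' splitting. The result approximates efficient enzyme usage and serves as
#' the wildtype flux distribution.
#'
#' @inheritParams fba
#' @param fix_tol relative half-width of the objective-fixing band.
#' @return list with `objective` (stage-1 optimum), `fluxes` (named pFBA
#'   flux vector) and `total_flux` (minimized sum of absolute fluxes).
#' @export
pfba <- function(model, objective = model$biomass_id, caps = NULL,
                 fix_tol = 1e-9) {
  stage1 <- fba(model, objective, "max", caps)
  opt <- stage1$objective

  bnd <- effective_bounds(model, caps)
  n <- nrow(model$reactions)
  ids <- model$reactions$id
  S <- as.matrix(model$S)

  # v = f - r, f/r >= 0; bounds mapped per reaction sign pattern
  f_lb <- pmax(bnd$lb, 0);  f_ub <- pmax(bnd$ub, 0)
  r_lb <- pmax(-bnd$ub, 0); r_ub <- pmax(-bnd$lb, 0)

  A <- cbind(S, -S)
  obj_row <- c(as.numeric(ids == objective), -as.numeric(ids == objective))
  band <- fix_tol * max(1, abs(opt))
  # auxiliary variable pins the objective inside [opt - band, opt + band]
  A <- rbind(cbind(A, 0), c(obj_row, -1))
  lbv <- c(f_lb, r_lb, opt - band)
  ubv <- c(f_ub, r_ub, opt + band)
  cost <- c(rep(1, 2 * n), 0)
  b <- numeric(nrow(A))

  sol <- solve_lp(A, cost, lbv, ubv, b = b, direction = "min")
  if (sol$status != "optimal")
    stop("pFBA stage 2 failed with status '", sol$status,
         "' after fixing objective at ", opt,
         " — check solver tolerances")
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  names(v) <- ids
  list(objective = opt, fluxes = v, total_flux = sum(abs(v)))
}

#' Wildtype flux caps
#'
#' Converts a wildtype flux distribution into sign-respecting per-reaction
#' caps: a forward wildtype flux `v` yields `[0, v]`, a reverse flux
#' `[v, 0]`, and a zero flux pins the reaction to exactly 0. Under these
#' caps fluxes may only shrink in magnitude relative to the wildtype —
#' no rerouting through alternative pathways.
#'
#' @param wt named wildtype flux vector (e.g. `pfba(...)$fluxes`).
#' @return object of class `flux_caps`: list with named vectors `lb`, `ub`.
#' @export
wildtype_caps <- function(wt) {
  structure(list(lb = pmin(wt, 0), ub = pmax(wt, 0)), class = "flux_caps")
}

#' Restrict a gene's reactions to a fraction of wildtype capacity
#'
#' Simulates a partial loss-of-function allele: every reaction that
#' requires the gene (see [gene_constrained_reactions()]) has its flux
#' capped at `fraction` times the absolute wildtype flux, keeping the
#' wildtype direction. `fraction = 1` returns the caps unchanged;
#' `fraction = 0` is a full knockout.
#'
#' @param caps `flux_caps` to start from (usually [wildtype_caps()]).
#' @param model a [metabolic_model()].
#' @param gene gene id.
#' @param fraction remaining capacity, in `[0, 1]`.
#' @param wt wildtype flux vector the caps derive from.
#' @return modified `flux_caps`.
#' @export
restrict_gene <- function(caps, model, gene, fraction, wt) {
  stopifnot(fraction >= 0, fraction <= 1)
  rxns <- gene_constrained_reactions(model, gene)
  for (r in rxns) {
    v <- unname(wt[r])
    if (is.na(v)) stop("wildtype flux missing for reaction ", r)
    if (v >= 0) { caps$lb[r] <- 0;            caps$ub[r] <- fraction * v }
    else        { caps$lb[r] <- fraction * v; caps$ub[r] <- 0 }
  }
  caps
}
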