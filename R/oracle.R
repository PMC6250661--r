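# Brute-force oracle: an independent, deliberately naive implementation of
# the pleiotropy calculations. Every quantity is recomputed from the raw
# model with a fresh LP per component per capacity fraction — no caching,
# no warm starts, no shared state with the engine in pleiotropy.R — so
# engine results can be checked against it on small fixtures. GPR
# essentiality is decided by evaluating the raw rule string as an R
# boolean expression rather than through the package's parser.

oracle_gpr_essential <- function(gpr, gene) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(FALSE)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|&&|\\|\\||&|\\||[^\\s()&|]+",
                                   gpr, perl = TRUE))[[1]]
  expr <- vapply(toks, function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "&"
    else if (tl %in% c("or", "|", "||")) "|"
    else if (t %in% c("(", ")")) t
    else if (identical(t, gene)) "FALSE"
    else "TRUE"
  }, character(1), USE.NAMES = FALSE)
  !isTRUE(eval(parse(text = paste(expr, collapse = " "))))
}

# reactions the gene constrains, by raw rule evaluation
oracle_constrained <- function(model, gene) {
  hit <- vapply(model$reactions$gpr, oracle_gpr_essential, logical(1),
                gene = gene, USE.NAMES = FALSE)
  model$reactions$id[hit]
}

# max c'v s.t. Sv = 0, lb <= v <= ub; dense, built from scratch
oracle_max <- function(S, lb, ub, objcol) {
  obj <- numeric(ncol(S)); obj[objcol] <- 1
  sol <- solve_lp(S, obj, lb, ub, direction = "max")
  if (sol$status != "optimal") stop("oracle LP not optimal: ", sol$status)
  sol
}

# independent pFBA: maximize biomass, then minimize total flux via split
oracle_wildtype <- function(model) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  ibm <- match(model$biomass_id, model$reactions$id)
  opt <- oracle_max(S, lb, ub, ibm)$objective

  n <- ncol(S)
  A <- cbind(S, -S)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  # pin biomass at the optimum
  lb2[ibm] <- max(lb2[ibm], opt - 1e-9 * max(1, abs(opt)))
  ub2[ibm] <- min(ub2[ibm], opt + 1e-9 * max(1, abs(opt)))
  sol <- solve_lp(A, rep(1, 2 * n), lb2, ub2, direction = "min")
  if (sol$status != "optimal") stop("oracle pFBA failed: ", sol$status)
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  names(v) <- model$reactions$id
  list(v = v, biomass = opt)
}

# stoichiometric matrix with one secretion exchange appended per component
oracle_ext <- function(model, comps) {
  S <- as.matrix(model$S)
  E <- matrix(0, nrow(S), length(comps))
  E[cbind(match(comps, rownames(S)), seq_along(comps))] <- -1
  cbind(S, E)
}

# max production of component `ci` (index into comps) with given caps on
# the original reactions; added exchanges free in [0, Inf). `Sx` may be
# passed to avoid rebuilding the constant extended matrix (the LP itself
# is still solved from scratch).
oracle_comp_max <- function(model, comps, ci, lb, ub, Sx = NULL) {
  if (is.null(Sx)) Sx <- oracle_ext(model, comps)
  n0 <- nrow(model$reactions)
  lbx <- c(lb, rep(0, length(comps)))
  ubx <- c(ub, rep(Inf, length(comps)))
  oracle_max(Sx, lbx, ubx, n0 + ci)$objective
}

eq1_caps <- function(v) list(lb = pmin(v, 0), ub = pmax(v, 0))

#' Brute-force pleiotropy profile (test oracle)
#'
#' Recomputes a gene's pleiotropy profile from scratch: one independent LP
#' per biomass component per capacity fraction, with no shared state.
#' Intended for validating the engine on small fixtures.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id.
#' @param fractions decreasing capacity-fraction grid.
#' @param exclude biomass-component exclusions.
#' @param threshold,floor counting rule parameters (see
#'   [build_reference()]).
#' @return list with `count` (per fraction), `steps`, `ko_pleiotropy`,
#'   `affected` (list of component id sets).
#' @export
oracle_profile <- function(model, gene, fractions = seq(1, 0, by = -0.005),
                           exclude = character(0),
                           threshold = 1e-4, floor = 1e-9) {
  comps <- biomass_components(model, exclude)$id
  wt <- oracle_wildtype(model)
  caps <- eq1_caps(wt$v)
  Sx <- oracle_ext(model, comps)
  wt_max <- vapply(seq_along(comps), function(ci)
    oracle_comp_max(model, comps, ci, caps$lb, caps$ub, Sx), numeric(1))
  rxns <- oracle_constrained(model, gene)
  idx <- match(rxns, model$reactions$id)

  aff <- lapply(fractions, function(f) {
    lbf <- caps$lb; ubf <- caps$ub
    for (i in idx) {
      v <- wt$v[i]
      if (v >= 0) { lbf[i] <- 0; ubf[i] <- f * v }
      else        { lbf[i] <- f * v; ubf[i] <- 0 }
    }
    hit <- vapply(seq_along(comps), function(ci) {
      if (wt_max[ci] <= floor) return(FALSE)
      mm <- oracle_comp_max(model, comps, ci, lbf, ubf, Sx)
      mm < (1 - threshold) * wt_max[ci]
    }, logical(1))
    comps[hit]
  })
  counts <- lengths(aff)
  list(count = as.integer(counts), steps = as.integer(sum(diff(counts) > 0)),
       ko_pleiotropy = as.integer(counts[length(counts)]), affected = aff)
}

#' Brute-force knockout essentiality count (test oracle)
#'
#' Native model bounds throughout; the gene's reactions are capped at the
#' wildtype flux for the baseline and at `fraction` of it for the mutant.
#'
#' @inheritParams oracle_profile
#' @param fraction remaining capacity.
#' @return integer count of affected components.
#' @export
oracle_essentiality <- function(model, gene, fraction = 0,
                                exclude = character(0),
                                threshold = 1e-4, floor = 1e-9) {
  comps <- biomass_components(model, exclude)$id
  wt <- oracle_wildtype(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  rxns <- oracle_constrained(model, gene)
  idx <- match(rxns, model$reactions$id)
  capped <- function(f) {
    lbf <- lb; ubf <- ub
    for (i in idx) {
      v <- wt$v[i]
      if (v >= 0) { lbf[i] <- 0; ubf[i] <- f * v }
      else        { lbf[i] <- f * v; ubf[i] <- 0 }
    }
    list(lb = lbf, ub = ubf)
  }
  b1 <- capped(1); bf <- capped(fraction)
  Sx <- oracle_ext(model, comps)
  sum(vapply(seq_along(comps), function(ci) {
    base <- oracle_comp_max(model, comps, ci, b1$lb, b1$ub, Sx)
    if (base <= floor) return(FALSE)
    mm <- oracle_comp_max(model, comps, ci, bf$lb, bf$ub, Sx)
    mm < (1 - threshold) * base
  }, logical(1)))
}

#' Brute-force knockout table for all genes (test oracle / ground truth)
#'
#' @param model a [metabolic_model()].
#' @param exclude biomass-component exclusions.
#' @return data.frame with `gene`, `ko_pleiotropy`, `essentiality`.
#' @export
oracle_ko_table <- function(model, exclude = character(0)) {
  comps <- biomass_components(model, exclude)$id
  wt <- oracle_wildtype(model)
  caps <- eq1_caps(wt$v)
  Sx <- oracle_ext(model, comps)
  wt_max <- vapply(seq_along(comps), function(ci)
    oracle_comp_max(model, comps, ci, caps$lb, caps$ub, Sx), numeric(1))

  rows <- lapply(model$genes, function(g) {
    rxns <- oracle_constrained(model, g)
    idx <- match(rxns, model$reactions$id)
    lb0 <- caps$lb; ub0 <- caps$ub
    lb0[idx] <- 0; ub0[idx] <- 0
    kp <- sum(vapply(seq_along(comps), function(ci) {
      if (wt_max[ci] <= 1e-9) return(FALSE)
      oracle_comp_max(model, comps, ci, lb0, ub0, Sx) <
        (1 - 1e-4) * wt_max[ci]
    }, logical(1)))
    data.frame(gene = g, ko_pleiotropy = kp,
               essentiality = oracle_essentiality(model, g, 0, exclude),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
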