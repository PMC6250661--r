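#' Build the wildtype reference for pleiotropy analysis
#'
#' Runs pFBA on the model to obtain the wildtype flux distribution, derives
#' sign-respecting wildtype flux caps, appends one secretion exchange per
#' biomass component (flux >= 0, unbounded above, so all other components
#' may be excreted freely while one is maximized), and records each
#' component's maximal production rate under the wildtype caps.
#'
#' Components whose wildtype maximum is (numerically) zero are recorded but
#' can never register a reduction.
#'
#' @param model a [metabolic_model()].
#' @param exclude metabolite ids excluded from the biomass component set
#'   (inorganic ions, water).
#' @param components optional data.frame as returned by
#'   [biomass_components()]; computed from the model when `NULL`.
#' @param threshold relative production-reduction threshold; the default
#'   `1e-4` counts a component as affected when its maximum drops by at
#'   least 0.01%.
#' @param floor absolute floor below which a wildtype maximum is treated
#'   as zero.
#' @return object of class `wildtype_reference` with elements `model`
#'   (original), `model_ext` (with secretion exchanges), `wt` (pFBA
#'   fluxes), `caps`, `components`, `comp_exchange` (component ->
#'   secretion reaction id), `comp_max` (wildtype per-component maxima),
#'   `biomass_max`, `threshold`, `floor`.
#' @export
build_reference <- function(model, exclude = character(0),
                            components = NULL,
                            threshold = 1e-4, floor = 1e-9) {
  if (is.null(components)) components <- biomass_components(model, exclude)
  wt <- pfba(model)
  caps <- wildtype_caps(wt$fluxes)

  ext <- model
  comp_exchange <- character(nrow(components))
  names(comp_exchange) <- components$id
  for (cid in components$id) {
    rid <- paste0("EXC_", cid)
    k <- 1L
    while (rid %in% ext$reactions$id) { rid <- paste0("EXC_", cid, "_", k); k <- k + 1L }
    ext <- add_reaction(ext, rid, stats::setNames(-1, cid), lb = 0, ub = Inf)
    comp_exchange[cid] <- rid
  }

  comp_max <- vapply(components$id, function(cid) {
    fba(ext, comp_exchange[[cid]], "max", caps = caps)$objective
  }, numeric(1))

  structure(list(model = model, model_ext = ext, wt = wt$fluxes,
                 caps = caps, components = components,
                 comp_exchange = comp_exchange, comp_max = comp_max,
                 biomass_max = wt$objective,
                 threshold = threshold, floor = floor),
            class = "wildtype_reference")
}

#' @export
print.wildtype_reference <- function(x, ...) {
  cat(sprintf("<wildtype_reference: %d biomass components, biomass max %.6g, %d scorable (wildtype max > 0)>\n",
              nrow(x$components), x$biomass_max,
              sum(x$comp_max > x$floor)))
  invisible(x)
}

# which components lose >= threshold of their wildtype maximum under caps
affected_components <- function(ref, caps) {
  scorable <- names(ref$comp_max)[ref$comp_max > ref$floor]
  hit <- vapply(scorable, function(cid) {
    mm <- fba(ref$model_ext, ref$comp_exchange[[cid]], "max",
              caps = caps)$objective
    mm < (1 - ref$threshold) * ref$comp_max[[cid]]
  }, logical(1))
  scorable[hit]
}

#' Pleiotropy of one allele of one gene
#'
#' Restricts the gene's reactions to `fraction` of their wildtype flux
#' (keeping all other wildtype caps) and counts the biomass components
#' whose maximal production falls at least 0.01% (the reference
#' `threshold`) below the wildtype maximum.
#'
#' @param ref a [build_reference()] object.
#' @param gene gene id.
#' @param fraction remaining capacity in `[0, 1]`.
#' @return list with `count` and `affected` (component ids).
#' @export
allele_pleiotropy <- function(ref, gene, fraction) {
  caps <- restrict_gene(ref$caps, ref$model, gene, fraction, ref$wt)
  if (identical(caps$lb, ref$caps$lb) && identical(caps$ub, ref$caps$ub))
    return(list(count = 0L, affected = character(0)))
  aff <- affected_components(ref, caps)
  list(count = length(aff), affected = aff)
}

#' Allele sweep: pleiotropy profile over the capacity-fraction grid
#'
#' Evaluates [allele_pleiotropy()] on a grid of capacity fractions from
#' 100% down to 0% (default step 0.5%, i.e. 201 points) and counts the
#' pleiotropy steps: grid transitions at which the count strictly
#' increases as the allele becomes more severe.
#'
#' Because the caps shrink monotonically as the fraction decreases, each
#' component's "affected" status flips exactly once along the grid; the
#' default `method = "bisect"` locates that flip by binary search per
#' component (identical result to evaluating every grid point, which
#' `method = "grid"` does).
#'
#' @param ref a [build_reference()] object.
#' @param gene gene id.
#' @param fractions decreasing fraction grid (default `seq(1, 0, -0.005)`).
#' @param method `"bisect"` (default) or `"grid"`.
#' @return object of class `pleiotropy_profile`: list with `gene`,
#'   `fractions`, `count` (per grid point), `affected` (list of component
#'   id vectors per grid point), `steps`, `ko_pleiotropy`.
#' @export
sweep_gene <- function(ref, gene, fractions = seq(1, 0, by = -0.005),
                       method = c("bisect", "grid")) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(rev(fractions)))
  np <- length(fractions)
  scorable <- names(ref$comp_max)[ref$comp_max > ref$floor]

  rxns <- gene_constrained_reactions(ref$model, gene)
  active <- rxns[abs(ref$wt[rxns]) > ref$floor]
  if (length(active) == 0) {
    # the gene carries no wildtype flux: restriction can never bind
    counts <- integer(np)
    aff <- rep(list(character(0)), np)
  } else if (method == "grid") {
    aff <- lapply(fractions, function(f)
      allele_pleiotropy(ref, gene, f)$affected)
    counts <- lengths(aff)
  } else {
    affected_at <- function(cid, idx) {
      caps <- restrict_gene(ref$caps, ref$model, gene, fractions[idx], ref$wt)
      mm <- fba(ref$model_ext, ref$comp_exchange[[cid]], "max",
                caps = caps)$objective
      mm < (1 - ref$threshold) * ref$comp_max[[cid]]
    }
    # first grid index (fractions descending) at which the component is
    # affected; np + 1 when never affected
    first_idx <- vapply(scorable, function(cid) {
      if (!affected_at(cid, np)) return(np + 1L)
      lo <- 1L; hi <- np   # invariant: !affected(lo) (fraction 1), affected(hi)
      if (affected_at(cid, 1L)) return(1L)
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (affected_at(cid, mid)) hi <- mid else lo <- mid
      }
      hi
    }, integer(1))
    aff <- lapply(seq_len(np), function(i) scorable[first_idx <= i])
    counts <- lengths(aff)
  }

  steps <- sum(diff(counts) > 0)
  structure(list(gene = gene, fractions = fractions,
                 count = as.integer(counts), affected = aff,
                 steps = as.integer(steps),
                 ko_pleiotropy = as.integer(counts[np])),
            class = "pleiotropy_profile")
}

#' @export
print.pleiotropy_profile <- function(x, ...) {
  cat(sprintf("<pleiotropy_profile %s: knockout pleiotropy %d, %d steps over %d grid points>\n",
              x$gene, x$ko_pleiotropy, x$steps, length(x$fractions)))
  invisible(x)
}

# per-gene essentiality baseline: native bounds, gene at full wildtype
# capacity (fraction 1); so the fraction-1 allele is the baseline itself
essentiality_baseline <- function(ref, gene) {
  caps1 <- restrict_gene(
    structure(list(lb = numeric(0), ub = numeric(0)), class = "flux_caps"),
    ref$model, gene, 1, ref$wt)
  vapply(names(ref$comp_max), function(cid) {
    fba(ref$model_ext, ref$comp_exchange[[cid]], "max",
        caps = caps1)$objective
  }, numeric(1))
}

#' Essentiality count of an allele (free flux redistribution)
#'
#' Counts the biomass components for which the gene product is essential
#' after the mutant is allowed to adapt: fluxes are free within native
#' model bounds (no wildtype caps), only the gene's own reactions are
#' capped at `fraction` of their absolute wildtype flux. The comparison
#' baseline is the same computation at fraction 1, so an unrestricted
#' allele is never counted.
#'
#' @inheritParams allele_pleiotropy
#' @return list with `count` and `affected` (component ids).
#' @export
essentiality_count <- function(ref, gene, fraction) {
  base <- essentiality_baseline(ref, gene)
  capsf <- restrict_gene(
    structure(list(lb = numeric(0), ub = numeric(0)), class = "flux_caps"),
    ref$model, gene, fraction, ref$wt)
  scorable <- names(base)[base > ref$floor]
  aff <- scorable[vapply(scorable, function(cid) {
    mm <- fba(ref$model_ext, ref$comp_exchange[[cid]], "max",
              caps = capsf)$objective
    mm < (1 - ref$threshold) * base[[cid]]
  }, logical(1))]
  list(count = length(aff), affected = aff)
}

#' Pleiotropy of blocking a single reaction
#'
#' Caps one reaction to zero while every other reaction keeps its wildtype
#' cap, and counts affected biomass components. Comparing this to the full
#' gene knockout separates pleiotropy caused by multiple molecular
#' functions (type I) from pleiotropy emerging from a single function
#' (type II).
#'
#' @param ref a [build_reference()] object.
#' @param reaction reaction id of the original model.
#' @return affected-component count (integer).
#' @export
reaction_pleiotropy <- function(ref, reaction) {
  if (!reaction %in% ref$model$reactions$id)
    stop("reaction not in model: ", reaction)
  caps <- ref$caps
  caps$lb[reaction] <- 0
  caps$ub[reaction] <- 0
  length(affected_components(ref, caps))
}

#' Share of gene pleiotropy attributable to a single reaction
#'
#' For a gene constraining two or more reactions with nonzero full-knockout
#' pleiotropy: the maximum single-reaction pleiotropy divided by the full
#' gene-knockout pleiotropy. A ratio near 1 means the gene's pleiotropy is
#' essentially type II (one function, many physiological consequences).
#'
#' @param ref a [build_reference()] object.
#' @param gene gene id.
#' @return list with `ratio`, `gene_pleiotropy`, `reaction_pleiotropy`
#'   (named per-reaction counts); `NULL` when the gene does not qualify
#'   (fewer than 2 constrained reactions or zero knockout pleiotropy).
#' @export
type2_share <- function(ref, gene) {
  rxns <- gene_constrained_reactions(ref$model, gene)
  if (length(rxns) < 2) return(NULL)
  gp <- allele_pleiotropy(ref, gene, 0)$count
  if (gp == 0) return(NULL)
  rp <- vapply(rxns, function(r) reaction_pleiotropy(ref, r), numeric(1))
  list(ratio = max(rp) / gp, gene_pleiotropy = gp, reaction_pleiotropy = rp)
}

#' Aggregate type-II pleiotropy share over qualifying genes
#'
#' @param ref a [build_reference()] object.
#' @param genes genes to consider (default: all model genes).
#' @return list with `mean_of_ratios`, `ratio_of_sums`, and the per-gene
#'   table `per_gene` (gene, gene_pleiotropy, max_reaction_pleiotropy,
#'   ratio).
#' @export
type2_aggregate <- function(ref, genes = ref$model$genes) {
  rows <- list()
  for (g in genes) {
    ts <- type2_share(ref, g)
    if (is.null(ts)) next
    rows[[g]] <- data.frame(gene = g,
                            gene_pleiotropy = ts$gene_pleiotropy,
                            max_reaction_pleiotropy = max(ts$reaction_pleiotropy),
                            ratio = ts$ratio, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(mean_of_ratios = NA_real_, ratio_of_sums = NA_real_,
                per_gene = data.frame()))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(mean_of_ratios = mean(tab$ratio),
       ratio_of_sums = sum(tab$max_reaction_pleiotropy) /
                       sum(tab$gene_pleiotropy),
       per_gene = tab)
}

#' Classify genes by fitness contribution and knockout pleiotropy
#'
#' A gene is fitness-contributing when its full knockout (under wildtype
#' caps) reduces the maximal biomass production rate by at least the
#' reference threshold. Fitness-contributing genes are further classified
#' by full-knockout pleiotropy: 0 affected components (possible for, e.g.,
#' transporters whose loss hurts biomass but no single component), exactly
#' 1, 2 or more, or all components.
#'
#' @param ref a [build_reference()] object.
#' @param genes genes to classify (default: all model genes).
#' @return data.frame with columns `gene`, `fitness_contributing`,
#'   `ko_pleiotropy`, `class` (one of `"no_effect"`, `"pleiotropy_0"`,
#'   `"pleiotropy_1"`, `"pleiotropic"`, `"all_components"`).
#' @export
classify_genes <- function(ref, genes = ref$model$genes) {
  ncomp_scorable <- nrow(ref$components)
  rows <- lapply(genes, function(g) {
    caps0 <- restrict_gene(ref$caps, ref$model, g, 0, ref$wt)
    bm <- fba(ref$model_ext, ref$model$biomass_id, "max",
              caps = caps0)$objective
    fit <- bm < (1 - ref$threshold) * ref$biomass_max &&
           ref$biomass_max > ref$floor
    kp <- allele_pleiotropy(ref, g, 0)$count
    cls <- if (!fit) "no_effect"
           else if (kp == 0) "pleiotropy_0"
           else if (kp == 1) "pleiotropy_1"
           else if (kp == ncomp_scorable) "all_components"
           else "pleiotropic"
    data.frame(gene = g, fitness_contributing = fit,
               ko_pleiotropy = kp, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
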