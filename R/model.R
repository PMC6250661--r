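#' Construct a constraint-based metabolic model
#'
#' The in-memory container used throughout the package: a stoichiometric
#' matrix, reaction bounds, GPR rules and a designated biomass reaction.
#' Exchange reactions are those with a single nonzero stoichiometric entry
#' (boundary reactions).
#'
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`
#'   (GPR rule string, `""` if none).
#' @param stoich list mapping reaction id to a named numeric vector of
#'   stoichiometric coefficients (negative = substrate), or a
#'   metabolites-by-reactions matrix with dimnames.
#' @param biomass_id reaction id of the biomass pseudo-reaction.
#' @param metabolites optional data.frame with columns `id`, `compartment`;
#'   derived from `stoich` when omitted.
#' @param id model identifier string.
#' @return object of class `metabolic_model` with elements `S` (sparse
#'   metabolites x reactions matrix), `reactions`, `metabolites`, `genes`,
#'   `gpr` (parsed rule trees, by reaction id) and `biomass_id`.
#' @export
metabolic_model <- function(reactions, stoich, biomass_id,
                            metabolites = NULL, id = "model") {
  stopifnot(is.data.frame(reactions),
            all(c("id", "lb", "ub", "gpr") %in% names(reactions)))
  reactions$id <- as.character(reactions$id)
  reactions$gpr <- as.character(reactions$gpr)
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (any(reactions$lb > reactions$ub)) stop("reaction bounds violate lb <= ub")

  if (is.list(stoich) && !is.data.frame(stoich)) {
    mets <- unique(unlist(lapply(stoich, names)))
    S <- Matrix::Matrix(0, nrow = length(mets), ncol = nrow(reactions),
                        sparse = TRUE,
                        dimnames = list(mets, reactions$id))
    for (rid in names(stoich)) {
      v <- stoich[[rid]]
      v <- v[v != 0]
      if (length(v)) S[names(v), rid] <- v
    }
  } else {
    S <- Matrix::Matrix(as.matrix(stoich), sparse = TRUE)
    if (is.null(rownames(S)) || is.null(colnames(S)))
      stop("stoichiometric matrix needs dimnames")
    S <- S[, reactions$id, drop = FALSE]
  }

  if (!biomass_id %in% reactions$id)
    stop("biomass reaction not in model: ", biomass_id)

  if (is.null(metabolites)) {
    metabolites <- data.frame(id = rownames(S),
                              compartment = "c",
                              stringsAsFactors = FALSE)
  }

  gpr <- lapply(stats::setNames(reactions$gpr, reactions$id), function(g) {
    tryCatch(parse_gpr(g),
             error = function(e) stop("unparsable GPR: ", conditionMessage(e)))
  })
  genes <- sort(unique(unlist(lapply(gpr, gpr_genes))))

  structure(list(id = id, S = S, reactions = reactions,
                 metabolites = metabolites, genes = genes,
                 gpr = gpr, biomass_id = biomass_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d reactions, %d metabolites, %d genes; biomass = %s>\n",
              x$id, nrow(x$reactions), nrow(x$metabolites),
              length(x$genes), x$biomass_id))
  invisible(x)
}

#' Reaction ids of exchange (boundary) reactions
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$S != 0)
  model$reactions$id[nz <= 1L]
}

#' Biomass components of a model
#'
#' The substrates (negative-coefficient species) of the biomass
#' pseudo-reaction, minus an exclusion list (typically inorganic ions and
#' water, which are not informative traits). Each component is one
#' phenotypic trait in the pleiotropy analysis.
#'
#' @param model a `metabolic_model`.
#' @param exclude metabolite ids to drop from the component set.
#' @return data.frame with columns `id` and `coefficient` (the positive
#'   stoichiometric demand per unit biomass flux).
#' @export
biomass_components <- function(model, exclude = character(0)) {
  col <- model$S[, model$biomass_id]
  subs <- col[col < 0]
  keep <- setdiff(names(subs), exclude)
  if (length(keep) == 0)
    stop("biomass reaction has no substrate components after exclusions")
  data.frame(id = keep, coefficient = -as.numeric(subs[keep]),
             stringsAsFactors = FALSE)
}

#' Reactions whose catalysis requires a given gene
#'
#' A reaction is constrained by a gene when the gene is boolean-essential
#' for its GPR rule: setting the gene to absent with all other genes
#' present makes the rule false. Reactions listing the gene only as one of
#' several isoenzymes (an `or` alternative) are therefore not constrained.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id.
#' @return character vector of reaction ids (possibly empty).
#' @export
gene_constrained_reactions <- function(model, gene) {
  if (!gene %in% model$genes)
    stop("unknown gene '", gene, "'; model genes: ",
         paste(utils::head(model$genes, 20), collapse = ", "))
  hit <- vapply(model$gpr, gpr_gene_essential, logical(1), gene = gene)
  model$reactions$id[hit]
}

#' Add a reaction to a model
#'
#' Used to append biomass-component secretion exchanges and free-cofactor
#' interconversion reactions. New metabolite ids appearing in `stoich` are
#' added to the model (compartment `"c"`).
#'
#' @param model a `metabolic_model`.
#' @param id new reaction id (must not collide).
#' @param stoich named numeric vector, metabolite id -> coefficient.
#' @param lb,ub flux bounds.
#' @param gpr GPR rule string (default none).
#' @return the extended `metabolic_model`.
#' @export
add_reaction <- function(model, id, stoich, lb, ub, gpr = "") {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  new_mets <- setdiff(names(stoich), rownames(model$S))
  S <- model$S
  if (length(new_mets)) {
    pad <- Matrix::Matrix(0, nrow = length(new_mets), ncol = ncol(S),
                          sparse = TRUE,
                          dimnames = list(new_mets, colnames(S)))
    S <- rbind(S, pad)
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, compartment = "c", stringsAsFactors = FALSE))
  }
  newcol <- Matrix::Matrix(0, nrow = nrow(S), ncol = 1, sparse = TRUE,
                           dimnames = list(rownames(S), id))
  newcol[names(stoich), 1] <- stoich
  model$S <- cbind(S, newcol)
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, lb = lb, ub = ub, gpr = gpr,
               stringsAsFactors = FALSE))
  model$gpr[[id]] <- parse_gpr(gpr)
  model$genes <- sort(unique(c(model$genes, gpr_genes(model$gpr[[id]]))))
  model
}
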