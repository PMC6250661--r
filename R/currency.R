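#' Make a cofactor freely available
#'
#' Adds a reversible, unbounded reaction interconverting the charged
#' (activated) and discharged form of a currency metabolite, e.g.
#' `NADPH <-> NADP+ + H+ + 2 e-`, so the cofactor's regeneration can never
#' limit production. Balancing species (protons, an electron pseudo-species)
#' appear on the discharged side; any balancing species absent from the
#' model is added together with its own free boundary exchange, so the
#' interconversion stays balanced.
#'
#' When `charged`/`discharged` are vectors (one id per compartment
#' instance), an interconversion reaction is added for every pair whose
#' two species both exist in the model.
#'
#' @param model a [metabolic_model()].
#' @param charged species id(s) of the activated form.
#' @param discharged species id(s) of the inactivated form (same length).
#' @param balancing named numeric vector of balancing species produced
#'   alongside the discharged form (e.g. `c(h = 1, e_pseudo = 2)`).
#' @param name short cofactor name used in new reaction ids.
#' @return the extended `metabolic_model`.
#' @export
add_free_cofactor <- function(model, charged, discharged,
                              balancing = NULL, name = charged[1]) {
  stopifnot(length(charged) == length(discharged))
  added <- 0L
  tried <- character(0)
  for (i in seq_along(charged)) {
    ch <- charged[i]; dis <- discharged[i]
    tried <- c(tried, paste0(ch, "/", dis))
    if (!(ch %in% rownames(model$S)) || !(dis %in% rownames(model$S))) next
    if (!is.null(balancing) && length(balancing)) {
      for (bsp in setdiff(names(balancing), rownames(model$S))) {
        # boundary pseudo-species with a free exchange
        model <- add_reaction(model, paste0("EXF_", bsp),
                              stats::setNames(-1, bsp), lb = -Inf, ub = Inf)
      }
    }
    st <- stats::setNames(c(-1, 1), c(ch, dis))
    if (!is.null(balancing) && length(balancing))
      st <- c(st, balancing)
    rid <- paste0("FREE_", name, if (length(charged) > 1) paste0("_", i) else "")
    model <- add_reaction(model, rid, st, lb = -Inf, ub = Inf)
    added <- added + 1L
  }
  if (added == 0L)
    stop("no compartment instance of cofactor '", name,
         "' found in model (tried: ", paste(tried, collapse = ", "), ")")
  model
}

#' Count non-exchange reactions involving currency metabolites
#'
#' @param model a [metabolic_model()].
#' @param species character vector of currency species ids (all
#'   compartment instances).
#' @return integer count of non-exchange reactions whose stoichiometry
#'   involves at least one listed species.
#' @export
count_currency_reactions <- function(model, species) {
  if (length(species) == 0) return(0L)
  species <- intersect(species, rownames(model$S))
  if (length(species) == 0) return(0L)
  non_ex <- setdiff(model$reactions$id, exchange_reactions(model))
  sub <- model$S[species, non_ex, drop = FALSE]
  sum(Matrix::colSums(sub != 0) > 0)
}

#' Read a currency-metabolite list from a TSV file
#'
#' Expected columns: `name`, `charged`, `discharged` (each possibly a
#' comma-separated list of per-compartment ids) and optionally `balancing`
#' in `species:coef;species:coef` form.
#'
#' @param path TSV file.
#' @return list of cofactor entries usable with [add_free_cofactor()].
#' @export
read_currency_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "charged", "discharged") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    bal <- NULL
    if ("balancing" %in% names(tab) && nzchar(tab$balancing[i]) &&
        !is.na(tab$balancing[i])) {
      parts <- strsplit(tab$balancing[i], ";", fixed = TRUE)[[1]]
      kv <- strsplit(parts, ":", fixed = TRUE)
      bal <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                             vapply(kv, `[`, "", 1))
    }
    list(name = tab$name[i],
         charged = strsplit(tab$charged[i], ",", fixed = TRUE)[[1]],
         discharged = strsplit(tab$discharged[i], ",", fixed = TRUE)[[1]],
         balancing = bal)
  })
}

ko_counts <- function(ref, genes, mode) {
  vapply(genes, function(g) {
    if (mode == "pleiotropy") allele_pleiotropy(ref, g, 0)$count
    else essentiality_count(ref, g, 0)$count
  }, integer(1))
}

#' Currency-metabolite mediation of pleiotropy
#'
#' For each currency metabolite, rebuilds the model with that cofactor
#' freely available (see [add_free_cofactor()]), reruns the whole pipeline
#' from pFBA onward, and reports the fraction of previously pleiotropic
#' genes (baseline full-knockout count >= 2) whose count strictly
#' decreased. Also reports the union over metabolites ("any") and a run
#' with all cofactors freed simultaneously.
#'
#' @param model a [metabolic_model()].
#' @param currency list of cofactor entries (`name`, `charged`,
#'   `discharged`, optional `balancing`), e.g. from [read_currency_list()].
#' @param exclude biomass-component exclusion list passed to
#'   [build_reference()].
#' @param mode `"pleiotropy"` (wildtype-capped) or `"essentiality"`
#'   (free redistribution).
#' @param genes genes to analyze (default: all).
#' @return list with `baseline` (per-gene knockout counts),
#'   `pleiotropic_genes`, `per_metabolite` (data.frame: name,
#'   n_reduced, fraction_reduced), `any_fraction`, `all_free_fraction`,
#'   and `counts` (gene x metabolite matrix of knockout counts).
#' @export
currency_reduction_analysis <- function(model, currency,
                                        exclude = character(0),
                                        mode = c("pleiotropy", "essentiality"),
                                        genes = NULL) {
  mode <- match.arg(mode)
  ref0 <- build_reference(model, exclude)
  if (is.null(genes)) genes <- model$genes
  base <- ko_counts(ref0, genes, mode)
  pleio <- genes[base >= 2L]

  run_variant <- function(m) {
    refm <- build_reference(m, exclude)
    ko_counts(refm, pleio, mode)
  }

  if (length(pleio) == 0) {
    return(list(baseline = base, pleiotropic_genes = character(0),
                per_metabolite = data.frame(name = vapply(currency, `[[`, "", "name"),
                                            n_reduced = 0L,
                                            fraction_reduced = NA_real_),
                any_fraction = NA_real_, all_free_fraction = NA_real_,
                counts = NULL))
  }

  counts <- matrix(NA_integer_, nrow = length(pleio), ncol = length(currency),
                   dimnames = list(pleio,
                                   vapply(currency, `[[`, "", "name")))
  reduced_any <- stats::setNames(rep(FALSE, length(pleio)), pleio)
  per <- data.frame(name = character(0), n_reduced = integer(0),
                    fraction_reduced = numeric(0), stringsAsFactors = FALSE)
  for (cm in currency) {
    m2 <- add_free_cofactor(model, cm$charged, cm$discharged,
                            cm$balancing, cm$name)
    km <- run_variant(m2)
    counts[, cm$name] <- km
    red <- km < base[pleio]
    reduced_any <- reduced_any | red
    per <- rbind(per, data.frame(name = cm$name, n_reduced = sum(red),
                                 fraction_reduced = mean(red),
                                 stringsAsFactors = FALSE))
  }

  m_all <- model
  for (cm in currency)
    m_all <- add_free_cofactor(m_all, cm$charged, cm$discharged,
                               cm$balancing, cm$name)
  k_all <- run_variant(m_all)

  list(baseline = base, pleiotropic_genes = pleio,
       per_metabolite = per,
       any_fraction = mean(reduced_any),
       all_free_fraction = mean(k_all < base[pleio]),
       counts = counts)
}
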