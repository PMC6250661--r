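#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the fbc (version 2) extension — flux bounds
#' as referenced parameters, gene products and `geneProductAssociation`
#' trees — and, as a fallback, legacy COBRA-style SBML Level 2 with
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters and
#' `GENE_ASSOCIATION:` notes. Species flagged `boundaryCondition="true"`
#' are excluded from mass balance, following the COBRA convention.
#'
#' @param path SBML file.
#' @param biomass_id biomass reaction id; when `NULL`, taken from the fbc
#'   active objective. Missing/undeterminable biomass reaction is an error.
#' @return a [metabolic_model()].
#' @export
read_sbml_model <- function(path, biomass_id = NULL) {
  doc <- xml2::read_xml(path)

  ln <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) {
      # namespaced attribute (e.g. fbc:id) — try any prefix
      at <- xml2::xml_attrs(node)
      hit <- grep(paste0("(^|:)", name, "$"), names(at))
      v <- if (length(hit)) at[[hit[1]]] else NA_character_
    }
    v
  }

  model_node <- ln(doc, "model")[[1]]
  model_id <- attr1(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- ln(model_node, "species")
  sp_id <- vapply(sp_nodes, attr1, character(1), "id")
  sp_comp <- vapply(sp_nodes, attr1, character(1), "compartment")
  sp_bnd <- vapply(sp_nodes, attr1, character(1), "boundaryCondition")
  boundary <- !is.na(sp_bnd) & sp_bnd == "true"
  metabolites <- data.frame(id = sp_id[!boundary],
                            compartment = ifelse(is.na(sp_comp[!boundary]),
                                                 "c", sp_comp[!boundary]),
                            stringsAsFactors = FALSE)

  params <- ln(model_node, "parameter")
  pval <- stats::setNames(
    as.numeric(vapply(params, attr1, character(1), "value")),
    vapply(params, attr1, character(1), "id"))

  gp_nodes <- ln(model_node, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lab <- attr1(n, "label")
      if (is.na(lab)) attr1(n, "id") else lab
    }, character(1)),
    vapply(gp_nodes, attr1, character(1), "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr1(node, "geneProduct")
      g <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
      return(g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- ln(model_node, "reaction")
  n <- length(rx_nodes)
  if (n == 0) stop("SBML file contains no reactions: ", path)
  rid <- character(n); lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  stoich <- vector("list", n)

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    rid[i] <- attr1(node, "id")
    rev_ok <- identical(attr1(node, "reversible"), "true")

    # bounds: fbc parameter refs, then kinetic-law parameters, then defaults
    lbp <- attr1(node, "lowerFluxBound"); ubp <- attr1(node, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(pval)) lb[i] <- pval[[lbp]]
    else {
      kl <- ln(node, "parameter")
      kid <- vapply(kl, attr1, character(1), "id")
      lbk <- which(kid == "LOWER_BOUND")
      lb[i] <- if (length(lbk)) as.numeric(attr1(kl[[lbk[1]]], "value"))
               else if (rev_ok) -1000 else 0
    }
    if (!is.na(ubp) && ubp %in% names(pval)) ub[i] <- pval[[ubp]]
    else {
      kl <- ln(node, "parameter")
      kid <- vapply(kl, attr1, character(1), "id")
      ubk <- which(kid == "UPPER_BOUND")
      ub[i] <- if (length(ubk)) as.numeric(attr1(kl[[ubk[1]]], "value"))
               else 1000
    }

    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      lst <- xml2::xml_find_first(node,
        sprintf(".//*[local-name()='%s']", side))
      if (!inherits(lst, "xml_missing")) {
        for (sr in ln(lst, "speciesReference")) {
          sp <- attr1(sr, "species")
          st <- attr1(sr, "stoichiometry")
          st <- if (is.na(st)) 1 else as.numeric(st)
          coef[sp] <- (if (sp %in% names(coef)) coef[[sp]] else 0) + sgn * st
        }
      }
    }
    stoich[[i]] <- coef[names(coef) %in% metabolites$id]

    gpa <- xml2::xml_find_first(node,
      ".//*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      gpr[i] <- gpa_to_string(xml2::xml_children(gpa)[[1]])
    } else {
      notes <- xml2::xml_text(
        xml2::xml_find_first(node, ".//*[local-name()='notes']"))
      m <- regmatches(notes,
        regexpr("GENE[ _]ASSOCIATION:[^<\n]*", notes, perl = TRUE))
      gpr[i] <- if (length(m) && !is.na(m))
        trimws(sub("GENE[ _]ASSOCIATION:", "", m)) else ""
    }
  }
  names(stoich) <- rid

  if (is.null(biomass_id)) {
    fo <- xml2::xml_find_first(model_node,
      ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) biomass_id <- attr1(fo, "reaction")
  }
  if (is.null(biomass_id) || is.na(biomass_id))
    stop("no biomass reaction id given and no fbc objective found in ", path)

  reactions <- data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                          stringsAsFactors = FALSE)
  metabolic_model(reactions, stoich, biomass_id,
                  metabolites = metabolites, id = model_id)
}

#' Write a metabolic model to SBML (Level 3, fbc version 2)
#'
#' Bounds are written as referenced parameters at full double precision
#' (`%.17g`), so numeric round-trips are exact. GPR rules are exported as
#' fbc `geneProductAssociation` trees and the biomass reaction as the
#' active fbc objective.
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('<model id="%s" fbc:strict="true">', esc(model$id)))

  comps <- unique(model$metabolites$compartment)
  out <- c(out, "<listOfCompartments>",
           sprintf('<compartment id="%s" constant="true"/>', esc(comps)),
           "</listOfCompartments>")

  out <- c(out, "<listOfSpecies>",
           sprintf(paste0('<species id="%s" compartment="%s" constant="false" ',
                          'boundaryCondition="false" hasOnlySubstanceUnits="false"/>'),
                   esc(model$metabolites$id), esc(model$metabolites$compartment)),
           "</listOfSpecies>")

  rx <- model$reactions
  out <- c(out, "<listOfParameters>",
           sprintf('<parameter id="bnd_lb_%d" value="%s" constant="true"/>',
                   seq_len(nrow(rx)), num(rx$lb)),
           sprintf('<parameter id="bnd_ub_%d" value="%s" constant="true"/>',
                   seq_len(nrow(rx)), num(rx$ub)),
           "</listOfParameters>")

  if (length(model$genes)) {
    out <- c(out, "<fbc:listOfGeneProducts>",
             sprintf('<fbc:geneProduct fbc:id="gp_%d" fbc:label="%s"/>',
                     seq_along(model$genes), esc(model$genes)),
             "</fbc:listOfGeneProducts>")
  }
  gp_ref <- stats::setNames(sprintf("gp_%d", seq_along(model$genes)),
                            model$genes)

  gpa_xml <- function(tree) {
    if (is.character(tree))
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     gp_ref[[tree]]))
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    inner <- paste(vapply(tree$args, gpa_xml, character(1)), collapse = "")
    sprintf('<%s>%s</%s>', tag, inner, tag)
  }

  out <- c(out, "<listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    col <- model$S[, rid]
    col <- col[col != 0]
    reac <- col[col < 0]; prod <- col[col > 0]
    out <- c(out, sprintf(
      paste0('<reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="bnd_lb_%d" fbc:upperFluxBound="bnd_ub_%d">'),
      esc(rid), if (rx$lb[i] < 0) "true" else "false", i, i))
    if (length(reac)) out <- c(out, "<listOfReactants>",
      sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              esc(names(reac)), num(-as.numeric(reac))), "</listOfReactants>")
    if (length(prod)) out <- c(out, "<listOfProducts>",
      sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              esc(names(prod)), num(as.numeric(prod))), "</listOfProducts>")
    tree <- model$gpr[[rid]]
    if (!is.null(tree))
      out <- c(out, "<fbc:geneProductAssociation>", gpa_xml(tree),
               "</fbc:geneProductAssociation>")
    out <- c(out, "</reaction>")
  }
  out <- c(out, "</listOfReactions>")

  out <- c(out,
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$biomass_id)),
    '</fbc:listOfFluxObjectives>', '</fbc:objective>',
    '</fbc:listOfObjectives>', "</model>", "</sbml>")

  writeLines(out, path)
  invisible(path)
}
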