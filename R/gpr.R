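#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' encodes a protein complex (all subunits required) and `or` encodes
#' isoenzymes or alternative transporters (any one suffices). Accepts
#' `and`/`or` (case-insensitive), `&`/`&&`, `|`/`||` and parentheses.
#'
#' @param text GPR string; `""`/`NA` yield `NULL` (reaction not
#'   gene-associated).
#' @return expression tree: a gene id (character leaf) or
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for empty rules.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)

  toks <- regmatches(text, gregexpr(
    "\\(|\\)|&&|\\|\\||&|\\||[^\\s()&|]+", text, perl = TRUE))[[1]]
  norm <- vapply(toks, function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "AND"
    else if (tl %in% c("or", "|", "||")) "OR"
    else t
  }, character(1), USE.NAMES = FALSE)

  pos <- 1L
  peek <- function() if (pos <= length(norm)) norm[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && peek() == "OR") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && peek() == "AND") {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed GPR rule: ", text)
    if (tk == "(") {
      advance()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("unbalanced parentheses in GPR: ", text)
      advance()
      return(e)
    }
    if (tk %in% c(")", "AND", "OR")) stop("malformed GPR rule: ", text)
    advance()
    tk
  }

  tree <- parse_or()
  if (pos <= length(norm)) stop("trailing tokens in GPR rule: ", text)
  tree
}

#' Genes referenced by a GPR expression tree
#' @param tree result of [parse_gpr()].
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR expression under a gene truth assignment
#'
#' @param tree result of [parse_gpr()].
#' @param state named logical vector; genes absent from `state` default to
#'   `default`.
#' @param default truth value for unlisted genes (default `TRUE`).
#' @return logical: can the reaction be catalyzed?
#' @export
eval_gpr <- function(tree, state, default = TRUE) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) {
    if (tree %in% names(state)) return(unname(state[[tree]]))
    return(default)
  }
  vals <- vapply(tree$args, eval_gpr, logical(1), state = state,
                 default = default)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Is a gene boolean-essential for a GPR rule?
#'
#' A gene is essential for catalysis when the rule evaluates to `FALSE`
#' with that gene absent and every other gene present; i.e. the gene
#' appears alone or only as an obligatory complex member, never merely as
#' one interchangeable isoenzyme.
#'
#' @param tree result of [parse_gpr()].
#' @param gene gene id.
#' @return logical.
#' @export
gpr_gene_essential <- function(tree, gene) {
  if (is.null(tree)) return(FALSE)
  st <- stats::setNames(FALSE, gene)
  !eval_gpr(tree, st, default = TRUE)
}

# render a tree back to a canonical rule string (for SBML export)
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (tree$op == "and") " and " else " or ")
}
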