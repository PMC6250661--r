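#' TOY1: two independent linear pathways
#'
#' Fixed deterministic fixture. An uptake `EX_A` (capacity 10) feeds two
#' single-gene reactions `R1: A -> B1` (gene `g1`) and `R2: A -> B2`
#' (gene `g2`); biomass consumes one B1 and one B2. Maximal biomass is 5
#' with the uptake split 5/5; each gene knockout affects exactly one
#' component.
#'
#' @return a [metabolic_model()].
#' @export
make_toy1 <- function() {
  reactions <- data.frame(
    id  = c("EX_A", "R1", "R2", "BIOMASS"),
    lb  = c(0, 0, 0, 0),
    ub  = c(10, 1000, 1000, 1000),
    gpr = c("", "g1", "g2", ""),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A    = c(A = 1),
    R1      = c(A = -1, B1 = 1),
    R2      = c(A = -1, B2 = 1),
    BIOMASS = c(B1 = -1, B2 = -1))
  metabolic_model(reactions, stoich, "BIOMASS", id = "TOY1")
}

#' TOY2: two pathways coupled through a currency-metabolite cycle
#'
#' Fixed deterministic fixture. A generator reaction
#' `RGEN: A + X -> W + Xa` (gene `gE`) charges the cofactor pair
#' (`Xa` activated, `X` discharged); both producing reactions
#' `R1: A + Xa -> B1 + X` and `R2: A + Xa -> B2 + X` consume it. Uptake
#' capacity 12 gives maximal biomass 3 (4 units of A per biomass). The
#' generator gene `gE` is pleiotropic purely through cofactor supply: its
#' alleles affect both components once capacity falls below half, and none
#' once the cofactor pair is freed.
#'
#' The registered currency pair is available via
#' `attr(model, "currency")`.
#'
#' @return a [metabolic_model()].
#' @export
make_toy2 <- function() {
  reactions <- data.frame(
    id  = c("EX_A", "RGEN", "R1", "R2", "EX_W", "BIOMASS"),
    lb  = c(0, 0, 0, 0, 0, 0),
    ub  = c(12, 1000, 1000, 1000, 1000, 1000),
    gpr = c("", "gE", "g1", "g2", "", ""),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A    = c(A = 1),
    RGEN    = c(A = -1, X = -1, W = 1, Xa = 1),
    R1      = c(A = -1, Xa = -1, B1 = 1, X = 1),
    R2      = c(A = -1, Xa = -1, B2 = 1, X = 1),
    EX_W    = c(W = -1),
    BIOMASS = c(B1 = -1, B2 = -1))
  m <- metabolic_model(reactions, stoich, "BIOMASS", id = "TOY2")
  attr(m, "currency") <- list(
    list(name = "X", charged = "Xa", discharged = "X", balancing = NULL))
  m
}

#' Specification for a random synthetic network
#'
#' @param n_components number of biomass components.
#' @param topology `"linear"` (independent chains), `"branched"` (chains
#'   share a precursor trunk) or `"currency"` (pathways additionally
#'   consume a cofactor charged by a shared generator reaction).
#' @param isoenzymes,complexes allow OR / AND GPR rules on chain steps?
#' @param uptake_budget uptake capacity of the carbon source.
#' @param generator_capacity upper bound of the cofactor generator
#'   (currency topology; `NA` = unbounded).
#' @param cofactor_cost charged-cofactor units consumed per component
#'   produced (currency topology).
#' @param max_chain maximal pathway length per component.
#' @param seed RNG seed (mandatory: networks are reproducible).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_components = 3,
                           topology = c("linear", "branched", "currency"),
                           isoenzymes = TRUE, complexes = TRUE,
                           uptake_budget = 4 * n_components,
                           generator_capacity = NA,
                           cofactor_cost = 1,
                           max_chain = 3, seed = 1) {
  topology <- match.arg(topology)
  structure(list(n_components = n_components, topology = topology,
                 isoenzymes = isoenzymes, complexes = complexes,
                 uptake_budget = uptake_budget,
                 generator_capacity = generator_capacity,
                 cofactor_cost = cofactor_cost,
                 max_chain = max_chain, seed = seed),
            class = "synthetic_spec")
}

#' Generate a random synthetic metabolic network with ground truth
#'
#' Seeded generator producing a feasible model (positive biomass optimum)
#' matching a [synthetic_spec()], together with the brute-force ground
#' truth: per-gene full-knockout pleiotropy and essentiality computed by
#' [oracle_ko_table()], independent of the pipeline engine. Stoichiometric
#' coefficients are small integers (1 or 2) so results remain hand
#' checkable.
#'
#' @param spec a [synthetic_spec()].
#' @param max_retries resampling attempts if a draw is infeasible.
#' @return list with `model` (a [metabolic_model()]) and `truth`
#'   (data.frame: gene, ko_pleiotropy, essentiality).
#' @export
make_random_network <- function(spec, max_retries = 5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in 0:max_retries) {
    set.seed(spec$seed + 1000L * attempt)
    model <- draw_network(spec)
    opt <- tryCatch(fba(model)$objective, error = function(e) 0)
    if (opt > 1e-6) {
      truth <- oracle_ko_table(model)
      return(list(model = model, truth = truth))
    }
  }
  stop("could not draw a feasible network for this spec after ",
       max_retries + 1, " attempts")
}

draw_network <- function(spec) {
  k <- spec$n_components
  gene_n <- 0L
  new_gene <- function() { gene_n <<- gene_n + 1L; sprintf("g%02d", gene_n) }
  draw_gpr <- function() {
    u <- stats::runif(1)
    if (spec$isoenzymes && u < 0.25)
      paste(new_gene(), "or", new_gene())
    else if (spec$complexes && u < 0.5)
      paste(new_gene(), "and", new_gene())
    else new_gene()
  }

  rx_id <- character(0); rx_lb <- numeric(0); rx_ub <- numeric(0)
  rx_gpr <- character(0); stoich <- list()
  add <- function(id, st, lb = 0, ub = 1000, gpr = "") {
    rx_id <<- c(rx_id, id); rx_lb <<- c(rx_lb, lb); rx_ub <<- c(rx_ub, ub)
    rx_gpr <<- c(rx_gpr, gpr); stoich[[id]] <<- st
  }

  add("EX_A", c(A = 1), ub = spec$uptake_budget)

  trunk_out <- "A"
  if (spec$topology == "branched") {
    add("TRUNK", c(A = -1, P = 1), gpr = draw_gpr())
    trunk_out <- "P"
  }
  use_currency <- spec$topology == "currency"
  if (use_currency) {
    gen_ub <- if (is.na(spec$generator_capacity)) 1000 else
      spec$generator_capacity
    add("RGEN", c(A = -1, X = -1, W = 1, Xa = 1), ub = gen_ub,
        gpr = new_gene())
    add("EX_W", c(W = -1))
  }

  comp_ids <- sprintf("B%d", seq_len(k))
  for (i in seq_len(k)) {
    len <- sample.int(spec$max_chain, 1)
    prev <- trunk_out
    for (s in seq_len(len)) {
      prod <- if (s == len) comp_ids[i] else sprintf("I%d_%d", i, s)
      st <- stats::setNames(c(-1, 1), c(prev, prod))
      if (s == 1 && stats::runif(1) < 0.3)
        st[prev] <- -2          # occasional 2:1 step, still hand checkable
      if (use_currency && s == len) {
        st <- c(st, Xa = -spec$cofactor_cost, X = spec$cofactor_cost)
      }
      add(sprintf("R%d_%d", i, s), st, gpr = draw_gpr())
      prev <- prod
    }
  }

  add("BIOMASS", stats::setNames(rep(-1, k), comp_ids))

  reactions <- data.frame(id = rx_id, lb = rx_lb, ub = rx_ub, gpr = rx_gpr,
                          stringsAsFactors = FALSE)
  m <- metabolic_model(reactions, stoich, "BIOMASS",
                       id = sprintf("synthetic_%s_seed%d",
                                    spec$topology, spec$seed))
  if (use_currency)
    attr(m, "currency") <- list(
      list(name = "X", charged = "Xa", discharged = "X", balancing = NULL))
  m
}
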