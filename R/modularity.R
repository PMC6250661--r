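#' Build the bipartite gene-trait network
#'
#' Nodes are genes and biomass components (traits); an edge links a gene to
#' every component affected by its full knockout. Genes with empty affected
#' sets are dropped (isolated nodes carry no modularity information).
#'
#' @param affected named list: gene id -> character vector of affected
#'   component ids (e.g. from [allele_pleiotropy()] at fraction 0).
#' @return object of class `gene_trait_network`: list with `genes`,
#'   `traits`, `A` (gene x trait 0/1 incidence), `m` (edge count),
#'   `k` (gene degrees), `d` (trait degrees), `edges` (data.frame).
#' @export
gene_trait_network <- function(affected) {
  affected <- affected[lengths(affected) > 0]
  if (length(affected) == 0) stop("empty gene-trait network: no edges")
  genes <- names(affected)
  traits <- sort(unique(unlist(affected)))
  if (length(intersect(genes, traits)))
    stop("gene ids and trait ids overlap; node names must be unique")
  A <- matrix(0L, length(genes), length(traits),
              dimnames = list(genes, traits))
  for (g in genes) A[g, affected[[g]]] <- 1L
  edges <- data.frame(gene = rep(genes, times = lengths(affected)),
                      trait = unlist(affected, use.names = FALSE),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, traits = traits, A = A,
                 m = sum(A), k = rowSums(A), d = colSums(A),
                 edges = edges),
            class = "gene_trait_network")
}

#' @export
print.gene_trait_network <- function(x, ...) {
  cat(sprintf("<gene_trait_network: %d genes, %d traits, %d edges>\n",
              length(x$genes), length(x$traits), x$m))
  invisible(x)
}

# Barber's bipartite modularity matrix B = A - k d' / m
barber_matrix <- function(net) {
  net$A - outer(net$k, net$d) / net$m
}

#' Barber bipartite modularity of a partition
#'
#' `Q = (1/m) * sum over gene-trait pairs in the same module of
#' (A_gt - k_g d_t / m)`. Modules are mixed: they may contain both genes
#' and traits. The all-in-one partition has `Q = 0` for every network.
#'
#' @param net a [gene_trait_network()].
#' @param partition named integer/character vector assigning every gene and
#'   trait node to a module.
#' @return numeric Q in `[-1, 1]`.
#' @export
barber_q <- function(net, partition) {
  nodes <- c(net$genes, net$traits)
  if (!all(nodes %in% names(partition)))
    stop("partition must label every gene and trait node")
  gl <- partition[net$genes]
  tl <- partition[net$traits]
  B <- barber_matrix(net)
  same <- outer(gl, tl, "==")
  sum(B[same]) / net$m
}

# one label-propagation + BRIM run; returns list(partition, q).
# Each run refines the stochastic label-propagation seed and (with
# `singleton_start`) the deterministic all-singletons partition, keeping
# the better. Label propagation tends to collapse connected networks into
# one module, a Q = 0 plateau that BRIM's single-side reassignments cannot
# leave; the singleton start never lands there. Being deterministic, the
# singleton start only needs to run once per network, so multi-restart
# callers enable it on the first restart only.
lp_brim_once <- function(net, max_sweeps = 50, max_brim = 100,
                         singleton_start = TRUE) {
  G <- length(net$genes); Tt <- length(net$traits)
  A <- net$A
  B <- barber_matrix(net)
  relabel <- function(lg, lt) {
    u <- sort(unique(c(lg, lt)))
    list(g = match(lg, u), t = match(lt, u), k = length(u))
  }
  q_of <- function(lg, lt) sum(B[outer(lg, lt, "==")]) / net$m

  # BRIM refinement on B = A - k d'/m from a given start
  brim <- function(lab_g, lab_t) {
    rl <- relabel(lab_g, lab_t); lab_g <- rl$g; lab_t <- rl$t
    q <- q_of(lab_g, lab_t)
    for (it in seq_len(max_brim)) {
      nmod <- max(lab_g, lab_t)
      # genes given trait labels
      Tm <- matrix(0, Tt, nmod); Tm[cbind(seq_len(Tt), lab_t)] <- 1
      score_g <- B %*% Tm                       # G x modules
      bg <- max.col(score_g, ties.method = "first")
      val <- score_g[cbind(seq_len(G), bg)]
      fresh <- val < 0                          # better off alone
      lab_g <- bg
      if (any(fresh)) lab_g[fresh] <- nmod + seq_len(sum(fresh))
      # traits given gene labels
      nmod <- max(lab_g, lab_t)
      Gm <- matrix(0, G, nmod); Gm[cbind(seq_len(G), lab_g)] <- 1
      score_t <- t(B) %*% Gm
      bt <- max.col(score_t, ties.method = "first")
      valt <- score_t[cbind(seq_len(Tt), bt)]
      fresht <- valt < 0
      lab_t <- bt
      if (any(fresht)) lab_t[fresht] <- nmod + seq_len(sum(fresht))
      rl <- relabel(lab_g, lab_t); lab_g <- rl$g; lab_t <- rl$t
      q_new <- q_of(lab_g, lab_t)
      if (q_new <= q + 1e-12) { q <- max(q, q_new); break }
      q <- q_new
    }
    list(g = lab_g, t = lab_t, q = q)
  }

  # start 1: label propagation on the bipartite graph
  N <- G + Tt
  nb_g <- lapply(seq_len(G), function(i) which(A[i, ] == 1L))
  nb_t <- lapply(seq_len(Tt), function(j) which(A[, j] == 1L))
  majority <- function(labs) {
    cnt <- tabulate(labs, nbins = N)
    best <- which(cnt == max(cnt))
    best[sample.int(length(best), 1L)]
  }
  lab_g <- seq_len(G)
  lab_t <- G + seq_len(Tt)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in sample.int(G)) {
      nb <- nb_g[[i]]
      if (!length(nb)) next
      new <- majority(lab_t[nb])
      if (new != lab_g[i]) { lab_g[i] <- new; changed <- TRUE }
    }
    for (j in sample.int(Tt)) {
      nb <- nb_t[[j]]
      if (!length(nb)) next
      new <- majority(lab_g[nb])
      if (new != lab_t[j]) { lab_t[j] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  res <- brim(lab_g, lab_t)

  # start 2: every node its own module
  if (singleton_start) {
    res2 <- brim(seq_len(G), G + seq_len(Tt))
    if (res2$q > res$q) res <- res2
  }

  partition <- stats::setNames(c(res$g, res$t), c(net$genes, net$traits))
  list(partition = partition, q = res$q)
}

#' LP&BRIM community detection on a bipartite network
#'
#' Label propagation seeds module assignments; BRIM (Bipartite Recursively
#' Induced Modules) then alternately reassigns gene-side and trait-side
#' labels, each node moving to the adjacent module that maximizes Barber's
#' Q, until Q stops improving. The best of `nrestarts` seeded restarts is
#' returned. The result never has lower Q than the all-in-one partition
#' (Q = 0), since nodes may always retreat to singleton modules.
#'
#' @param net a [gene_trait_network()].
#' @param nrestarts number of random restarts.
#' @param seed optional RNG seed.
#' @return list with `partition` (named module labels over all nodes) and
#'   `q` (best Barber modularity found).
#' @export
lp_brim <- function(net, nrestarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(nrestarts)) {
    res <- lp_brim_once(net, singleton_start = (r == 1L))
    if (is.null(best) || res$q > best$q) best <- res
  }
  # guard: never worse than the trivial single-module partition (Q = 0)
  if (best$q < 0) {
    best <- list(partition = stats::setNames(
      rep(1L, length(net$genes) + length(net$traits)),
      c(net$genes, net$traits)), q = 0)
  }
  best
}

#' Degree-preserving rewiring of a bipartite network
#'
#' Attempts `nswaps` double-edge swaps (default `10 * m`): two random
#' edges (g1, t1), (g2, t2) exchange endpoints to (g1, t2), (g2, t1)
#' unless that would create a duplicate edge. Both degree sequences are
#' preserved exactly. Networks with no legal swaps (e.g. complete
#' bipartite) are returned unchanged.
#'
#' @param net a [gene_trait_network()].
#' @param nswaps number of attempted swaps.
#' @param seed optional RNG seed.
#' @return a rewired `gene_trait_network`.
#' @export
rewire_null <- function(net, nswaps = 10 * net$m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (net$m < 2) stop("rewiring needs at least 2 edges")
  eg <- net$edges$gene
  et <- net$edges$trait
  m <- length(eg)
  key <- function(g, t) paste(g, t, sep = "\r")
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(key(eg[i], et[i]), TRUE, have)
  for (s in seq_len(nswaps)) {
    ij <- sample.int(m, 2)
    i <- ij[1]; j <- ij[2]
    g1 <- eg[i]; t1 <- et[i]
    g2 <- eg[j]; t2 <- et[j]
    if (g1 == g2 || t1 == t2) next
    if (exists(key(g1, t2), have) || exists(key(g2, t1), have)) next
    rm(list = c(key(g1, t1), key(g2, t2)), envir = have)
    assign(key(g1, t2), TRUE, have)
    assign(key(g2, t1), TRUE, have)
    et[i] <- t2; et[j] <- t1
  }
  gene_trait_network(split(et, eg))
}

#' Scaled modularity against degree-preserving nulls
#'
#' Runs LP&BRIM on the observed network and on `n_null` rewired nulls,
#' then reports the z-score ("scaled modularity")
#' `z = (Q_obs - mean(Q_null)) / sd(Q_null)` and the empirical p-value
#' `(1 + #(Q_null >= Q_obs)) / (1 + n_null)`.
#'
#' @param net a [gene_trait_network()].
#' @param n_null number of rewired null networks.
#' @param seed RNG seed for the whole computation.
#' @param restarts_obs LP&BRIM restarts on the observed network.
#' @param restarts_null LP&BRIM restarts per null network (fewer, for
#'   tractability at large `n_null`).
#' @return object of class `modularity_result`: list with `q`,
#'   `partition`, `null_q`, `z` (`NA` when the null has zero variance),
#'   `p`, `n_null`.
#' @export
scaled_modularity <- function(net, n_null = 10000, seed = NULL,
                              restarts_obs = 20, restarts_null = 5) {
  stopifnot(n_null >= 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- lp_brim(net, nrestarts = restarts_obs)
  null_q <- vapply(seq_len(n_null), function(i) {
    lp_brim(rewire_null(net), nrestarts = restarts_null)$q
  }, numeric(1))
  sdn <- stats::sd(null_q)
  z <- if (sdn > 0) (obs$q - mean(null_q)) / sdn else NA_real_
  p <- (1 + sum(null_q >= obs$q)) / (1 + n_null)
  structure(list(q = obs$q, partition = obs$partition, null_q = null_q,
                 z = z, p = p, n_null = n_null),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result: Q = %.4f, scaled modularity z = %.2f, empirical p = %.4g (%d nulls)>\n",
              x$q, x$z, x$p, x$n_null))
  invisible(x)
}
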