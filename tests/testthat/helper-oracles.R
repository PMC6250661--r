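# Test-side helpers, independent of the package's own implementations.

# Exhaustive Barber-Q maximization: enumerate every set partition of the
# nodes (restricted growth strings) and return the best Q. Feasible for
# networks with <= 10 nodes (Bell(10) = 115975 partitions).
exhaustive_best_q <- function(net) {
  nodes <- c(net$genes, net$traits)
  n <- length(nodes)
  stopifnot(n <= 10)
  best <- -Inf
  labels <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) {
      part <- stats::setNames(labels, nodes)
      q <- barber_q(net, part)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (l in seq_len(kmax + 1L)) {
      labels[i] <<- l
      recurse(i + 1L, max(kmax, l))
    }
  }
  recurse(1L, 0L)
  best
}

# GPR ground truth by direct boolean evaluation of the raw rule string.
eval_gpr_string <- function(gpr, state) {
  if (!nzchar(trimws(gpr))) return(TRUE)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^\\s()]+", gpr, perl = TRUE))[[1]]
  expr <- vapply(toks, function(t) {
    tl <- tolower(t)
    if (tl == "and") "&"
    else if (tl == "or") "|"
    else if (t %in% c("(", ")")) t
    else if (state[[t]]) "TRUE" else "FALSE"
  }, character(1), USE.NAMES = FALSE)
  isTRUE(eval(parse(text = paste(expr, collapse = " "))))
}

# a small pool of GPR rules covering every operator combination
gpr_rule_pool <- function() c(
  "g1",
  "g1 and g2",
  "g1 or g2",
  "g1 and g2 and g3",
  "g1 or g2 or g3",
  "(g1 and g2) or g3",
  "g1 and (g2 or g3)",
  "(g1 or g2) and (g3 or g4)",
  "((g1 and g2) or (g3 and g4)) and g5",
  "g1 or (g2 and (g3 or (g4 and g5)))",
  "(g1) and ((g2 or g3))",
  "g1 and g2 or g3"
)

# random LP in standard-ish form for cross-checking the solver against
# pracma::linprog (via its A x <= b plus Aeq x = beq path, cc >= 0 form)
random_lp <- function(seed, m = 4, n = 7) {
  set.seed(seed)
  A <- matrix(stats::rnorm(m * n), m, n)
  x0 <- stats::runif(n, 0, 2)          # a known feasible point
  b <- as.numeric(A %*% x0)
  obj <- stats::rnorm(n)
  list(A = A, b = b, obj = obj, n = n)
}
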