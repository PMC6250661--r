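# two disjoint edges: ga-t1, gb-t2
net2 <- gene_trait_network(list(ga = "t1", gb = "t2"))

test_that("gene_trait_network builds the incidence structure", {
  net <- gene_trait_network(list(ga = c("t1", "t2"), gb = "t2",
                                 gz = character(0)))
  expect_identical(net$genes, c("ga", "gb"))   # empty gene dropped
  expect_identical(net$traits, c("t1", "t2"))
  expect_identical(net$m, 3L)
  expect_equal(unname(net$k), c(2, 1))
  expect_equal(unname(net$d), c(1, 2))
  expect_error(gene_trait_network(list(gz = character(0))), "empty")
  expect_error(gene_trait_network(list(t1 = "t1")), "overlap")
})

test_that("Barber Q identities hold", {
  # all-in-one partition: Q = 0 on any network
  nets <- list(net2,
               gene_trait_network(list(ga = c("t1", "t2"), gb = c("t2", "t3"),
                                       gc = "t3")))
  for (net in nets) {
    all_one <- stats::setNames(rep(1L, length(net$genes) + length(net$traits)),
                               c(net$genes, net$traits))
    expect_equal(barber_q(net, all_one), 0)
  }
  # two disjoint edges, each its own module: Q = 0.5
  part <- c(ga = 1L, gb = 2L, t1 = 1L, t2 = 2L)
  expect_equal(barber_q(net2, part), 0.5)
  # incomplete partitions are rejected
  expect_error(barber_q(net2, c(ga = 1L, t1 = 1L)), "every gene and trait")
})

test_that("LP&BRIM finds the exhaustive optimum on small networks", {
  nets <- list(
    net2,
    gene_trait_network(list(ga = c("t1", "t2"), gb = c("t1", "t2"),
                            gc = c("t3", "t4"), gd = c("t3", "t4"))),
    gene_trait_network(list(ga = c("t1", "t2"), gb = c("t2", "t3"),
                            gc = c("t3", "t4"), gd = "t4"))
  )
  for (net in nets) {
    qstar <- exhaustive_best_q(net)
    res <- lp_brim(net, nrestarts = 20, seed = 42)
    expect_equal(res$q, qstar, tolerance = 1e-12)
    expect_equal(barber_q(net, res$partition), res$q)
  }
})

test_that("LP&BRIM never returns Q below the all-in-one partition", {
  # complete bipartite network: best Q is 0
  net <- gene_trait_network(list(ga = c("t1", "t2"), gb = c("t1", "t2")))
  res <- lp_brim(net, nrestarts = 10, seed = 1)
  expect_gte(res$q, 0)
  expect_equal(res$q, exhaustive_best_q(net))
})

test_that("rewired nulls preserve both degree sequences exactly", {
  set.seed(3)
  aff <- lapply(stats::setNames(1:8, sprintf("g%d", 1:8)), function(i)
    sample(sprintf("t%d", 1:5), sample(1:3, 1)))
  net <- gene_trait_network(aff)
  for (s in 1:20) {
    rn <- rewire_null(net, seed = s)
    expect_identical(sort(names(rn$k)), sort(names(net$k)))
    expect_equal(rn$k[names(net$k)], net$k)
    expect_equal(rn$d[names(net$d)], net$d)
    expect_identical(rn$m, net$m)
    # simple graph: no duplicate edges
    expect_false(any(duplicated(rn$edges)))
  }
})

test_that("complete bipartite networks are rewire-invariant", {
  net <- gene_trait_network(list(ga = c("t1", "t2"), gb = c("t1", "t2"),
                                 gc = c("t1", "t2")))
  rn <- rewire_null(net, seed = 7)
  e1 <- rn$edges[order(rn$edges$gene, rn$edges$trait), ]
  e2 <- net$edges[order(net$edges$gene, net$edges$trait), ]
  expect_equal(unname(as.matrix(e1)), unname(as.matrix(e2)))
})

test_that("scaled modularity separates modular from null-level structure", {
  # strongly modular: two disjoint complete blocks
  aff <- c(lapply(stats::setNames(1:4, sprintf("ga%d", 1:4)),
                  function(i) c("t1", "t2")),
           lapply(stats::setNames(1:4, sprintf("gb%d", 1:4)),
                  function(i) c("t3", "t4")))
  net <- gene_trait_network(aff)
  sm <- scaled_modularity(net, n_null = 200, seed = 11)
  expect_equal(sm$q, 0.5)
  expect_gt(sm$z, 2)
  expect_lt(sm$p, 0.05)
  expect_length(sm$null_q, 200)
  # empirical p always respects the resolution floor
  expect_gte(sm$p, 1 / 201)
})

test_that("scaled modularity is reproducible under a fixed seed", {
  aff <- list(ga = c("t1", "t2"), gb = c("t2", "t3"), gc = c("t3", "t4"),
              gd = c("t4", "t1"), ge = "t1")
  net <- gene_trait_network(aff)
  a <- scaled_modularity(net, n_null = 50, seed = 5)
  b <- scaled_modularity(net, n_null = 50, seed = 5)
  expect_identical(a$q, b$q)
  expect_identical(a$null_q, b$null_q)
  expect_identical(a$z, b$z)
})
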