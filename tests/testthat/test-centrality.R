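# Phase IV: weighted betweenness (Brandes over Dijkstra DAGs) and
# eigenvector centrality (shifted power iteration).

path_net <- function(d = c(1, 1)) {
  list(nodes = c("A", "B", "C"),
       edges = data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                          distance = d, affinity = 1 - d + d,  # placeholder 1s
                          stringsAsFactors = FALSE))
}

test_that("betweenness reproduces worked small-graph examples", {
  b <- weighted_betweenness(path_net())
  expect_equal(unname(b), c(0, 1, 0))
  star <- list(nodes = c("X", "L1", "L2", "L3"),
               edges = data.frame(gene1 = "X", gene2 = c("L1", "L2", "L3"),
                                  distance = c(0.3, 0.6, 0.9)))
  expect_equal(unname(weighted_betweenness(star)), c(1, 0, 0, 0))
  cyc <- list(nodes = c("A", "B", "C", "D"),
              edges = data.frame(gene1 = c("A", "B", "C", "A"),
                                 gene2 = c("B", "C", "D", "D"),
                                 distance = c(0.1, 0.1, 0.1, 0.5)))
  expect_equal(unname(weighted_betweenness(cyc)), c(0, 2/3, 2/3, 0),
               tolerance = 1e-12)
  expect_error(weighted_betweenness(list(nodes = c("A", "B"),
    edges = data.frame(gene1 = "A", gene2 = "B", distance = -1))), "negative")
})

test_that("tied shortest paths are split fractionally; zero distances are legal", {
  # equal-length diamond: every node sits on one of two tied shortest
  # paths for the opposite pair, so each carries 1/2 of one pair out of
  # the (n-1)(n-2)/2 = 3 it could bridge
  dia <- list(nodes = c("A", "B", "C", "D"),
              edges = data.frame(gene1 = c("A", "A", "B", "C"),
                                 gene2 = c("B", "C", "D", "D"),
                                 distance = c(0.2, 0.2, 0.2, 0.2)))
  b <- weighted_betweenness(dia)
  expect_equal(unname(b), rep(1 / 6, 4), tolerance = 1e-12)
  # zero-distance edge (|cc| = 1) must not error and keeps B on all paths
  z <- path_net(d = c(0, 0.5))
  expect_equal(unname(weighted_betweenness(z)), c(0, 1, 0))
})

test_that("betweenness equals the exhaustive-path oracle on random graphs", {
  for (i in 1:60) {
    net <- rand_net(n = sample(3:8, 1), extra = sample(0:4, 1), seed = i)
    expect_equal(weighted_betweenness(net), oracle_betweenness(net),
                 tolerance = 1e-9)
  }
})

test_that("betweenness agrees with igraph on strictly positive weights", {
  for (i in 1:10) {
    net <- rand_net(n = sample(4:10, 1), extra = 3, seed = 100 + i)
    g <- igraph::graph_from_data_frame(net$edges[, c("gene1", "gene2")],
                                       directed = FALSE, vertices = net$nodes)
    ig <- igraph::betweenness(g, weights = net$edges$distance,
                              normalized = TRUE)
    expect_equal(unname(weighted_betweenness(net)), unname(ig[net$nodes]),
                 tolerance = 1e-9)
  }
})

test_that("with equal affinities weighted betweenness equals unweighted", {
  for (i in 1:5) {
    net <- rand_net(n = 7, extra = 3, seed = 200 + i)
    net$edges$distance <- 1
    g <- igraph::graph_from_data_frame(net$edges[, c("gene1", "gene2")],
                                       directed = FALSE, vertices = net$nodes)
    expect_equal(unname(weighted_betweenness(net)),
                 unname(igraph::betweenness(g, normalized = TRUE)[net$nodes]),
                 tolerance = 1e-9)
  }
})

test_that("eigenvector centrality reproduces closed-form cases", {
  tri <- list(nodes = c("A", "B", "C"),
              edges = data.frame(gene1 = c("A", "B", "A"),
                                 gene2 = c("B", "C", "C"),
                                 affinity = 1))
  expect_equal(unname(eigenvector_centrality(tri)), rep(1 / sqrt(3), 3),
               tolerance = 1e-8)
  pathn <- list(nodes = c("A", "B", "C"),
                edges = data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                                   affinity = 1))
  expect_equal(unname(eigenvector_centrality(pathn)),
               c(0.5, sqrt(0.5), 0.5), tolerance = 1e-8)
})

test_that("minor components get near-zero eigenvector centrality", {
  net <- list(nodes = c("A", "B", "C", "D", "E"),
              edges = data.frame(gene1 = c("A", "B", "A", "D"),
                                 gene2 = c("B", "C", "C", "E"),
                                 affinity = 1))
  v <- eigenvector_centrality(net)
  expect_equal(unname(v[1:3]), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  expect_lt(max(v[4:5]), 1e-8)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  for (i in 1:40) {
    net <- rand_net(n = sample(4:12, 1), extra = sample(0:5, 1), seed = 300 + i)
    expect_equal(eigenvector_centrality(net), oracle_eigen(net),
                 tolerance = 1e-8)
  }
})

test_that("eigenvector output is non-negative with unit norm (Perron-Frobenius)", {
  for (i in 1:10) {
    net <- rand_net(n = 9, extra = 4, seed = 400 + i)
    v <- eigenvector_centrality(net)
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
  # all-zero affinities degrade gracefully
  net <- path_net()
  net$edges$affinity <- 0
  expect_warning(v <- eigenvector_centrality(net), "zero")
  expect_true(all(v == 0))
})

test_that("centrality table carries absolute symmetric differences", {
  set.seed(55)
  net1 <- rand_net(8, extra = 4, seed = 501)
  net2 <- net1
  net2$edges$cc <- runif(nrow(net2$edges), 0, 0.9)
  net2$edges$distance <- 1 - net2$edges$cc
  net2$edges$affinity <- net2$edges$cc
  net1$condition <- "a"; net2$condition <- "b"
  tab <- centrality_table(list(net1, net2))
  expect_equal(tab$delta_betweenness,
               abs(tab$betweenness_c2 - tab$betweenness_c1), tolerance = 1e-9)
  expect_equal(tab$delta_eigenvector,
               abs(tab$eigen_c2 - tab$eigen_c1), tolerance = 1e-9)
  tab_sw <- centrality_table(list(net2, net1))
  expect_equal(tab_sw$delta_betweenness, tab$delta_betweenness, tolerance = 1e-12)
  expect_equal(tab_sw$delta_eigenvector, tab$delta_eigenvector, tolerance = 1e-12)
  # identical networks give zero deltas
  tab_id <- centrality_table(list(net1, net1))
  expect_true(all(tab_id$delta_betweenness == 0))
  expect_true(all(tab_id$delta_eigenvector == 0))
  # node-set mismatch
  net3 <- net2; net3$nodes <- rev(net3$nodes)
  expect_error(centrality_table(list(net1, net3)), "node sets")
  expect_error(centrality_delta(data.frame(gene = "A", betweenness = 1,
                                           eigenvector = 1),
                                data.frame(gene = "B", betweenness = 1,
                                           eigenvector = 1)),
               "different gene sets")
})
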