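# Collection in which every pair of pathways shares exactly one dedicated
# gene out of equally sized sets, so all candidate Jaccards are equal and
# rewiring reduces to uniform sampling over all pairs.
uniform_candidate_collection <- function(n = 4) {
  sets <- list()
  ids <- paste0("Q", seq_len(n))
  pairs <- combn(ids, 2, simplify = FALSE)  # all pairs overlap
  shared <- lapply(seq_along(pairs), function(i) sprintf("s%02d", i))
  for (id in ids) sets[[id]] <- character()
  for (i in seq_along(pairs)) {
    sets[[pairs[[i]][1]]] <- c(sets[[pairs[[i]][1]]], shared[[i]])
    sets[[pairs[[i]][2]]] <- c(sets[[pairs[[i]][2]]], shared[[i]])
  }
  for (id in ids) sets[[id]] <- c(sets[[id]], paste0(id, "x", 1:2))
  pathway_collection(sets)
}

pxpn_like <- function(collection, edges) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(collection$sets),
                            name = names(collection$sets))
  igraph::add_edges(g, edges)
}

test_that("rewiring conserves nodes and edge count, edges join overlapping pairs", {
  col <- uniform_candidate_collection()
  g <- pxpn_like(col, c("Q1", "Q2", "Q3", "Q4"))
  cand <- brute_force_pairs(col)
  withr::local_seed(1)
  for (i in 1:50) {
    r <- rewire_network(g, col)
    expect_setequal(igraph::V(r)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(r), igraph::ecount(g))
    keys <- apply(igraph::as_edgelist(r), 1, function(x)
      paste(sort(x), collapse = "|"))
    expect_true(all(keys %in% cand))
    expect_false(igraph::any_loop(r))
    expect_false(igraph::any_multiple(r))
  }
  # forced case: one edge, one candidate pair
  two <- pathway_collection(list(A = c("g1", "g2"), B = c("g2", "g3")))
  gf <- pxpn_like(two, c("A", "B"))
  expect_equal(igraph::as_edgelist(rewire_network(gf, two)),
               igraph::as_edgelist(gf))
  # more edges than candidates is impossible
  expect_error(rewire_network(pxpn_like(two, c("A", "B")),
                              two, min_region_size = 5),
               "exceeds candidate")
})

test_that("equal-Jaccard candidates are resampled uniformly", {
  col <- uniform_candidate_collection()
  g <- pxpn_like(col, c("Q1", "Q2", "Q3", "Q4"))  # 2 of 6 candidates as edges
  cand <- brute_force_pairs(col)
  n <- 5000
  counts <- stats::setNames(numeric(length(cand)), cand)
  withr::local_seed(99)
  for (i in seq_len(n)) {
    keys <- apply(igraph::as_edgelist(rewire_network(g, col)), 1, function(x)
      paste(sort(x), collapse = "|"))
    counts[keys] <- counts[keys] + 1
  }
  expect_equal(sum(counts), n * 2)
  p_inc <- 2 / 6  # inclusion probability of each candidate
  tol <- 3 * sqrt(n * p_inc * (1 - p_inc))
  for (k in cand) expect_lt(abs(counts[[k]] - n * p_inc), tol)
  # chi-square goodness of fit over which pair was drawn, not rejected at 0.01
  gof <- stats::chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("rewiring picks pairs proportionally to Jaccard weight", {
  # two candidate pairs with Jaccard 0.4 (A-B: 4/10) vs 0.1 (A-C: 1/10),
  # one edge to place
  sets <- list(A = c(paste0("c", 1:4), "x", "a1"),
               B = c(paste0("c", 1:4), paste0("b", 1:4)),
               C = c("x", paste0("w", 1:4)))
  col <- pathway_collection(sets)
  cand <- crosstalk_regions(col)
  expect_equal(sort(cand$jaccard), c(0.1, 0.4))
  g <- pxpn_like(col, c("A", "B"))
  n <- 5000
  hits <- 0
  withr::local_seed(12)
  for (i in seq_len(n)) {
    el <- igraph::as_edgelist(rewire_network(g, col))
    if (setequal(el[1, ], c("A", "B"))) hits <- hits + 1
  }
  expect_lt(abs(hits - n * 0.8), 3 * sqrt(n * 0.8 * 0.2))
})

test_that("z-test matches the hand formula", {
  vals <- c(1, 2, 3)
  zt <- ztest(2, vals)
  expect_equal(zt$z, 0, tolerance = 1e-12)
  expect_equal(zt$p, 1, tolerance = 1e-12)
  zt <- ztest(4.2, vals)
  expect_equal(zt$z, (4.2 - 2) / 1, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-2.2), tolerance = 1e-12)
  # observed at mean + 1.96 sd -> p ~ 0.05
  withr::local_seed(5)
  vals <- rnorm(500)
  zt <- ztest(mean(vals) + 1.96 * sd(vals), vals)
  expect_equal(zt$p, 0.05, tolerance = 1e-3)
  expect_true(is.na(ztest(1, c(2, 2, 2))$z))
  expect_error(ztest(1, 3), "at least 2")
})

test_that("the rewiring ensemble conserves counts and flags unusual clustering", {
  col <- uniform_candidate_collection(6)
  # observed graph: complete bipartite K(3,3) -- 9 edges, no triangle, so
  # clustering 0; rewired graphs draw 9 of the 15 candidate pairs and are
  # dense enough to close many triangles
  bip <- as.vector(t(expand.grid(paste0("Q", 1:3), paste0("Q", 4:6))))
  g <- pxpn_like(col, bip)
  es <- rewire_ensemble(g, col, n = 1000, seed = 4)
  m <- es$metrics
  expect_equal(m$null_sd[m$metric == "nodes"], 0)
  expect_equal(m$null_sd[m$metric == "edges"], 0)
  expect_equal(m$observed[m$metric == "edges"],
               m$null_mean[m$metric == "edges"])
  expect_true(is.na(m$z[m$metric == "nodes"]))
  zc <- m$z[m$metric == "clustering_coefficient"]
  expect_gt(abs(zc), 2)
  # reproducible given the seed
  es2 <- rewire_ensemble(g, col, n = 1000, seed = 4)
  expect_equal(es$metrics, es2$metrics)
})

test_that("label shuffling preserves values and permutes labels uniformly", {
  sc <- planted_scenario()
  ex <- simulate_expression(sc$collection, sc$truth, sc$params, seed = 1)
  withr::local_seed(2)
  sh <- shuffle_gene_labels(ex)
  expect_equal(dim(sh), dim(ex))
  expect_setequal(rownames(sh$values), rownames(ex$values))
  for (j in seq_len(ncol(ex$values)))
    expect_equal(sort(sh$values[, j]), sort(ex$values[, j]),
                 ignore_attr = TRUE)
  # identity permutation frequency for a 3-row matrix ~ 1/6
  m3 <- ex$values[1:3, ]
  e3 <- expr_matrix(m3, ex$design, reference = "A")
  n <- 6000
  ident <- 0
  withr::local_seed(3)
  for (i in seq_len(n)) {
    if (identical(rownames(shuffle_gene_labels(e3)$values), rownames(m3)))
      ident <- ident + 1
  }
  expect_lt(abs(ident - n / 6), 3 * sqrt(n * (1 / 6) * (5 / 6)))
})

test_that("trivial structures are classified with fixed precedence", {
  named <- function(g) igraph::set_vertex_attr(
    g, "name", value = paste0("v", seq_len(igraph::vcount(g))))
  expect_equal(classify_structure(named(igraph::make_empty_graph(3, directed = FALSE))),
               "empty")
  g1 <- igraph::add_edges(named(igraph::make_empty_graph(4, directed = FALSE)),
                          c("v1", "v2"))
  expect_equal(classify_structure(g1), "single_edge")
  k3iso <- igraph::add_vertices(igraph::make_full_graph(3), 2)
  expect_equal(classify_structure(named(k3iso)), "clique")
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(classify_structure(named(star)), "star")
  expect_equal(classify_structure(named(igraph::make_ring(4))), "other")
  # a triangle is a clique, not a star; K4 is a clique
  expect_equal(classify_structure(named(igraph::make_full_graph(3))), "clique")
  expect_equal(classify_structure(named(igraph::make_full_graph(4))), "clique")
  # two edges sharing a node: neither clique nor >=3-edge star
  p3 <- igraph::add_edges(named(igraph::make_empty_graph(3, directed = FALSE)),
                          c("v1", "v2", "v2", "v3"))
  expect_equal(classify_structure(p3), "other")
})

test_that("the shuffle ensemble on null data yields mostly empty networks", {
  sc <- null_scenario()
  ex <- simulate_expression(sc$collection, sc$truth, sc$params, seed = 17)
  zero <- shuffle_ensemble(ex, sc$collection, n = 10, alpha = 0, seed = 5)
  expect_equal(unname(zero$counts["empty"]), 10L)
  expect_equal(zero$more_than_one_edge, 0L)

  ss <- shuffle_ensemble(ex, sc$collection, n = 200, alpha = 0.05, seed = 5)
  expect_equal(sum(ss$counts), 200L)
  expect_gte(ss$counts[["empty"]] / 200, 0.80)
  # reproducible given the seed
  ss2 <- shuffle_ensemble(ex, sc$collection, n = 50, alpha = 0.05, seed = 5)
  expect_equal(ss2$counts, shuffle_ensemble(ex, sc$collection, n = 50,
                                            alpha = 0.05, seed = 5)$counts)
})
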