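#' Rewire a network by Jaccard-weighted edge resampling
#'
#' Null-model replicate: keeps the node set and the edge count, and redraws
#' the edges from the candidate pairs (node pairs whose pathway gene sets
#' overlap) without replacement, with sampling probability proportional to
#' the pairwise Jaccard index. No self-loops or multi-edges can arise.
#'
#' @param graph an undirected named [igraph::igraph] with >= 1 edge.
#' @param collection a [pathway_collection()] covering the graph's nodes.
#' @param min_region_size minimum shared-gene count for a candidate pair
#'   (default 1).
#' @return a rewired [igraph::igraph] with the same vertices (attributes
#'   preserved) and the same number of edges.
#' @export
rewire_network <- function(graph, collection, min_region_size = 1L) {
  stopifnot(igraph::is_igraph(graph))
  e <- igraph::ecount(graph)
  if (e < 1L) stop("graph has no edges to rewire")
  cand <- crosstalk_regions(collection, igraph::V(graph)$name,
                            min_region_size = min_region_size)
  if (e > nrow(cand))
    stop("edge count (", e, ") exceeds candidate pair count (", nrow(cand), ")")
  pick <- sample.int(nrow(cand), e, replace = FALSE, prob = cand$jaccard)
  g <- igraph::delete_edges(graph, igraph::E(graph))
  igraph::add_edges(g, rbind(cand$a[pick], cand$b[pick]),
                    regionSize = cand$size[pick], jaccard = cand$jaccard[pick])
}

#' Z-test of an observed value against ensemble values
#'
#' @param observed a real number.
#' @param values numeric vector of null-ensemble values (length >= 2).
#' @return list with `mean`, `sd` (sample sd, n - 1 denominator), `z`, and
#'   two-sided normal `p`; `z`/`p` are `NA` when the ensemble sd is 0.
#' @export
ztest <- function(observed, values) {
  if (length(values) < 2L) stop("need at least 2 ensemble values")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    return(list(mean = m, sd = s, z = NA_real_, p = NA_real_))
  z <- (observed - m) / s
  list(mean = m, sd = s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Per-replicate seed stream derived from the master seed, so ensembles are
# reproducible replicate-by-replicate. Kept within 32-bit integer range.
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Rewiring null-model ensemble with Z-tests
#'
#' Generates `n` rewired replicates of `graph` (see [rewire_network()]),
#' computes the topological summary of each, and compares every metric of
#' the observed network against the null distribution with a Z-test.
#' Node and edge counts are conserved by construction, so their null sd is
#' 0 and their z is undefined.
#'
#' @param graph an undirected named [igraph::igraph] with >= 1 edge.
#' @param collection a [pathway_collection()].
#' @param n ensemble size (default 5000).
#' @param seed master RNG seed; replicate i uses a seed derived from
#'   (seed, i).
#' @param min_region_size candidate-pair threshold (default 1).
#' @return list of class `ensemble_summary`: `metrics` (data.frame with
#'   metric, observed, null_mean, null_sd, z, p), `ensemble_size`, `seed`.
#' @export
rewire_ensemble <- function(graph, collection, n = 5000L, seed = 1L,
                            min_region_size = 1L) {
  stopifnot(igraph::is_igraph(graph))
  metric_names <- c("nodes", "edges", "density", "average_degree",
                    "clustering_coefficient", "average_shortest_path",
                    "connected_components", "single_nodes")
  pull <- function(ts) vapply(metric_names, function(m) as.numeric(ts[[m]]),
                              numeric(1))
  obs <- pull(topology_summary(graph))
  null <- matrix(NA_real_, nrow = n, ncol = length(metric_names),
                 dimnames = list(NULL, metric_names))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n)) {
    set.seed(replicate_seed(seed, i))
    null[i, ] <- pull(topology_summary(
      rewire_network(graph, collection, min_region_size = min_region_size)))
  }
  rows <- lapply(metric_names, function(m) {
    zt <- ztest(obs[[m]], null[, m])
    data.frame(metric = m, observed = obs[[m]], null_mean = zt$mean,
               null_sd = zt$sd, z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows),
                 ensemble_size = as.integer(n), seed = as.integer(seed)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("rewiring null ensemble of", x$ensemble_size, "networks (seed",
      paste0(x$seed, ")\n"))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shuffle gene labels of an expression matrix
#'
#' Permutes the row (gene) labels uniformly at random; the values, their
#' order, and the dimensions are untouched, so every sample column keeps an
#' identical value multiset.
#'
#' @param expr an [expr_matrix()].
#' @return an `expr_matrix` with permuted rownames.
#' @export
shuffle_gene_labels <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  rownames(v) <- rownames(v)[sample.int(nrow(v))]
  expr_matrix(v, expr$design, reference = expr$groups[1])
}

#' Classify a network's trivial structure
#'
#' Classes, in precedence order (first match wins): `empty` (no edges),
#' `single_edge` (exactly one edge), `clique` (>= 3 non-isolated nodes, all
#' mutually adjacent), `star` (>= 3 edges all sharing one common node),
#' `other`.
#'
#' @param graph an undirected [igraph::igraph].
#' @return one of `"empty"`, `"single_edge"`, `"clique"`, `"star"`,
#'   `"other"`.
#' @export
classify_structure <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  e <- igraph::ecount(graph)
  if (e == 0L) return("empty")
  if (e == 1L) return("single_edge")
  deg <- igraph::degree(graph)
  core <- igraph::induced_subgraph(graph, which(deg > 0))
  k <- igraph::vcount(core)
  if (k >= 3L && igraph::ecount(core) == k * (k - 1) / 2 &&
      !igraph::any_multiple(core))
    return("clique")
  if (e >= 3L) {
    el <- igraph::as_edgelist(core, names = FALSE)
    common <- Reduce(intersect, split(el, row(el)))
    if (length(common) >= 1L) return("star")
  }
  "other"
}

#' Gene-label-shuffling null ensemble
#'
#' For each of `n` replicates: shuffle the gene labels of `expr`, rebuild
#' the PXPN with the same pipeline and threshold, and classify the
#' resulting structure. Reports per-class counts plus the number of
#' replicates whose network has more than one edge.
#'
#' @param expr an [expr_matrix()] (filtered).
#' @param collection a [pathway_collection()].
#' @param n ensemble size (default 1500).
#' @param alpha q-value threshold passed to [build_pxpn()] (default 0.05).
#' @param seed master RNG seed (per-replicate streams as in
#'   [rewire_ensemble()]).
#' @param ... further arguments to [build_pxpn()].
#' @return list of class `shuffle_summary`: `counts` (named integer vector
#'   over the structure classes), `more_than_one_edge` (count),
#'   `ensemble_size`, `seed`.
#' @export
shuffle_ensemble <- function(expr, collection, n = 1500L, alpha = 0.05,
                             seed = 1L, ...) {
  classes <- c("empty", "single_edge", "star", "clique", "other")
  counts <- stats::setNames(integer(length(classes)), classes)
  gt1 <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n)) {
    set.seed(replicate_seed(seed, i))
    g <- build_pxpn(shuffle_gene_labels(expr), collection, alpha = alpha, ...)
    cl <- classify_structure(g)
    counts[[cl]] <- counts[[cl]] + 1L
    if (igraph::ecount(g) > 1L) gt1 <- gt1 + 1L
  }
  structure(list(counts = counts, more_than_one_edge = gt1,
                 ensemble_size = as.integer(n), seed = as.integer(seed)),
            class = "shuffle_summary")
}

#' @export
print.shuffle_summary <- function(x, ...) {
  cat("label-shuffle null ensemble of", x$ensemble_size, "datasets (seed",
      paste0(x$seed, ")\n"))
  print(x$counts)
  cat("networks with > 1 edge:", x$more_than_one_edge, "\n")
  invisible(x)
}
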