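#' Edge density
#'
#' @param n node count (>= 2).
#' @param e edge count.
#' @return 2e / (n (n - 1)).
#' @export
net_density <- function(n, e) {
  if (n < 2) stop("density needs at least 2 nodes")
  2 * e / (n * (n - 1))
}

#' Average degree
#'
#' @param n node count (>= 1).
#' @param e edge count.
#' @return 2e / n.
#' @export
average_degree <- function(n, e) {
  if (n < 1) stop("average degree needs at least 1 node")
  2 * e / n
}

#' Specific density
#'
#' Edges divided by the number of *possible* crosstalks among the network's
#' nodes: node pairs whose pathway gene sets intersect (with at least
#' `min_region_size` shared genes). A density normalized to biologically
#' possible edges rather than all pairs.
#'
#' @param graph an undirected named [igraph::igraph] whose node names are
#'   pathway ids of `collection`.
#' @param collection a [pathway_collection()].
#' @param min_region_size minimum shared-gene count for a possible crosstalk
#'   (default 1).
#' @return list with `numerator` (edge count), `denominator` (possible
#'   crosstalks), `ratio` (`NA` when the denominator is 0).
#' @export
specific_density <- function(graph, collection, min_region_size = 1L) {
  stopifnot(igraph::is_igraph(graph), inherits(collection, "pathway_collection"))
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(collection$sets)))
    stop("graph nodes must be pathway ids of the collection")
  den <- nrow(crosstalk_regions(collection, nodes,
                                min_region_size = min_region_size))
  num <- igraph::ecount(graph)
  list(numerator = num, denominator = den,
       ratio = if (den == 0L) NA_real_ else num / den)
}

#' Topological summary of a network
#'
#' Computes the standard global descriptors: node/edge counts, density,
#' specific density (when a collection is supplied), average degree, mean
#' local clustering coefficient, average shortest path, connected
#' components, and degree-0 ("single") nodes.
#'
#' Clustering convention: nodes with degree < 2 contribute 0 to the average
#' (set `clustering_isolates = "exclude"` for the other common convention).
#' Average shortest path: mean over reachable pairs within components;
#' unreachable pairs are excluded, so disconnected graphs still get a
#' finite value.
#'
#' @param graph an undirected [igraph::igraph].
#' @param collection optional [pathway_collection()] for specific density.
#' @param clustering_isolates `"zero"` (default) or `"exclude"`.
#' @param min_region_size passed to [specific_density()].
#' @return list of class `topology_summary`.
#' @export
topology_summary <- function(graph, collection = NULL,
                             clustering_isolates = c("zero", "exclude"),
                             min_region_size = 1L) {
  clustering_isolates <- match.arg(clustering_isolates)
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  local_cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc <- if (n == 0L) NA_real_
        else if (clustering_isolates == "zero") mean(local_cc)
        else {
          ok <- igraph::degree(graph) >= 2
          if (any(ok)) mean(local_cc[ok]) else NA_real_
        }
  comps <- if (n == 0L) 0L else igraph::count_components(graph)
  sp <- specific_density_or_null(graph, collection, min_region_size)
  structure(list(
    nodes = n,
    edges = e,
    density = if (n >= 2) net_density(n, e) else NA_real_,
    specific_density = sp,
    average_degree = if (n >= 1) average_degree(n, e) else NA_real_,
    clustering_coefficient = cc,
    average_shortest_path = if (e >= 1)
      igraph::mean_distance(graph, unconnected = TRUE) else NA_real_,
    connected_components = comps,
    single_nodes = if (n == 0L) 0L else sum(igraph::degree(graph) == 0)
  ), class = "topology_summary")
}

specific_density_or_null <- function(graph, collection, min_region_size) {
  if (is.null(collection)) return(NULL)
  specific_density(graph, collection, min_region_size = min_region_size)
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("nodes:", x$nodes, " edges:", x$edges, "\n")
  cat(sprintf("density: %.3f  average degree: %.2f\n",
              x$density, x$average_degree))
  if (!is.null(x$specific_density))
    cat(sprintf("specific density: %d/%d = %.3f\n",
                x$specific_density$numerator, x$specific_density$denominator,
                x$specific_density$ratio))
  cat(sprintf("clustering: %.3f  average shortest path: %.2f\n",
              x$clustering_coefficient, x$average_shortest_path))
  cat("components:", x$connected_components,
      " single nodes:", x$single_nodes, "\n")
  invisible(x)
}

#' Detect communities with Infomap
#'
#' Map-equation (Infomap) partition with a fixed RNG seed and best of
#' `trials` attempts; isolated nodes become singleton communities.
#' Community ids are renumbered to be contiguous from 0 in order of first
#' appearance, so the result is deterministic given (graph, seed, trials).
#'
#' @param graph a non-empty undirected [igraph::igraph].
#' @param seed integer RNG seed (default 1).
#' @param trials number of Infomap attempts, best codelength kept
#'   (default 10).
#' @return list of class `community_partition`: `assignment` (named integer
#'   vector, node -> community id from 0), `seed`, `method`.
#' @export
detect_communities <- function(graph, seed = 1L, trials = 10L) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_infomap(graph, nb.trials = trials)
  memb <- igraph::membership(cl)
  ids <- unique(as.integer(memb))
  assignment <- match(as.integer(memb), ids) - 1L
  nm <- igraph::V(graph)$name
  names(assignment) <- if (is.null(nm)) as.character(seq_along(assignment)) else nm
  structure(list(assignment = assignment, seed = as.integer(seed),
                 method = "infomap"),
            class = "community_partition")
}

#' Community quotient ("network of networks") graph
#'
#' Collapses each community to one meta-node; a meta-edge joins two
#' communities when at least one original edge crosses between them, with
#' weight equal to the number of crossing edges. Intra-community edges are
#' dropped.
#'
#' @param graph an undirected [igraph::igraph].
#' @param partition a `community_partition` from [detect_communities()]
#'   covering every node of `graph`.
#' @return an undirected [igraph::igraph]; vertex attributes `name`
#'   (community id as character), `size`, `members` (comma-separated);
#'   edge attribute `weight` (crossing-edge count).
#' @export
community_quotient <- function(graph, partition) {
  stopifnot(igraph::is_igraph(graph),
            inherits(partition, "community_partition"))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  missing <- setdiff(nodes, names(partition$assignment))
  if (length(missing))
    stop("nodes missing from partition: ", paste(missing, collapse = ", "))
  memb <- partition$assignment[nodes]
  comms <- sort(unique(memb))
  q <- igraph::make_empty_graph(n = 0, directed = FALSE)
  members <- vapply(comms, function(cid)
    paste(sort(nodes[memb == cid]), collapse = ","), character(1))
  q <- igraph::add_vertices(q, length(comms), name = as.character(comms),
                            size = as.integer(table(memb)[as.character(comms)]),
                            members = members)
  if (igraph::ecount(graph) > 0L) {
    el <- igraph::as_edgelist(graph, names = TRUE)
    ca <- memb[el[, 1]]; cb <- memb[el[, 2]]
    cross <- ca != cb
    if (any(cross)) {
      key <- paste(pmin(ca[cross], cb[cross]), pmax(ca[cross], cb[cross]))
      w <- table(key)
      pairs <- do.call(rbind, strsplit(names(w), " ", fixed = TRUE))
      q <- igraph::add_edges(q, rbind(pairs[, 1], pairs[, 2]),
                             weight = as.integer(w))
    }
  }
  q
}
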