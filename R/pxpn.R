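#' Read an expression matrix and design from TSV
#'
#' Expression file: tab-separated, first column gene id, header row of
#' sample ids. Design file: two-column TSV (sample id, group label), no
#' header required (a header line is detected when its first token matches
#' no expression column).
#'
#' @param expr_path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @param reference optional reference ("from") group label.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(expr_path, design_path, reference = NULL) {
  tab <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes
  des <- utils::read.table(design_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!des[1, 1] %in% colnames(values)) des <- des[-1, , drop = FALSE]
  design <- stats::setNames(as.character(des[[2]]), as.character(des[[1]]))
  expr_matrix(values, design, reference = reference)
}

#' Write an expression matrix (and its design) to TSV
#'
#' @param expr an [expr_matrix()].
#' @param expr_path,design_path output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, expr_path, design_path) {
  stopifnot(inherits(expr, "expr_matrix"))
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expr$design), group = unname(expr$design)),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(expr_path)
}

#' Build a pathway crosstalk perturbation network (PXPN)
#'
#' Four steps: (1) pathways enriched between the two states at q < `alpha`
#' become nodes; (2) crosstalk regions (pairwise gene-set intersections)
#' among those enriched pathways become candidate edges; (3) each candidate
#' region is tested with the same enrichment function and kept at
#' q < `alpha` (regions form their own BH family); (4) nodes and surviving
#' edges are integrated into an undirected graph. Enriched pathways whose
#' regions are all untested or not enriched remain as isolated nodes.
#'
#' @param expr an [expr_matrix()], already [filter_genes()]-filtered.
#' @param collection a [pathway_collection()].
#' @param alpha q-value threshold for both pathway and region enrichment
#'   (default 0.05).
#' @param transition optional name for the state transition (e.g. `"HTD"`),
#'   stored as a graph attribute together with the two group labels.
#' @param mode,n_perm enrichment mode, see [set_statistic()].
#' @param min_set_size minimum member overlap for a pathway to be tested
#'   (default 2).
#' @param min_region_size minimum intersection size for a crosstalk region
#'   (default 1); regions are tested whenever at least one member gene is
#'   scored.
#' @param u_cap zero-variance score cap, see [gene_scores()].
#' @param verbose print tested/enriched counts (default FALSE).
#' @return an undirected [igraph::igraph]; vertex attributes `name`
#'   (pathway id), `pathwayName`, `T`, `q`; edge attributes `regionSize`,
#'   `T`, `q`, `jaccard`; graph attributes `transition`, `state_from`,
#'   `state_to`, `alpha`. Empty node set gives an empty graph.
#' @export
build_pxpn <- function(expr, collection, alpha = 0.05, transition = "",
                       mode = c("parametric", "permutation"), n_perm = 1000L,
                       min_set_size = 2L, min_region_size = 1L, u_cap = 50,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(collection, "pathway_collection"))
  if (!any(collection_universe(collection) %in% rownames(expr$values)))
    stop("no overlap between expression gene ids and pathway gene sets")

  # step 1: perturbed pathways
  ptab <- enrich(expr, collection$sets, alpha = alpha, mode = mode,
                 n_perm = n_perm, min_set_size = min_set_size, u_cap = u_cap)
  nodes <- sort(ptab$id[ptab$enriched])
  if (verbose)
    message(sum(!is.na(ptab$p)), " pathways tested, ", length(nodes),
            " enriched at q < ", alpha)

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::set_graph_attr(g, "transition", transition)
  g <- igraph::set_graph_attr(g, "state_from", expr$groups[1])
  g <- igraph::set_graph_attr(g, "state_to", expr$groups[2])
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  if (length(nodes) == 0L) return(g)

  prow <- match(nodes, ptab$id)
  g <- igraph::add_vertices(
    g, length(nodes), name = nodes,
    pathwayName = unname(collection$names[nodes]),
    T = ptab$T[prow], q = ptab$q[prow])

  # step 2: candidate crosstalk regions among enriched pathways
  reg <- crosstalk_regions(collection, nodes, min_region_size = min_region_size)
  if (nrow(reg) == 0L) return(g)

  # step 3: region enrichment (its own BH family)
  region_sets <- stats::setNames(reg$genes, paste(reg$a, reg$b, sep = "|"))
  rtab <- enrich(expr, region_sets, alpha = alpha, mode = mode,
                 n_perm = n_perm, min_set_size = 1L, u_cap = u_cap)
  keep <- which(rtab$enriched)
  if (verbose)
    message(sum(!is.na(rtab$p)), " crosstalk regions tested, ", length(keep),
            " enriched at q < ", alpha)

  # step 4: integrate
  if (length(keep) > 0L) {
    g <- igraph::add_edges(
      g, rbind(reg$a[keep], reg$b[keep]),
      regionSize = reg$size[keep], T = rtab$T[keep], q = rtab$q[keep],
      jaccard = reg$jaccard[keep])
  }
  g
}

#' Write / read a network in GML
#'
#' `write_gml()` writes the graph with its declared node and edge attributes
#' in the GML dialect used by common graph toolkits (integer node `id`,
#' `label` = pathway id); `read_gml()` reads it back, restoring `label` as
#' the vertex name so the round trip is lossless for node ids, edges, and
#' attributes. Isolated nodes are preserved.
#'
#' @param graph an undirected [igraph::igraph].
#' @param path file path.
#' @return `write_gml()`: `path`, invisibly. `read_gml()`: the graph.
#' @export
write_gml <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  g <- graph
  # GML reserves `id` for the integer node key igraph writes itself
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  if ("name" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "label",
                                 value = igraph::V(g)$name)
    g <- igraph::delete_vertex_attr(g, "name")
  }
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' @rdname write_gml
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- tryCatch(igraph::read_graph(path, format = "gml"),
                error = function(e) stop("GML parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if ("label" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(igraph::V(g)$label))
    g <- igraph::delete_vertex_attr(g, "label")
  }
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
  g
}

# Canonical sorted-pair edge keys ("a|b" with a < b) of a named graph.
edge_keys <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(character())
  el <- igraph::as_edgelist(graph, names = TRUE)
  apply(el, 1L, function(r) paste(sort(r), collapse = "|"))
}

#' Node and edge Jaccard similarity of two networks
#'
#' @param g1,g2 undirected named [igraph::igraph]s over the same pathway
#'   namespace; not both empty.
#' @return list with `node_jaccard` and `edge_jaccard`, each in \[0, 1\].
#'   When neither graph has any edge the edge comparison is undefined and
#'   `edge_jaccard` is `NA`.
#' @export
compare_networks <- function(g1, g2) {
  stopifnot(igraph::is_igraph(g1), igraph::is_igraph(g2))
  n1 <- igraph::V(g1)$name; n2 <- igraph::V(g2)$name
  if (length(n1) == 0L && length(n2) == 0L)
    stop("both graphs are empty; similarity undefined")
  e1 <- edge_keys(g1); e2 <- edge_keys(g2)
  list(
    node_jaccard = jaccard(n1, n2),
    edge_jaccard = if (length(e1) == 0L && length(e2) == 0L) NA_real_
                   else jaccard(e1, e2))
}
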