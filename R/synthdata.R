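#' Simulation parameters
#'
#' Study conditions for the synthetic generator: pathway collections with
#' controlled pairwise overlap, and two-group Gaussian abundance matrices
#' with planted mean-shift perturbations. Defaults mirror a small
#' two-condition RNA profiling design with 6 samples per group.
#'
#' @param n_pathways number of pathways (default 10).
#' @param genes_per_pathway genes per pathway, overlap included
#'   (default 20).
#' @param overlap_size shared genes for each planned pathway pair
#'   (default 4).
#' @param n_background_genes genes outside every pathway (default 100).
#' @param samples_per_group samples in each of the two groups (default 6).
#' @param delta effect size: mean shift of affected genes in the target
#'   group, in units of `sigma` (default 3).
#' @param sigma per-gene noise standard deviation (default 1).
#' @param baseline_mean baseline abundance mean (default 10; large enough
#'   that flooring at 0 is negligible at the default noise level).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_pathways = 10L, genes_per_pathway = 20L,
                       overlap_size = 4L, n_background_genes = 100L,
                       samples_per_group = 6L, delta = 3, sigma = 1,
                       baseline_mean = 10) {
  if (overlap_size >= genes_per_pathway)
    stop("overlap_size must be smaller than genes_per_pathway")
  if (samples_per_group < 2L) stop("need at least 2 samples per group")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 overlap_size = as.integer(overlap_size),
                 n_background_genes = as.integer(n_background_genes),
                 samples_per_group = as.integer(samples_per_group),
                 delta = delta, sigma = sigma,
                 baseline_mean = baseline_mean),
            class = "sim_params")
}

#' Generate a pathway collection with planned overlaps
#'
#' Builds `n_pathways` gene sets of exactly `genes_per_pathway` genes each.
#' Every pair listed in `pair_plan` shares exactly `overlap_size` genes
#' (dedicated to that pair); all other pairs are disjoint. Gene ids are
#' deterministic given the seed.
#'
#' @param params a [sim_params()].
#' @param pair_plan list of length-2 character vectors of pathway ids
#'   (`"P1"` ... `"Pn"`), or a 2-column matrix; default empty (all
#'   pathways disjoint).
#' @param seed integer RNG seed.
#' @return a [pathway_collection()] with pathways `P1..Pn`.
#' @export
make_collection <- function(params = sim_params(), pair_plan = list(),
                            seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  ids <- paste0("P", seq_len(params$n_pathways))
  if (is.matrix(pair_plan))
    pair_plan <- split(pair_plan, row(pair_plan))
  pair_plan <- lapply(pair_plan, function(p) sort(as.character(p)))
  if (length(pair_plan)) {
    keys <- vapply(pair_plan, paste, "", collapse = "|")
    if (anyDuplicated(keys)) stop("pair_plan pairs must be distinct")
    bad <- unlist(pair_plan)[!unlist(pair_plan) %in% ids]
    if (length(bad)) stop("unknown pathway id(s) in pair_plan: ",
                          paste(unique(bad), collapse = ", "))
    if (any(vapply(pair_plan, function(p) p[1] == p[2], TRUE)))
      stop("pair_plan pairs must join distinct pathways")
  }
  plan_degree <- stats::setNames(integer(length(ids)), ids)
  for (p in pair_plan) plan_degree[p] <- plan_degree[p] + 1L
  if (any(plan_degree * params$overlap_size > params$genes_per_pathway - 1L))
    stop("infeasible plan: planned overlaps exceed pathway size")
  gene_counter <- 0L
  fresh <- function(k) {
    g <- sprintf("g%05d", gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    g
  }
  sets <- stats::setNames(replicate(length(ids), character(), simplify = FALSE), ids)
  for (p in pair_plan) {
    shared <- fresh(params$overlap_size)
    sets[[p[1]]] <- c(sets[[p[1]]], shared)
    sets[[p[2]]] <- c(sets[[p[2]]], shared)
  }
  for (id in ids)
    sets[[id]] <- c(sets[[id]],
                    fresh(params$genes_per_pathway - length(sets[[id]])))
  pathway_collection(sets, names = paste("synthetic pathway", seq_along(ids)))
}

#' Planted ground truth
#'
#' @param collection a [pathway_collection()].
#' @param perturbed_pathways pathway ids planted as perturbed.
#' @param perturbed_regions list of length-2 vectors of pathway ids (pairs
#'   among `perturbed_pathways` whose shared genes are also shifted).
#' @return list of class `synthetic_truth` with `perturbed_pathways`,
#'   `perturbed_regions` (canonical sorted pairs), and the derived
#'   `affected_genes`: the exclusive genes (members of no other pathway) of
#'   each perturbed pathway, plus the shared genes of each perturbed
#'   region. Shared genes of pairs *not* listed stay unshifted, keeping the
#'   edge ground truth unambiguous.
#' @export
synthetic_truth <- function(collection, perturbed_pathways,
                            perturbed_regions = list()) {
  stopifnot(inherits(collection, "pathway_collection"))
  ids <- names(collection$sets)
  if (!all(perturbed_pathways %in% ids))
    stop("unknown pathway id in perturbed_pathways")
  perturbed_regions <- lapply(perturbed_regions,
                              function(p) sort(as.character(p)))
  for (p in perturbed_regions) {
    if (!all(p %in% perturbed_pathways))
      stop("perturbed_regions must join perturbed pathways")
    if (length(intersect(collection$sets[[p[1]]], collection$sets[[p[2]]])) == 0L)
      stop("perturbed region ", paste(p, collapse = "|"),
           " has an empty crosstalk region")
  }
  gene_count <- table(unlist(collection$sets, use.names = FALSE))
  affected <- character()
  for (id in perturbed_pathways) {
    g <- collection$sets[[id]]
    affected <- c(affected, g[gene_count[g] == 1L])  # exclusive genes
  }
  for (p in perturbed_regions)
    affected <- c(affected,
                  intersect(collection$sets[[p[1]]], collection$sets[[p[2]]]))
  structure(list(perturbed_pathways = sort(unique(perturbed_pathways)),
                 perturbed_regions = perturbed_regions,
                 affected_genes = sort(unique(affected))),
            class = "synthetic_truth")
}

#' Simulate a two-group expression matrix under a planted truth
#'
#' Every gene (pathway universe plus background genes) is drawn
#' Normal(`baseline_mean`, `sigma`^2) in the reference group A. In the
#' target group B, genes in `truth$affected_genes` get an additional
#' `+delta * sigma` mean shift; all others are unshifted. Values are
#' floored at 0 (abundances are nonnegative).
#'
#' @param collection a [pathway_collection()].
#' @param truth a [synthetic_truth()] consistent with `collection`.
#' @param params a [sim_params()].
#' @param seed integer RNG seed; the matrix is bitwise-reproducible given
#'   (collection, truth, params, seed).
#' @return an [expr_matrix()] with groups `"A"` (reference) and `"B"`.
#' @export
simulate_expression <- function(collection, truth, params = sim_params(),
                                seed = 1L) {
  stopifnot(inherits(collection, "pathway_collection"),
            inherits(truth, "synthetic_truth"),
            inherits(params, "sim_params"))
  universe <- collection_universe(collection)
  if (!all(truth$affected_genes %in% universe))
    stop("truth affects genes outside the collection universe")
  genes <- c(universe,
             if (params$n_background_genes > 0L)
               sprintf("bg%05d", seq_len(params$n_background_genes)))
  ns <- params$samples_per_group
  samples <- c(paste0("A", seq_len(ns)), paste0("B", seq_len(ns)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  values <- matrix(stats::rnorm(length(genes) * 2 * ns,
                                mean = params$baseline_mean,
                                sd = params$sigma),
                   nrow = length(genes), ncol = 2 * ns,
                   dimnames = list(genes, samples))
  affected <- genes %in% truth$affected_genes
  values[affected, ns + seq_len(ns)] <-
    values[affected, ns + seq_len(ns)] + params$delta * params$sigma
  values[values < 0] <- 0
  design <- stats::setNames(rep(c("A", "B"), each = ns), samples)
  expr_matrix(values, design, reference = "A")
}

#' Recovery of a planted truth by a built network
#'
#' Node metrics compare the network's node set against the planted
#' perturbed pathways over the whole collection; edge metrics compare the
#' network's edge set against the planted region pairs over all candidate
#' pairs (overlapping pairs) among the planted pathways.
#'
#' @param graph a PXPN built from data simulated under `truth`.
#' @param truth a [synthetic_truth()].
#' @param collection the [pathway_collection()] used for the simulation.
#' @return list with `node_sensitivity`, `node_specificity`,
#'   `edge_sensitivity`, `edge_specificity`, each in \[0, 1\] (`NA` where
#'   the denominator is empty, e.g. sensitivity under an empty truth).
#' @export
recovery_metrics <- function(graph, truth, collection) {
  stopifnot(igraph::is_igraph(graph), inherits(truth, "synthetic_truth"),
            inherits(collection, "pathway_collection"))
  all_ids <- names(collection$sets)
  found_nodes <- igraph::V(graph)$name
  planted <- truth$perturbed_pathways
  nonplanted <- setdiff(all_ids, planted)
  node_sens <- if (length(planted) == 0L) NA_real_
               else length(intersect(found_nodes, planted)) / length(planted)
  node_spec <- if (length(nonplanted) == 0L) NA_real_
               else 1 - length(intersect(found_nodes, nonplanted)) / length(nonplanted)
  cand <- crosstalk_regions(collection, planted)
  cand_keys <- if (nrow(cand)) paste(cand$a, cand$b, sep = "|") else character()
  planted_keys <- vapply(truth$perturbed_regions, paste, "", collapse = "|")
  found_keys <- edge_keys(graph)
  neg_keys <- setdiff(cand_keys, planted_keys)
  edge_sens <- if (length(planted_keys) == 0L) NA_real_
               else length(intersect(found_keys, planted_keys)) / length(planted_keys)
  edge_spec <- if (length(neg_keys) == 0L) NA_real_
               else 1 - length(intersect(found_keys, neg_keys)) / length(neg_keys)
  list(node_sensitivity = node_sens, node_specificity = node_spec,
       edge_sensitivity = edge_sens, edge_specificity = edge_spec)
}
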