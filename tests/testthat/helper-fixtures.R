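# Shared fixture builders. Everything is generated in code; no binary data.

# Small hand-written collection with known overlap structure.
toy_collection <- function() {
  pathway_collection(list(
    PA = c("g1", "g2", "g3"),
    PB = c("g3", "g4"),
    PC = c("g5", "g6"),
    PD = c("g1", "g4", "g7")
  ))
}

# Random collection over a small universe (for brute-force comparisons).
random_collection <- function(n_pathways, universe_size, set_size, seed) {
  withr::local_seed(seed)
  universe <- sprintf("u%03d", seq_len(universe_size))
  sets <- lapply(seq_len(n_pathways), function(i)
    sample(universe, set_size))
  names(sets) <- paste0("R", seq_len(n_pathways))
  pathway_collection(sets)
}

# Independent brute-force all-pairs overlap scan (oracle for
# crosstalk_regions / build_pxn).
brute_force_pairs <- function(collection, min_size = 1L) {
  ids <- sort(names(collection$sets))
  out <- character()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      shared <- intersect(collection$sets[[ids[i]]], collection$sets[[ids[j]]])
      if (length(shared) >= min_size)
        out <- c(out, paste(ids[i], ids[j], sep = "|"))
    }
  }
  out
}

# Standard planted-signal scenario used across modules: 10 pathways,
# P1-P2-P3 overlap in a chain plus P1-P3, P4-P5 overlap; P1..P3 perturbed
# with the P1|P2 and P2|P3 regions shifted.
planted_scenario <- function() {
  params <- sim_params()
  plan <- list(c("P1", "P2"), c("P2", "P3"), c("P1", "P3"), c("P4", "P5"))
  collection <- make_collection(params, plan, seed = 42)
  truth <- synthetic_truth(collection, c("P1", "P2", "P3"),
                           list(c("P1", "P2"), c("P2", "P3")))
  list(params = params, collection = collection, truth = truth, plan = plan)
}

null_scenario <- function() {
  params <- sim_params(delta = 0)
  plan <- list(c("P1", "P2"), c("P2", "P3"), c("P4", "P5"))
  collection <- make_collection(params, plan, seed = 42)
  truth <- synthetic_truth(collection, character(0))
  list(params = params, collection = collection, truth = truth)
}

# Tiny deterministic two-group matrix.
toy_expr <- function(values, genes, n_a = 3, n_b = 3) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  design <- stats::setNames(rep(c("ctrl", "case"), c(n_a, n_b)), colnames(m))
  expr_matrix(m, design, reference = "ctrl")
}
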