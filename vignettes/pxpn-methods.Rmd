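---
title: "Pathway crosstalk perturbation networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway crosstalk perturbation networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxpn)
library(igraph)
```

## The model

Biological pathways communicate through *crosstalk*: molecules shared by
two pathways let a perturbation propagate between processes. This package
operationalizes a pathway purely as a gene set, and crosstalk between two
pathways as a non-empty intersection of their gene sets — the *crosstalk
region*. Pathway topology (directed molecular interaction graphs) is
deliberately not modeled; only membership is used.

Given an expression matrix for two physiological states and a pathway
collection, a *pathway crosstalk perturbation network* (PXPN) is built in
four steps:

1. **Perturbed pathways.** Every pathway is tested for enrichment in
   per-gene perturbation between the two states; pathways with BH-adjusted
   q < α become nodes.
2. **Candidate crosstalk.** All pairwise gene-set intersections *among the
   step-1 nodes* are enumerated. Crosstalk of unperturbed pathways is never
   tested — the model asks how perturbed processes communicate, not how all
   processes do.
3. **Perturbed crosstalk regions.** Each candidate region is itself tested
   as a gene set with the same enrichment function, and BH-adjusted within
   its own family (regions are a separate multiple-testing universe from
   pathways, because the two families answer different questions and are
   produced by separate enrichment runs).
4. **Integration.** Nodes from step 1 and the edges surviving step 3 form
   an undirected graph. An enriched pathway with no enriched region stays
   in the graph as an isolated ("single") node; isolation is informative —
   a pathway can have large crosstalk *potential* yet perturb none of it.

The reference container for all networks is an `igraph` graph, and all
network I/O uses GML, the dialect common to igraph, NetworkX and Cytoscape.

## The enrichment function and its default

The model is agnostic to the enrichment statistic: `enrich()` is the
pluggable contract (scores in, per-set statistic + p out), and any gene-set
method could stand behind it. The default is fully specified so results
are reproducible from this package alone:

* **Per-gene score.** A Welch two-sample *t* statistic of the target state
  against the reference state, per gene. Perturbation is *undirected*:
  the score is the absolute statistic, so up- and down-regulation count
  equally and the graph does not depend on the direction of the contrast
  (the transition label is metadata).
* **Per-set statistic.** A Welch two-sample *t* comparing member scores
  against all non-member scores, with an upper-tail p-value under Student's
  *t* with Welch–Satterthwaite degrees of freedom. A permutation mode is
  available: p = (1 + #{random same-size sets with mean score ≥ observed})
  / (1 + n_perm), add-one corrected so p > 0; on small universes the
  permutation null can be enumerated exhaustively.
* **FDR control.** Benjamini–Hochberg across all sets tested in one call;
  a set is enriched when q < α (default α = 0.05). BH assumes positive
  regression dependence; gene sets overlap, so this is approximate — the
  type-I property test below checks the realized family-wise behaviour on
  null data.

Numerical conventions, chosen once:

* Genes with zero variance in both groups but unequal means would give an
  infinite *t*; their undirected score is capped at `u_cap = 50`
  (configurable), which keeps them maximally ranked without producing
  infinities downstream.
* A crosstalk region may contain a single gene and is still meaningful
  crosstalk, so regions are tested from size 1 (`min_set_size` for
  pathways defaults to 2). A singleton set has no sample variance; its
  variance term is taken as 0, so the statistic reduces to
  (score − mean(non-members)) / SE(non-members) with df = n − 1 over the
  non-members. This keeps the same two-sample form defined at m = 1.
* Genes with zero expression in every sample are removed before scoring.

## Topological summary conventions

`topology_summary()` reports nodes, edges, density 2E/(N(N−1)), average
degree 2E/N, mean local clustering, mean shortest path, connected
components, and degree-0 nodes. Two conventions are explicit because
different toolkits disagree:

* **Clustering.** Nodes of degree < 2 contribute 0 to the mean (the
  igraph/NetworkX `isolates = "zero"` convention). The alternative —
  excluding them — is available via `clustering_isolates = "exclude"`.
* **Shortest paths.** The mean is taken over reachable pairs within
  components; unreachable pairs are excluded. PXPNs are typically highly
  disconnected (tens of components), and this convention is the one that
  yields finite path lengths for such graphs.

The *specific density* divides the edge count not by all node pairs but by
the number of *possible* crosstalks among the network's nodes — pairs
whose gene sets actually overlap. It is the meaningful saturation measure
here, since non-overlapping pathways can never be connected; it always
dominates the raw density.

Communities are detected with the map-equation (Infomap) algorithm as
implemented in igraph. Infomap is stochastic, so the seed and the number
of trials (default 10, best codelength kept) are explicit arguments and
the partition is deterministic given both. Community ids are renumbered
contiguously from 0. `community_quotient()` collapses each community to a
meta-node and weights each meta-edge by the number of crossing edges,
giving the "network of networks" view of inter-community rewiring.

## Null models

Two complementary nulls separate real structure from pipeline artifacts:

* **Jaccard-weighted rewiring** (`rewire_ensemble()`). Each replicate
  keeps the node set and edge count and redraws the edges, without
  replacement, from the candidate pairs (overlapping node pairs) with
  probability proportional to the pairwise Jaccard index. The phrase
  "rewiring probability proportional to the Jaccard index" admits several
  mechanisms; weighted sampling without replacement is the implemented
  one because it is a well-defined distribution with exactly the stated
  proportionality. A degree-preserving swap variant is out of scope. Each
  observed metric is compared against the replicate distribution with a
  Z-test (sample sd, two-sided normal p); conserved metrics (nodes,
  edges) have zero null sd and an undefined z, reported as `NA`.
* **Gene-label shuffling** (`shuffle_ensemble()`). Each replicate permutes
  the gene labels of the expression matrix — preserving every sample's
  value multiset — rebuilds the PXPN with the identical pipeline, and
  classifies the result. The classification precedence is fixed: empty →
  single edge → clique (≥ 3 non-isolated, mutually adjacent nodes) → star
  (≥ 3 edges through one common node) → other; so a triangle is a clique,
  not a star, and a single edge is its own class.

Replicate RNG streams are derived from the master seed by replicate index,
so ensembles are reproducible and could be computed in parallel without
coordination.

## The synthetic-data generator

Because the package must be testable end to end without external data,
`make_collection()` / `simulate_expression()` generate the full input:

* A collection of `n_pathways` gene sets (default 10) of
  `genes_per_pathway` genes (default 20), in which *planned* pairs share
  exactly `overlap_size` dedicated genes (default 4) and all other pairs
  are disjoint — so the true crosstalk structure is known by construction.
* Abundances are Gaussian: every gene is Normal(`baseline_mean` = 10,
  `sigma` = 1) in the reference group; in the target group the *affected*
  genes are shifted by `delta`·`sigma` (default δ = 3). Affected genes are
  the exclusive genes of planted perturbed pathways plus the shared genes
  of planted perturbed regions; shared genes of unplanted pairs stay
  unshifted, which keeps the edge ground truth unambiguous. Values are
  floored at 0; with the default baseline this is a ~10σ event and
  negligible. Each group has `samples_per_group` = 6 samples, a typical
  small two-condition RNA profiling design.

Gaussian abundances (rather than negative-binomial counts) are used
because the default enrichment is *t*-based and the model itself is
data-type agnostic; the generator's job is to make recovery tests sharp,
not to emulate sequencing noise. Consequently the passing recovery tests
demonstrate correctness of the *pipeline* under its own assumptions; they
do not demonstrate robustness to count overdispersion, library-size
variation, batch effects, or correlated genes, which real RNA-seq data
exhibit.

`recovery_metrics()` scores a built network against the planted truth:
node sensitivity/specificity over pathways, edge sensitivity/specificity
over candidate pairs among the planted pathways.

## Validation problem sizes

The test suite validates: Welch/BH primitives against independent oracles
to 1e-9; exhaustive permutation enumeration on 6-gene universes; rewiring
frequencies against binomial/weighted-sampling expectations over 5000
replicates (±3 sd bands); label-shuffle nulls on unperturbed data (δ = 0)
giving ≥ 80% empty networks over 200 replicates; planted recovery at
δ = 3, n = 6 + 6 over 100 seeds (mean node sensitivity ≥ 0.9, edge
sensitivity ≥ 0.8); and closed forms on complete graphs K₃–K₈. These sizes
were chosen so each property has a tight sampling band while the whole
suite stays interactive.

## Other design choices

* Every GMT line is treated as an independent gene set; no attempt is made
  to deduplicate hierarchically related pathways (e.g. parent/child sets
  of a curated database) — that is the collection curator's decision.
* Pairs with several topologically disconnected shared gene groups are
  not distinguished: a pair has one crosstalk region, its full
  intersection, because membership (not pathway topology) defines regions
  in this model.
* Gene identifiers match case-sensitively by default; an optional
  case-folding mode exists for vendor GMTs, off by default because silent
  folding can merge distinct symbols (a real hazard with murine
  mixed-case symbols).
* `read_gml()` accepts attribute-free GML: externally produced networks
  (e.g. published supplementary files) may carry only ids and edges, and
  all topology functions work without attributes.
* The command-line interface (`inst/scripts/pxpn.R`) is a thin wrapper
  over the exported functions — everything it does is reproducible from
  the R API.

## Known limitations

* The default enrichment is not a reimplementation of GAGE or any other
  published gene-set method; substitute an adapter through the enrichment
  contract if a specific method is required.
* Region BH families depend on the step-1 node set, so edge sets are not
  monotone in α (node sets are).
* BH under overlapping sets is approximate FDR control (see above).
* Directed (up/down separated) enrichment reporting and moderated-variance
  statistics are out of scope.
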