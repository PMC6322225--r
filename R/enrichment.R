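#' Two-condition expression matrix
#'
#' Container for a genes-by-samples abundance matrix (any nonnegative
#' measure: counts, FPKM, intensities) with a two-group sample design.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames); nonnegative.
#' @param design named character vector mapping every sample id to one of
#'   exactly two group labels; each group needs at least 2 samples.
#' @param reference reference group label (state A / "from" state). Default:
#'   first design level in order of appearance.
#' @return object of class `expr_matrix` with elements `values`, `design`,
#'   `groups` (length-2: reference, target).
#' @export
expr_matrix <- function(values, design, reference = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` needs unique rownames (gene ids)")
  if (is.null(colnames(values))) stop("`values` needs colnames (sample ids)")
  if (any(values < 0)) stop("abundances must be nonnegative")
  design <- stats::setNames(as.character(design), names(design))
  if (is.null(names(design)) || !setequal(names(design), colnames(values)))
    stop("`design` must be named by exactly the sample ids of `values`")
  design <- design[colnames(values)]
  groups <- unique(unname(design))
  if (length(groups) != 2L) stop("design must have exactly two group labels")
  if (!is.null(reference)) {
    if (!reference %in% groups) stop("unknown reference group: ", reference)
    groups <- c(reference, setdiff(groups, reference))
  }
  if (any(table(design) < 2L)) stop("each group needs at least 2 samples")
  structure(list(values = values, design = design, groups = groups),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$design)
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Drop genes with zero abundance in every sample
#'
#' @param expr an [expr_matrix()].
#' @return the filtered `expr_matrix`, row order preserved.
#' @export
filter_genes <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- rowSums(expr$values != 0) > 0L
  if (!any(keep)) stop("no expressed genes after filtering")
  expr_matrix(expr$values[keep, , drop = FALSE], expr$design,
              reference = expr$groups[1])
}

# Vectorized Welch t statistics (target group B vs reference A), one per row.
# Zero-variance rows: equal means -> 0; unequal means -> sign * cap.
welch_t_rows <- function(values, is_b, cap = 50) {
  xa <- values[, !is_b, drop = FALSE]
  xb <- values[, is_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  degenerate <- se2 == 0
  t[degenerate] <- sign(mb - ma)[degenerate] * cap
  t[degenerate & mb == ma] <- 0
  t
}

#' Per-gene perturbation scores
#'
#' Scores each gene's change from the reference state to the target state
#' with a Welch two-sample t statistic. In undirected mode (the default) the
#' score is the absolute statistic, so perturbation in either direction
#' counts equally and the scores are invariant to swapping the group labels.
#'
#' @param expr an [expr_matrix()] (filtered).
#' @param directed if `TRUE`, return the signed statistic (target minus
#'   reference); default `FALSE` (absolute value).
#' @param u_cap cap assigned to zero-variance genes with unequal group means
#'   (default 50): keeps them maximally ranked without infinities.
#' @return named numeric vector of per-gene scores.
#' @export
gene_scores <- function(expr, directed = FALSE, u_cap = 50) {
  stopifnot(inherits(expr, "expr_matrix"))
  is_b <- unname(expr$design) == expr$groups[2]
  t <- welch_t_rows(expr$values, is_b, cap = u_cap)
  names(t) <- rownames(expr$values)
  if (directed) t else abs(t)
}

# Welch t of member scores vs non-member scores, upper-tail p under Student
# t with Welch-Satterthwaite df. A singleton member set contributes zero
# variance, so the statistic reduces to (score - mean(rest))/SE(rest) with
# df = n_rest - 1.
welch_members_vs_rest <- function(scores, member_idx) {
  x <- scores[member_idx]
  y <- scores[-member_idx]
  nx <- length(x); ny <- length(y)
  vx <- if (nx > 1L) stats::var(x) else 0
  vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  d <- mean(x) - mean(y)
  if (se2 == 0) {
    if (d == 0) return(c(T = 0, p = 0.5))
    return(c(T = sign(d) * Inf, p = if (d > 0) 0 else 1))
  }
  tt <- d / sqrt(se2)
  num <- se2^2
  den <- if (nx > 1L) (vx / nx)^2 / (nx - 1) else 0
  den <- den + (vy / ny)^2 / (ny - 1)
  df <- num / den
  c(T = tt, p = stats::pt(tt, df = df, lower.tail = FALSE))
}

#' Gene-set statistic for one set
#'
#' Default enrichment primitive: Welch two-sample t comparing the scores of
#' member genes against all non-member genes, with an upper-tail parametric
#' p (Welch-Satterthwaite df). In permutation mode the p-value is instead
#' `(1 + #{random same-size sets with mean score >= observed}) / (1 + n_perm)`
#' (add-one corrected, so p > 0).
#'
#' @param scores named numeric vector of per-gene scores (see
#'   [gene_scores()]).
#' @param members character vector of member gene ids; only those present in
#'   `scores` are used.
#' @param mode `"parametric"` (default) or `"permutation"`.
#' @param n_perm number of random sets in permutation mode (default 1000).
#' @param exhaustive in permutation mode, enumerate every same-size set
#'   instead of sampling (feasible only for small `choose(M, m)`); `n_perm`
#'   then becomes the number of enumerated sets.
#' @param min_set_size minimum member overlap to test (default 1).
#' @return list with `m` (member overlap size), `T`, `p`; `T`/`p` are `NA`
#'   (untested) when the overlap is below `min_set_size` or no non-member
#'   genes remain.
#' @export
set_statistic <- function(scores, members, mode = c("parametric", "permutation"),
                          n_perm = 1000L, exhaustive = FALSE,
                          min_set_size = 1L) {
  mode <- match.arg(mode)
  idx <- which(names(scores) %in% members)
  m <- length(idx)
  if (m < min_set_size || m >= length(scores))
    return(list(m = m, T = NA_real_, p = NA_real_))
  wt <- welch_members_vs_rest(scores, idx)
  if (mode == "parametric") {
    # keep p strictly positive so downstream BH preconditions hold
    p <- max(unname(wt["p"]), .Machine$double.xmin)
    return(list(m = m, T = unname(wt["T"]), p = p))
  }
  obs <- mean(scores[idx])
  if (exhaustive) {
    combos <- utils::combn(length(scores), m)
    hits <- sum(apply(combos, 2L, function(j) mean(scores[j]) >= obs))
    return(list(m = m, T = unname(wt["T"]),
                p = (1 + hits) / (1 + ncol(combos))))
  }
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (mean(scores[sample.int(length(scores), m)]) >= obs) hits <- hits + 1L
  }
  list(m = m, T = unname(wt["T"]), p = (1 + hits) / (1 + n_perm))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of raw p-values.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted q-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set enrichment over a two-condition matrix
#'
#' Scores genes with [gene_scores()] (undirected), applies
#' [set_statistic()] to each set, and BH-adjusts the raw p-values across all
#' sets tested in this call. A set is enriched when q < `alpha`.
#'
#' @param expr an [expr_matrix()] (filtered).
#' @param sets named list of character vectors (gene sets).
#' @param alpha enrichment significance threshold on the q-value
#'   (default 0.05).
#' @param mode,n_perm,min_set_size,u_cap passed through to the scoring and
#'   set statistic; see [set_statistic()] and [gene_scores()].
#' @return data.frame with columns `id`, `m`, `T`, `p`, `q`, `enriched`.
#'   Sets with member overlap below `min_set_size` keep `NA` p/q and are
#'   never enriched.
#' @export
enrich <- function(expr, sets, alpha = 0.05,
                   mode = c("parametric", "permutation"),
                   n_perm = 1000L, min_set_size = 2L, u_cap = 50) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(sets) == 0L || is.null(names(sets)))
    stop("`sets` must be a non-empty named list")
  scores <- gene_scores(expr, directed = FALSE, u_cap = u_cap)
  res <- lapply(sets, function(g)
    set_statistic(scores, g, mode = mode, n_perm = n_perm,
                  min_set_size = min_set_size))
  tab <- data.frame(
    id = names(sets),
    m = vapply(res, function(r) as.integer(r$m), 1L),
    T = vapply(res, `[[`, 1.0, "T"),
    p = vapply(res, `[[`, 1.0, "p"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$q <- NA_real_
  tested <- !is.na(tab$p)
  if (!any(tested))
    warning("no testable gene set (all below min_set_size)")
  tab$q[tested] <- bh_adjust(tab$p[tested])
  tab$enriched <- !is.na(tab$q) & tab$q < alpha
  tab
}
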