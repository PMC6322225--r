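#' Create a pathway collection
#'
#' A pathway collection is a named list of gene sets (character vectors of
#' gene identifiers) together with optional display names. The gene universe
#' is the union of all member sets.
#'
#' @param sets named list of character vectors; names are pathway ids.
#' @param names optional character vector of display names, parallel to
#'   `sets`; defaults to the ids.
#' @return an object of class `pathway_collection` with elements `sets`
#'   (named list, each a unique, sorted character vector) and `names`
#'   (named character vector of display names).
#' @export
pathway_collection <- function(sets, names = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  ids <- base::names(sets)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every pathway must have a non-empty id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate pathway id(s): ", paste(dup, collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    if (length(g) == 0L) stop("pathway gene sets must be non-empty")
    if (any(is.na(g) | g == "" | grepl("[[:space:]]", g)))
      stop("gene ids must be non-empty tokens without whitespace")
    sort(g)
  })
  if (is.null(names)) names <- ids
  names <- stats::setNames(as.character(names), ids)
  structure(list(sets = sets, names = names), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x$sets), "pathways,",
      length(collection_universe(x)), "genes in universe\n")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Gene universe of a collection
#'
#' @param collection a `pathway_collection`.
#' @return sorted character vector: the union of all member gene sets.
#' @export
collection_universe <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  sort(unique(unlist(collection$sets, use.names = FALSE)))
}

#' Read a GMT gene-set file
#'
#' Parses the MSigDB-style tab-separated GMT format: one gene set per line,
#' fields are set id, description, then member genes. Lines starting with
#' `#` and blank lines are skipped. Duplicate gene tokens within a line are
#' deduplicated.
#'
#' @param path path to a GMT file (UTF-8).
#' @param normalization gene-identifier normalization: `"none"` (default,
#'   case-sensitive exact match) or `"casefold"` (upper-case all symbols).
#'   Case-folding can merge distinct symbols and is off by default.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path, normalization = c("none", "casefold")) {
  normalization <- match.arg(normalization)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[f != ""]
    if (length(f) < 3L)
      stop("malformed GMT line ", lineno[i],
           ": expected at least 3 tab-separated fields, got ", length(f))
    genes <- f[-(1:2)]
    if (normalization == "casefold") genes <- toupper(genes)
    ids[i] <- f[1]
    nms[i] <- f[2]
    sets[[i]] <- unique(genes)
  }
  names(sets) <- ids
  pathway_collection(sets, names = nms)
}

#' Write a collection to GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors (treated as sets). Not both empty.
#' @return |a intersect b| / |a union b|, in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Crosstalk regions among pathways
#'
#' The crosstalk region of a pathway pair is the intersection of the two
#' member gene sets. One region is reported per unordered pair whose
#' intersection has at least `min_region_size` genes, in sorted pair order.
#'
#' @param collection a `pathway_collection`.
#' @param ids pathway ids to consider; default all. Must be known ids.
#' @param min_region_size minimum intersection size for a region (default 1,
#'   i.e. any non-empty overlap).
#' @return data.frame with columns `a`, `b` (sorted pathway-id pair,
#'   `a < b`), `size`, `jaccard`, and list-column `genes`.
#' @export
crosstalk_regions <- function(collection, ids = names(collection$sets),
                              min_region_size = 1L) {
  stopifnot(inherits(collection, "pathway_collection"))
  unknown <- setdiff(ids, names(collection$sets))
  if (length(unknown))
    stop("unknown pathway id(s): ", paste(unknown, collapse = ", "))
  ids <- sort(unique(ids))
  out <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      gi <- collection$sets[[ids[i]]]
      for (j in seq.int(i + 1L, length(ids))) {
        gj <- collection$sets[[ids[j]]]
        shared <- intersect(gi, gj)
        if (length(shared) >= min_region_size) {
          out[[length(out) + 1L]] <- list(
            a = ids[i], b = ids[j], size = length(shared),
            jaccard = length(shared) / length(union(gi, gj)),
            genes = list(sort(shared)))
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(), size = integer(),
                      jaccard = numeric(), genes = I(list())))
  df <- data.frame(
    a = vapply(out, `[[`, "", "a"),
    b = vapply(out, `[[`, "", "b"),
    size = vapply(out, function(r) as.integer(r$size), 1L),
    jaccard = vapply(out, `[[`, 1.0, "jaccard"),
    stringsAsFactors = FALSE)
  df$genes <- I(lapply(out, function(r) r$genes[[1]]))
  df
}

#' Build the full pathway crosstalk network (PXN)
#'
#' The PXN has one node per pathway in the collection and an undirected edge
#' for every pathway pair whose gene sets overlap (intersection of size at
#' least `min_region_size`). Edge attributes: `regionSize` and `jaccard`.
#'
#' @param collection a `pathway_collection`.
#' @param min_region_size minimum intersection size for an edge (default 1).
#' @return an undirected [igraph::igraph] with vertex attributes `name`
#'   (pathway id) and `pathwayName`.
#' @export
build_pxn <- function(collection, min_region_size = 1L) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (length(collection$sets) == 0L) stop("empty pathway collection")
  ids <- sort(names(collection$sets))
  reg <- crosstalk_regions(collection, ids, min_region_size = min_region_size)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            pathwayName = unname(collection$names[ids]))
  if (nrow(reg) > 0L) {
    g <- igraph::add_edges(g, rbind(reg$a, reg$b),
                           regionSize = reg$size, jaccard = reg$jaccard)
  }
  g
}
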