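## Overrepresentation analysis of the fold-change-gated DE mRNA list,
## category selection (an explicit curation step), gene pooling, and
## intersection with a disease gene list.

#' Hypergeometric overrepresentation test per gene set
#'
#' One-sided (upper tail) hypergeometric test of the overlap between a query
#' gene list and each set: \eqn{p = P(X \ge k)} with universe size
#' \eqn{N}, in-universe set size \eqn{K}, query size \eqn{n} and overlap
#' \eqn{k}. P-values are Benjamini-Hochberg adjusted across sets and the
#' result is sorted by adjusted p-value (ties by set name).
#'
#' @param query character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background gene ids; defaults to the
#'   collection's explicit universe. Conventionally the genes surviving the
#'   background filter, not the whole genome.
#' @return A data.frame sorted by \code{p_adj}: \code{set_name},
#'   \code{set_size} (in-universe), \code{query_size}, \code{universe_size},
#'   \code{overlap_count}, \code{overlap_members} (list column),
#'   \code{p_raw}, \code{p_adj}.
#' @export
overrepresentationTest <- function(query, sets, universe = geneSetUniverse(sets)) {
  stopifnot(is(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query gene list")
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe were dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes remain inside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(geneSetNames(sets), function(nm) {
    members <- intersect(geneSets(sets)[[nm]], universe)
    K <- length(members)
    overlap <- sort(intersect(members, query))
    k <- length(overlap)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(
      set_name = nm, set_size = K, query_size = n, universe_size = N,
      overlap_count = k, p_raw = p, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$overlap_members <- lapply(geneSetNames(sets), function(nm) {
    sort(intersect(intersect(geneSets(sets)[[nm]], universe), query))
  })
  res$p_adj <- bhAdjust(res$p_raw)
  res <- res[order(res$p_adj, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_name", "set_size", "query_size", "universe_size",
          "overlap_count", "overlap_members", "p_raw", "p_adj")]
}

#' Select enriched categories by rank and keyword
#'
#' The curation step: take the \code{topN} sets by adjusted p-value, then
#' keep those whose name or description matches any keyword
#' (case-insensitive substring), or exactly the explicitly named sets. The
#' selection should be recorded in the run manifest; it is a documented
#' choice, never automated biology.
#'
#' @param results enrichment data.frame from [overrepresentationTest()]
#'   (sorted by \code{p_adj}).
#' @param topN number of top sets to consider.
#' @param keywords character vector of substrings to match (e.g.
#'   \code{c("bacterium", "microb")}).
#' @param names explicit set names to select instead of keyword matching.
#' @param descriptions optional named character vector of set descriptions to
#'   match keywords against in addition to names.
#' @return Character vector of selected set names (possibly empty, with a
#'   warning).
#' @export
selectCategories <- function(results, topN = 15L, keywords = NULL, names = NULL,
                             descriptions = NULL) {
  stopifnot(is.data.frame(results), "set_name" %in% base::names(results))
  if (is.null(keywords) && is.null(names))
    stop("category selection needs either keywords or explicit set names; ",
         "this curation step cannot be left implicit")
  top <- utils::head(results$set_name, topN)
  if (!is.null(names)) {
    sel <- intersect(top, names)
  } else {
    text <- top
    if (!is.null(descriptions))
      text <- paste(top, descriptions[top])
    hit <- Reduce(`|`, lapply(keywords, function(k) {
      grepl(k, text, ignore.case = TRUE, fixed = FALSE)
    }))
    sel <- top[hit]
  }
  if (!length(sel))
    warning("no category matched the selection; empty selection returned")
  sel
}

#' Pool the unique query genes of the selected sets
#'
#' Union over the selected sets of (set members intersected with the query),
#' deduplicated and sorted. This is the "pooled unique genes" step that turns
#' several overlapping categories into one gene list.
#'
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param selected character vector of selected set names.
#' @param query character vector of query gene ids.
#' @return Sorted character vector of pooled gene ids.
#' @export
poolUniqueGenes <- function(sets, selected, query) {
  stopifnot(is(sets, "GeneSetCollection"))
  if (!length(selected)) stop("no selected categories to pool")
  missing <- setdiff(selected, geneSetNames(sets))
  if (length(missing))
    stop("selected sets absent from collection: ",
         paste(missing, collapse = ", "))
  pooled <- unlist(lapply(selected, function(nm) {
    intersect(geneSets(sets)[[nm]], query)
  }), use.names = FALSE)
  sort(unique(pooled))
}

#' Intersect two gene lists
#'
#' Sorted, case-sensitive exact-id intersection (the Venn-overlap step).
#'
#' @param a,b character vectors of gene ids.
#' @return Sorted character vector of common ids.
#' @export
intersectGeneLists <- function(a, b) {
  sort(intersect(as.character(a), as.character(b)))
}
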