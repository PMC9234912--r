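## Cross-layer Pearson correlation, threshold networks, refinement to a
## disease-gene subset, median-|R| hub ranking, and the OTU co-abundance
## network: the core of the cascade.

#' Pearson correlation between the features of two layers
#'
#' \eqn{r[f, g]} is the sample Pearson correlation between feature f of
#' layer A and feature g of layer B over the shared samples; two-sided
#' p-values come from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2}
#' degrees of freedom (\eqn{r = \pm 1} gives p = 0). Intended to be run on
#' Z-score normalized matrices after log2 transformation.
#'
#' @param a,b \linkS4class{OmicsMatrix} objects with identical sample ids in
#'   identical order and at least 4 samples.
#' @return A \linkS4class{CorrelationMatrix} (rows = features of \code{a}).
#' @export
crossLayerCorrelation <- function(a, b) {
  stopifnot(is(a, "OmicsMatrix"), is(b, "OmicsMatrix"))
  if (!identical(sampleIds(a), sampleIds(b)))
    stop("sample ids must be identical and identically ordered")
  n <- ncol(a)
  if (n < 4L) stop("at least 4 samples are required")
  va <- omicsValues(a); vb <- omicsValues(b)
  sda <- apply(va, 1, stats::sd); sdb <- apply(vb, 1, stats::sd)
  if (any(sda == 0) || any(sdb == 0))
    stop("zero-variance features cannot be correlated: ",
         paste(utils::head(c(rownames(va)[sda == 0], rownames(vb)[sdb == 0]), 5),
               collapse = ", "))
  r <- stats::cor(t(va), t(vb))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  dimnames(p) <- dimnames(r)
  new("CorrelationMatrix", r = r, p = p, n = as.integer(n),
      layerA = omicsLayer(a), layerB = omicsLayer(b))
}

#' Threshold a correlation matrix into a bipartite network
#'
#' An edge is kept when its correlation strictly exceeds \code{rMin}
#' (on \code{|r|} in \code{"absolute"} mode, on \code{r} in \code{"signed"}
#' mode) and, when \code{pMax} is not \code{NA}, its p-value is strictly
#' below \code{pMax}. Nodes left without a passing edge are dropped from
#' both sides; thresholds are recorded on the network.
#'
#' @param c a \linkS4class{CorrelationMatrix}.
#' @param rMin correlation threshold, in (0, 1), strict.
#' @param pMax p-value ceiling, strict; \code{NA} disables the p filter.
#' @param mode \code{"absolute"} (default) or \code{"signed"}.
#' @return A \linkS4class{BipartiteCorrelationNetwork}.
#' @export
buildNetwork <- function(c, rMin, pMax = 0.05, mode = c("absolute", "signed")) {
  stopifnot(is(c, "CorrelationMatrix"))
  mode <- match.arg(mode)
  if (length(rMin) != 1L || rMin <= 0 || rMin >= 1)
    stop("rMin must lie strictly between 0 and 1")
  if (is.null(pMax) || is.na(pMax)) pMax <- NA_real_
  r <- corValues(c); p <- corPvalues(c)
  pass <- if (mode == "absolute") abs(r) > rMin else r > rMin
  if (!is.na(pMax)) pass <- pass & (p < pMax)
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    source_id = rownames(r)[idx[, 1L]],
    source_layer = rep(c@layerA, nrow(idx)),
    target_id = colnames(r)[idx[, 2L]],
    target_layer = rep(c@layerB, nrow(idx)),
    pearson_r = r[idx],
    p_value = p[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  new("BipartiteCorrelationNetwork", edges = edges,
      layerA = c@layerA, layerB = c@layerB,
      rMin = rMin, pMax = pMax, mode = mode)
}

#' Restrict a network to a subset of side-B nodes
#'
#' Drops side-B nodes outside \code{keepB} (ids not present in the network
#' are warned about and ignored), then drops side-A nodes left isolated.
#' Thresholds are unchanged. This is the disease-gene refinement step.
#'
#' @param net a \linkS4class{BipartiteCorrelationNetwork}.
#' @param keepB character vector of side-B node ids to retain.
#' @return The restricted \linkS4class{BipartiteCorrelationNetwork}.
#' @export
restrictNetwork <- function(net, keepB) {
  stopifnot(is(net, "BipartiteCorrelationNetwork"))
  keepB <- unique(as.character(keepB))
  extra <- setdiff(keepB, sideBNodes(net))
  if (length(extra))
    warning(length(extra), " ids in keepB are not side-B nodes and were ignored")
  e <- networkEdges(net)
  e <- e[e$target_id %in% keepB, , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteCorrelationNetwork", edges = e,
      layerA = net@layerA, layerB = net@layerB,
      rMin = net@rMin, pMax = net@pMax, mode = net@mode)
}

#' Median-|R| node importance
#'
#' For every node on the chosen side of a network, the median of |r| to
#' \emph{all} opposite-side network nodes -- including sub-threshold pairs,
#' as in a full correlation heatmap -- taken from the dense correlation
#' matrix. Nodes are returned in descending importance; ties are broken
#' lexicographically by id.
#'
#' @param c the \linkS4class{CorrelationMatrix} the network was built from
#'   (or any correlation matrix covering the network's nodes).
#' @param net a \linkS4class{BipartiteCorrelationNetwork} defining the node
#'   sets.
#' @param axis which side to rank: \code{"a"} (rows of \code{c}) or
#'   \code{"b"} (columns).
#' @param direction optional named numeric vector (e.g. log2 fold-changes)
#'   whose sign is reported per node.
#' @return A data.frame: \code{node_id}, \code{median_abs_r},
#'   \code{direction} (sign of the supplied effect, or \code{NA}).
#' @export
medianImportance <- function(c, net, axis = c("a", "b"), direction = NULL) {
  stopifnot(is(c, "CorrelationMatrix"), is(net, "BipartiteCorrelationNetwork"))
  axis <- match.arg(axis)
  aIds <- sideANodes(net); bIds <- sideBNodes(net)
  missing <- base::c(setdiff(aIds, rownames(corValues(c))),
                     setdiff(bIds, colnames(corValues(c))))
  if (length(missing))
    stop("network nodes absent from the correlation matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  r <- abs(corValues(c)[aIds, bIds, drop = FALSE])
  med <- if (axis == "a") apply(r, 1, stats::median) else apply(r, 2, stats::median)
  ids <- if (axis == "a") aIds else bIds
  dir <- if (is.null(direction)) rep(NA_real_, length(ids)) else
    sign(unname(direction[ids]))
  out <- data.frame(node_id = ids, median_abs_r = unname(med),
                    direction = dir, stringsAsFactors = FALSE)
  out <- out[order(-out$median_abs_r, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' lncRNA:OTU co-abundance network with per-OTU sign consistency
#'
#' Correlates the refined hub lncRNAs with the differentially abundant OTUs
#' and thresholds at \code{|r| > rMin}, \code{p < pMax} (defaults 0.5 and
#' 0.05). Additionally reports, per retained OTU, whether its passing edges
#' are all positive, all negative, or mixed across the retained lncRNAs.
#'
#' @param lncSubset \linkS4class{OmicsMatrix} (zscore) of the refined
#'   network's lncRNA nodes.
#' @param otu \linkS4class{OmicsMatrix} (zscore) restricted to significantly
#'   different OTUs.
#' @param rMin,pMax thresholds (both strict).
#' @return A list: \code{network}
#'   (\linkS4class{BipartiteCorrelationNetwork}, side A = lncRNA, side B =
#'   OTU), \code{correlation} (the dense \linkS4class{CorrelationMatrix}),
#'   \code{sign_consistency} (data.frame \code{otu_id}, \code{n_pos},
#'   \code{n_neg}, \code{consistency}).
#' @export
otuCoabundance <- function(lncSubset, otu, rMin = 0.5, pMax = 0.05) {
  cm <- crossLayerCorrelation(lncSubset, otu)
  net <- buildNetwork(cm, rMin = rMin, pMax = pMax, mode = "absolute")
  e <- networkEdges(net)
  otus <- sideBNodes(net)
  signs <- do.call(rbind, lapply(otus, function(o) {
    rr <- e$pearson_r[e$target_id == o]
    data.frame(
      otu_id = o,
      n_pos = sum(rr > 0),
      n_neg = sum(rr < 0),
      consistency = if (all(rr > 0)) "positive" else
        if (all(rr < 0)) "negative" else "mixed",
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(signs))
    signs <- data.frame(otu_id = character(), n_pos = integer(),
                        n_neg = integer(), consistency = character(),
                        stringsAsFactors = FALSE)
  list(network = net, correlation = cm, sign_consistency = signs)
}
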