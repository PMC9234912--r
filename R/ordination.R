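## PCA-based sample separation per layer, a silhouette-style quantitative
## stand-in for "clearly separates", and deterministic heatmap ordering.

#' Principal component analysis of samples
#'
#' Singular-value decomposition of the samples x features matrix. Features
#' must already be Z-scored (correlation PCA: every feature is centered and
#' unit-variance across samples, which the \code{"zscore"} scale tag
#' certifies). Scores are the projections; \code{variance_fraction[i]} is
#' \eqn{\sigma_i^2 / \sum \sigma^2} over all components. Deterministic sign
#' convention: the largest-|loading| element of each component is positive.
#'
#' @param m an \linkS4class{OmicsMatrix} on the \code{"zscore"} scale with at
#'   least 3 samples.
#' @param nComponents number of score components to return.
#' @return An object of class \code{PcaResult}: list with \code{scores}
#'   (samples x nComponents, rownames = sample ids),
#'   \code{variance_fraction} (all components), \code{components_used}.
#' @export
pcaSamples <- function(m, nComponents = 2L) {
  stopifnot(is(m, "OmicsMatrix"))
  if (omicsScale(m) != "zscore")
    stop("pcaSamples expects Z-scored features (scale 'zscore')")
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  x <- t(omicsValues(m))  # samples x features; columns centered by Z-score
  kmax <- min(dim(x))
  if (nComponents > kmax)
    stop("nComponents exceeds min(samples, features) = ", kmax)
  sv <- svd(x)
  ## sign convention: largest-|loading| entry of each right singular vector > 0
  for (j in seq_len(kmax)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(nComponents), drop = FALSE] %*%
    diag(sv$d[seq_len(nComponents)], nrow = nComponents)
  rownames(scores) <- sampleIds(m)
  colnames(scores) <- paste0("PC", seq_len(nComponents))
  out <- list(
    scores = scores,
    variance_fraction = sv$d^2 / sum(sv$d^2),
    components_used = as.integer(nComponents)
  )
  class(out) <- "PcaResult"
  out
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf(
    "PcaResult: %d samples, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
    nrow(x$scores), x$components_used,
    100 * x$variance_fraction[1],
    if (length(x$variance_fraction) > 1) 100 * x$variance_fraction[2] else NA
  ))
  invisible(x)
}

#' Quantitative group separation in PC space
#'
#' A silhouette-style score of the group labels in PC1/PC2 space, used as
#' the quantitative stand-in for "clearly separates" on an ordination plot.
#' The centroid-based (simplified) silhouette is used: per sample,
#' \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} with \eqn{a_i} the Euclidean
#' distance to the own-group centroid and \eqn{b_i} the distance to the
#' other group's centroid (own-sample contribution excluded from neither;
#' centroids are plain group means). The score is the mean of \eqn{s_i},
#' in [-1, 1]: identical clouds give a score near 0, disjoint clouds
#' approach 1, and permuting the labels collapses it toward 0.
#'
#' @param pca a \code{PcaResult} with at least 2 components.
#' @param meta metadata data.frame with the \code{group} factor.
#' @return A list: \code{score} (mean simplified silhouette),
#'   \code{centroids} (group x PC matrix).
#' @export
groupSeparation <- function(pca, meta) {
  stopifnot(inherits(pca, "PcaResult"))
  if (ncol(pca$scores) < 2L) stop("two components are required")
  xy <- pca$scores[, 1:2, drop = FALSE]
  meta <- meta[rownames(xy), , drop = FALSE]
  grp <- droplevels(as.factor(meta$group))
  if (nlevels(grp) != 2L) stop("exactly two groups are required")
  cent <- rbind(
    colMeans(xy[grp == levels(grp)[1L], , drop = FALSE]),
    colMeans(xy[grp == levels(grp)[2L], , drop = FALSE])
  )
  rownames(cent) <- levels(grp)
  own <- cent[as.integer(grp), , drop = FALSE]
  other <- cent[3L - as.integer(grp), , drop = FALSE]
  a <- sqrt(rowSums((xy - own)^2))
  b <- sqrt(rowSums((xy - other)^2))
  s <- (b - a) / pmax(a, b)
  s[a == 0 & b == 0] <- 0
  list(score = mean(s), centroids = cent)
}

#' Deterministic heatmap row/column ordering
#'
#' K-means partitions the rows (fixed seed, 10 restarts, best inertia);
#' within each cluster, average-linkage hierarchical clustering on Euclidean
#' distance orders the rows; clusters are laid out by decreasing cluster
#' mean. Columns are ordered by the same hierarchical procedure on the
#' transpose (no k-means). Rows are first put in canonical (lexicographic)
#' id order, so the result is invariant to the input row permutation.
#'
#' @param m an \linkS4class{OmicsMatrix} (Z-scored values recommended).
#' @param k number of k-means row clusters (\code{k = 1} gives a pure
#'   hierarchical order).
#' @param seed integer seed for the k-means restarts.
#' @return A list: \code{row_order} (feature ids), \code{row_clusters}
#'   (named integer vector), \code{col_order} (sample ids).
#' @export
heatmapOrder <- function(m, k, seed = 1L) {
  stopifnot(is(m, "OmicsMatrix"))
  if (k < 1L || k > nrow(m)) stop("k must be in [1, n_features]")
  v <- omicsValues(m)
  v <- v[order(rownames(v)), , drop = FALSE]  # canonical order first
  if (k == 1L) {
    cl <- stats::setNames(rep(1L, nrow(v)), rownames(v))
  } else {
    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(v, centers = k, nstart = 10L, iter.max = 100L)
    cl <- stats::setNames(km$cluster, rownames(v))
  }
  ## clusters laid out by decreasing mean value, then ids ordered within by
  ## average-linkage hierarchical clustering
  clMeans <- tapply(rowMeans(v), cl, mean)
  clOrder <- as.integer(names(sort(clMeans, decreasing = TRUE)))
  rowOrder <- unlist(lapply(clOrder, function(g) {
    ids <- names(cl)[cl == g]
    if (length(ids) < 3L) return(sort(ids))
    hc <- stats::hclust(stats::dist(v[ids, , drop = FALSE]), method = "average")
    ids[hc$order]
  }), use.names = FALSE)
  colOrder <- if (ncol(v) < 3L) colnames(v) else {
    hc <- stats::hclust(stats::dist(t(v)), method = "average")
    colnames(v)[hc$order]
  }
  list(row_order = rowOrder, row_clusters = cl, col_order = colOrder)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
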