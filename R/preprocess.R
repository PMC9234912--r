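## Transformations applied ahead of inference: log2, background filtering,
## quantile normalization, empirical-Bayes batch adjustment, Z-scoring.
## All operations preserve feature and sample id order.

#' Log2-transform a raw matrix
#'
#' \code{out = log2(in + pseudocount)}. Intended for raw probe intensities
#' (pseudocount 0) and normalized OTU counts (pseudocount 1, since zeros
#' occur in count data).
#'
#' @param m an \linkS4class{OmicsMatrix} on the \code{"raw"} scale with
#'   non-negative values.
#' @param pseudocount non-negative offset added before the log.
#' @return An \linkS4class{OmicsMatrix} on the \code{"log2"} scale.
#' @export
log2Transform <- function(m, pseudocount = 0) {
  stopifnot(is(m, "OmicsMatrix"))
  if (omicsScale(m) != "raw")
    stop("log2Transform expects a matrix on the 'raw' scale, got '",
         omicsScale(m), "'")
  if (length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  v <- omicsValues(m)
  if (any(v < 0)) stop("negative values cannot be log2-transformed")
  if (pseudocount == 0 && any(v == 0))
    stop("zeros present with pseudocount 0 would give non-finite values")
  .withValues(m, log2(v + pseudocount), scale = "log2")
}

#' Per-sample background thresholds from negative-control features
#'
#' Summarizes designated negative-control rows into one threshold per sample:
#' \code{mean + 2 SD} of the control values in that sample (the default
#' summary; common array practice), or the plain mean.
#'
#' @param m an \linkS4class{OmicsMatrix} (log2 scale expected, same scale the
#'   thresholds will be compared on).
#' @param negctlIds feature ids of the negative-control rows.
#' @param method \code{"mean2sd"} (default) or \code{"mean"}.
#' @return Named numeric vector, one finite threshold per sample.
#' @export
computeBackground <- function(m, negctlIds, method = c("mean2sd", "mean")) {
  method <- match.arg(method)
  missing <- setdiff(negctlIds, featureIds(m))
  if (length(missing))
    stop("negative-control ids absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(negctlIds) < 2L && method == "mean2sd")
    stop("mean2sd background needs at least 2 negative-control features")
  v <- omicsValues(m)[negctlIds, , drop = FALSE]
  thr <- switch(method,
    mean2sd = colMeans(v) + 2 * apply(v, 2, stats::sd),
    mean = colMeans(v)
  )
  if (any(!is.finite(thr))) stop("non-finite background threshold")
  thr
}

#' Filter features by detection above background
#'
#' Keeps a feature when its value exceeds the per-sample background threshold
#' in at least \code{minFraction} of the samples (inclusive: "at least half"
#' means 72 of 144 is retained).
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param bg named numeric vector of per-sample thresholds on the same scale
#'   as \code{m} (names = sample ids), e.g. from [computeBackground()].
#' @param minFraction required fraction of samples above background, in
#'   \code{(0, 1]}.
#' @return The filtered \linkS4class{OmicsMatrix}; samples unchanged. A
#'   warning is raised if no feature survives.
#' @export
filterAboveBackground <- function(m, bg, minFraction = 0.5) {
  stopifnot(is(m, "OmicsMatrix"))
  if (length(minFraction) != 1L || minFraction <= 0 || minFraction > 1)
    stop("minFraction must be in (0, 1]")
  if (is.null(names(bg))) {
    if (length(bg) != ncol(m)) stop("one threshold per sample is required")
    names(bg) <- sampleIds(m)
  }
  if (!all(sampleIds(m) %in% names(bg)))
    stop("background thresholds missing for some samples")
  bg <- bg[sampleIds(m)]
  if (any(!is.finite(bg))) stop("background thresholds must be finite")
  v <- omicsValues(m)
  nAbove <- rowSums(sweep(v, 2, bg, ">"))
  keep <- nAbove >= minFraction * ncol(v)
  if (!any(keep))
    warning("no feature is above background in at least ",
            format(minFraction), " of the samples")
  .withValuesAllowEmpty(m, v[keep, , drop = FALSE])
}

## filtered matrices may legitimately be empty; bypass the non-empty invariant
.withValuesAllowEmpty <- function(m, values) {
  if (nrow(values) == 0L) {
    se <- SummarizedExperiment(assays = S4Vectors::SimpleList(exprs = values))
    new("OmicsMatrix", se, layer = omicsLayer(m), scale = omicsScale(m))
  } else {
    .withValues(m, values)
  }
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) to share one common value distribution: each
#' sample's sorted values are replaced by the across-sample mean of sorted
#' values; ties within a sample receive the mean of the reference quantiles
#' they span, so the operation is deterministic and idempotent. Ranks within
#' each sample are preserved. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param m an \linkS4class{OmicsMatrix} with no missing values.
#' @return The normalized \linkS4class{OmicsMatrix} (scale unchanged). A
#'   single-sample matrix is returned unchanged with a warning.
#' @importFrom limma normalizeQuantiles
#' @export
quantileNormalize <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  if (ncol(m) < 2L) {
    warning("quantile normalization of a single sample is the identity")
    return(m)
  }
  v <- limma::normalizeQuantiles(omicsValues(m), ties = TRUE)
  dimnames(v) <- dimnames(omicsValues(m))
  .withValues(m, v)
}

#' Empirical-Bayes batch adjustment (one factor)
#'
#' Parametric empirical-Bayes location/scale batch adjustment: per-feature
#' batch effects are estimated, shrunk toward normal (location) and
#' inverse-gamma (scale) priors with moment-matched hyperparameters, and
#' removed, while the two-group biological signal is preserved through the
#' model design. Delegates to \code{sva::ComBat} with
#' \code{mod = model.matrix(~ group)}. After adjustment, per-feature
#' within-group batch means agree within tolerance.
#'
#' Two batch factors (e.g. labeling and array) are adjusted sequentially, one
#' call per factor, in the order given by the pipeline configuration.
#'
#' @param m an \linkS4class{OmicsMatrix} (log2 scale).
#' @param meta metadata data.frame with a \code{group} factor and the batch
#'   column (see [readSampleMetadata()]).
#' @param factor name of the batch-factor column in \code{meta}.
#' @return The adjusted \linkS4class{OmicsMatrix}. A single batch level
#'   returns the input unchanged.
#' @importFrom sva ComBat
#' @importFrom stats model.matrix
#' @export
batchAdjust <- function(m, meta, factor) {
  stopifnot(is(m, "OmicsMatrix"))
  validateSampleMetadata(meta, m)
  if (!factor %in% names(meta)) stop("unknown batch factor: ", factor)
  meta <- meta[sampleIds(m), , drop = FALSE]
  batch <- droplevels(as.factor(meta[[factor]]))
  if (nlevels(batch) < 2L) return(m)
  if (any(table(batch) < 2L))
    stop("every level of '", factor, "' needs at least 2 samples")
  design <- stats::model.matrix(~ 0 + batch + meta$group)
  if (qr(design)$rank < ncol(design))
    stop("batch factor '", factor,
         "' is confounded with group; batch effect is inestimable")
  mod <- stats::model.matrix(~ group, data = meta)
  adj <- suppressMessages(
    sva::ComBat(dat = omicsValues(m), batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  )
  .withValues(m, adj)
}

#' Z-score features across samples
#'
#' Per feature: subtract the mean and divide by the sample standard deviation
#' (n - 1 denominator), so every row has mean 0 and SD 1.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @return An \linkS4class{OmicsMatrix} on the \code{"zscore"} scale.
#' @export
zscoreRows <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  v <- omicsValues(m)
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero))
    stop("zero-variance features cannot be Z-scored: ",
         paste(utils::head(rownames(v)[zero], 5), collapse = ", "),
         if (sum(zero) > 5) sprintf(" (and %d more)", sum(zero) - 5L) else "")
  .withValues(m, (v - mu) / sd, scale = "zscore")
}
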