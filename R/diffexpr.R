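## Two-group differential expression/abundance for all three layers.
## The moderated t-statistic is implemented here with an explicit,
## configurable prior degrees of freedom d0: d0 = 0 recovers the ordinary
## pooled t exactly, d0 -> Inf pools every feature's variance to s0^2, and
## d0 = NULL estimates (d0, s0^2) by moment-matching the distribution of
## log s^2 via digamma/trigamma equations.

.groupIndices <- function(m, meta) {
  validateSampleMetadata(meta, m)
  meta <- meta[sampleIds(m), , drop = FALSE]
  grp <- droplevels(as.factor(meta$group))
  lv <- levels(grp)
  list(a = which(grp == lv[1L]), b = which(grp == lv[2L]), levels = lv)
}

## Newton inversion of the trigamma function (for the d0 moment equation)
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

## moment-matching fit of the scaled inverse-chi-square prior on s^2:
## e_g = log s2_g - digamma(d_g/2) + log(d_g/2) has mean log s0^2 + digamma(d0/2)
## - log(d0/2) and variance trigamma(d_g/2) + trigamma(d0/2).
.fitVariancePrior <- function(s2, df) {
  ok <- s2 > 0
  s2 <- s2[ok]
  if (length(s2) < 2L)
    stop("too few positive residual variances to fit the prior")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * .trigammaInverse(excess)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

.deTable <- function(m, effect, tstat, df, layer) {
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[is.na(p) & effect == 0] <- 1  # 0/0 features: no evidence either way
  padj <- bhAdjust(p)
  data.frame(
    feature_id = featureIds(m),
    layer = layer,
    log2_fc = effect,
    statistic = tstat,
    df = df,
    p_raw = p,
    p_adj = padj,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per feature g with group means \eqn{\bar x_A, \bar x_B} and pooled residual
#' variance \eqn{s_g^2} on \eqn{d_g = n_A + n_B - 2} degrees of freedom, the
#' posterior variance is \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}
#' and the moderated statistic is
#' \eqn{t_g = (\bar x_A - \bar x_B) / (\tilde s_g \sqrt{1/n_A + 1/n_B})},
#' referred to a t-distribution on \eqn{d_0 + d_g} degrees of freedom.
#' The prior \eqn{(d_0, s_0^2)} is estimated by moment-matching the
#' distribution of \eqn{\log s_g^2} (features with \eqn{s_g^2 = 0} are
#' excluded from the fit).
#'
#' @param m an \linkS4class{OmicsMatrix} on the log2 scale.
#' @param meta metadata data.frame; effects are first group level minus
#'   second (see [readSampleMetadata()]).
#' @param d0 prior degrees of freedom: \code{NULL} (default) estimates it;
#'   \code{0} recovers the ordinary pooled two-sample t exactly; \code{Inf}
#'   (or a huge value) pools all variances to \eqn{s_0^2}.
#' @return A data.frame with one row per feature: \code{feature_id},
#'   \code{layer}, \code{log2_fc}, \code{statistic}, \code{df}, \code{p_raw},
#'   \code{p_adj} (Benjamini-Hochberg).
#' @seealso [twoSampleT()], [applyDeFilters()]
#' @export
moderatedTTest <- function(m, meta, d0 = NULL) {
  stopifnot(is(m, "OmicsMatrix"))
  idx <- .groupIndices(m, meta)
  nA <- length(idx$a); nB <- length(idx$b)
  if (nA < 2L || nB < 2L) stop("both groups need at least 2 samples")
  v <- omicsValues(m)
  mA <- rowMeans(v[, idx$a, drop = FALSE])
  mB <- rowMeans(v[, idx$b, drop = FALSE])
  ssA <- rowSums((v[, idx$a, drop = FALSE] - mA)^2)
  ssB <- rowSums((v[, idx$b, drop = FALSE] - mB)^2)
  dg <- nA + nB - 2L
  s2 <- (ssA + ssB) / dg
  if (mean(s2 == 0) > 0.5)
    stop("more than half of the features have zero residual variance")
  if (is.null(d0)) {
    prior <- .fitVariancePrior(s2, dg)
    d0 <- prior$d0
    s02 <- prior$s02
  } else {
    if (length(d0) != 1L || d0 < 0) stop("d0 must be a single number >= 0")
    s02 <- if (d0 > 0) .fitVariancePrior(s2, dg)$s02 else 0
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2post * (1 / nA + 1 / nB))
  tstat <- (mA - mB) / se
  tstat[se == 0 & mA == mB] <- 0
  res <- .deTable(m, mA - mB, tstat, df = d0 + dg, layer = omicsLayer(m))
  attr(res, "prior") <- list(d0 = d0, s02 = s02, groups = idx$levels)
  res
}

#' Ordinary two-sample t-test per feature
#'
#' Pooled-variance Student t by default; Welch's unequal-variance form via
#' \code{welch = TRUE}. Two-sided p-values.
#'
#' @inheritParams moderatedTTest
#' @param welch use Welch's t instead of the pooled-variance Student t.
#' @return A data.frame as in [moderatedTTest()].
#' @export
twoSampleT <- function(m, meta, welch = FALSE) {
  stopifnot(is(m, "OmicsMatrix"))
  idx <- .groupIndices(m, meta)
  nA <- length(idx$a); nB <- length(idx$b)
  if (nA < 2L || nB < 2L) stop("both groups need at least 2 samples")
  v <- omicsValues(m)
  xA <- v[, idx$a, drop = FALSE]; xB <- v[, idx$b, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  vA <- rowSums((xA - mA)^2) / (nA - 1L)
  vB <- rowSums((xB - mB)^2) / (nB - 1L)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
    se <- sqrt(se2)
  } else {
    s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se <- sqrt(s2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2L, length(se))
  }
  tstat <- (mA - mB) / se
  tstat[se == 0 & mA == mB] <- 0
  df[!is.finite(df)] <- nA + nB - 2L
  res <- .deTable(m, mA - mB, tstat, df = df, layer = omicsLayer(m))
  attr(res, "groups") <- idx$levels
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment: with ascending p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} m / j)} clipped at 1,
#' returned in the original order. Delegates to
#' \code{stats::p.adjust(method = "BH")} after validating the input range.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Flag significant and fold-change-passing features
#'
#' Adds \code{significant} (\eqn{p_{adj} \le \alpha}; "at most 5\%" is
#' inclusive) and \code{passes_fc} (\eqn{|log2 fc| > fcLog2}, strict) flags.
#' The fold-change gate applies to the mRNA layer only in the cascade; no
#' fold-change cut-off is applied to lncRNAs or OTUs.
#'
#' @param r a differential result data.frame from [moderatedTTest()] or
#'   [twoSampleT()].
#' @param alpha FDR ceiling (inclusive).
#' @param fcLog2 log2 fold-change gate (strict >; 0.58 corresponds to a
#'   1.5-fold change).
#' @param useFc whether the fold-change gate participates in the combined
#'   \code{selected} flag.
#' @return \code{r} with logical columns \code{significant}, \code{passes_fc}
#'   and \code{selected} (\code{significant} AND, when \code{useFc},
#'   \code{passes_fc}).
#' @export
applyDeFilters <- function(r, alpha = 0.05, fcLog2 = 0.58, useFc = FALSE) {
  stopifnot(is.data.frame(r), all(c("p_adj", "log2_fc") %in% names(r)))
  r$significant <- r$p_adj <= alpha
  r$passes_fc <- abs(r$log2_fc) > fcLog2
  r$selected <- r$significant & (!useFc | r$passes_fc)
  r
}

#' Split a joint differential result into mRNA and lncRNA layers
#'
#' Partition by an explicit feature-to-layer map when given; features absent
#' from the map fall back to the identifier-prefix rule: \code{NM_} is
#' protein-coding (mRNA); \code{NR_}, \code{XR_} (RefSeq non-coding) and
#' \code{ENS*} (Ensembl) are lncRNA. Features resolvable by neither route are
#' an error.
#'
#' @param r a differential result data.frame covering both layers.
#' @param annotation optional named character vector mapping feature id to
#'   \code{"mrna"}/\code{"lncrna"}; overrides the prefix rule.
#' @return A list with elements \code{mrna} and \code{lncrna}: disjoint
#'   data.frames covering all input features, with \code{layer} rewritten.
#' @export
splitLayers <- function(r, annotation = NULL) {
  stopifnot(is.data.frame(r), "feature_id" %in% names(r))
  ids <- r$feature_id
  layer <- rep(NA_character_, length(ids))
  if (!is.null(annotation)) {
    hit <- ids %in% names(annotation)
    layer[hit] <- unname(annotation[ids[hit]])
    bad <- which(hit & !layer %in% c("mrna", "lncrna"))
    if (length(bad))
      stop("annotation maps features to layers other than mrna/lncrna: ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  todo <- is.na(layer)
  layer[todo & grepl("^NM_", ids)] <- "mrna"
  layer[todo & grepl("^(NR_|XR_|ENS)", ids)] <- "lncrna"
  if (anyNA(layer))
    stop("features with no layer annotation and no inferable prefix: ",
         paste(utils::head(ids[is.na(layer)], 5), collapse = ", "))
  out <- lapply(c(mrna = "mrna", lncrna = "lncrna"), function(l) {
    sub <- r[layer == l, , drop = FALSE]
    sub$layer <- rep(l, nrow(sub))
    rownames(sub) <- NULL
    sub
  })
  out
}
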