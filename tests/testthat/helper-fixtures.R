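## Shared builders for small in-code fixtures.

omx <- function(values, layer = "mrna", scale = "log2",
                features = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (!is.null(features)) rownames(values) <- features
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  OmicsMatrix(values, layer = layer, scale = scale)
}

twoGroupMeta <- function(nA, nB, labels = c("RUS", "FIN"), batches = NULL) {
  n <- nA + nB
  meta <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = factor(rep(labels, c(nA, nB)), levels = labels),
    stringsAsFactors = FALSE
  )
  if (!is.null(batches)) meta <- cbind(meta, batches)
  rownames(meta) <- meta$sample_id
  meta
}

## a small cohort shared across tests (generated once per test run)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateCohort(fixtureConfig())
    cache
  }
})

## independent brute-force BH: q_i = min over all observed thresholds
## p_(j) >= p_i of p_(j) * m / j, clipped at 1 (the smallest FDR level at
## which p_i would be rejected by the step-up rule)
bruteForceBH <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    j <- which(sp >= pi)
    min(1, sp[j] * m / j)
  }, numeric(1))
}

## exact hypergeometric upper tail by enumeration
enumHyperTail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
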