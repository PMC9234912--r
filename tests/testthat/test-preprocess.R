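test_that("log2 transform applies the pseudocount and guards its domain", {
  m <- omx(matrix(c(0, 3, 7, 7), 2, 2), scale = "raw")
  out <- log2Transform(m, pseudocount = 1)
  expect_identical(omicsScale(out), "log2")
  expect_equal(omicsValues(out)[1, 1], 0)
  expect_equal(omicsValues(out)[2, 1], 2)
  expect_equal(unname(omicsValues(out)[, 2]), c(3, 3))

  expect_error(log2Transform(omx(matrix(c(-1, 2, 3, 4), 2, 2), scale = "raw")),
               "negative")
  expect_error(log2Transform(m, pseudocount = 0), "pseudocount 0")
  expect_error(log2Transform(out), "raw")
})

test_that("background filter keeps features detected in at least the required fraction", {
  ## inclusive boundary: 72 of 144 retained ("at least half"), 71 dropped
  n <- 144
  v <- rbind(
    at72 = c(rep(1, 72), rep(-1, n - 72)),
    at71 = c(rep(1, 71), rep(-1, n - 71)),
    all_below = rep(-1, n)
  )
  m <- omx(v, scale = "log2")
  bg <- stats::setNames(rep(0, n), sampleIds(m))
  out <- filterAboveBackground(m, bg, minFraction = 0.5)
  expect_identical(featureIds(out), "at72")
  expect_identical(sampleIds(out), sampleIds(m))

  expect_warning(
    empty <- filterAboveBackground(omx(v["all_below", , drop = FALSE],
                                       scale = "log2"), bg),
    "no feature"
  )
  expect_identical(nrow(empty), 0L)
  expect_error(filterAboveBackground(m, bg, minFraction = 0), "minFraction")
  expect_error(filterAboveBackground(m, bg, minFraction = 1.2), "minFraction")
})

test_that("background thresholds summarize negative-control rows", {
  v <- rbind(NEG1 = c(1, 2), NEG2 = c(3, 4), NEG3 = c(2, 3),
             NM_1 = c(10, 10))
  m <- omx(v, scale = "log2")
  thr <- computeBackground(m, c("NEG1", "NEG2", "NEG3"))
  expect_equal(unname(thr[1]), 2 + 2 * sd(c(1, 3, 2)))
  thrMean <- computeBackground(m, c("NEG1", "NEG2", "NEG3"), method = "mean")
  expect_equal(unname(thrMean), c(2, 3))
  expect_error(computeBackground(m, c("NEG1", "NOPE")), "absent")
})

test_that("quantile normalization equalizes distributions, preserves ranks, is idempotent", {
  m <- omx(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)))
  out <- quantileNormalize(m)
  expect_equal(unname(omicsValues(out)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(omicsValues(out)[, 2]), c(2.5, 3.5, 4.5))

  set.seed(42)
  r <- omx(matrix(rnorm(200), 20, 10))
  q1 <- quantileNormalize(r)
  ## all columns share one sorted value vector
  sorted <- apply(omicsValues(q1), 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  ## ranks preserved per sample
  expect_identical(apply(omicsValues(q1), 2, rank),
                   apply(omicsValues(r), 2, rank))
  ## idempotent
  q2 <- quantileNormalize(q1)
  expect_lt(max(abs(omicsValues(q2) - omicsValues(q1))), 1e-12)

  ## already-identical columns are a fixed point
  same <- omx(cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3)))
  expect_equal(omicsValues(quantileNormalize(same)), omicsValues(same))

  expect_warning(one <- quantileNormalize(omx(matrix(1:3, 3, 1))), "single")
  expect_equal(omicsValues(one), omicsValues(omx(matrix(1:3, 3, 1))))
})

test_that("batch adjustment removes a pure shift and preserves the group effect", {
  set.seed(101)
  nFeat <- 500; nSamp <- 40
  meta <- twoGroupMeta(20, 20, batches = data.frame(
    batch = rep(rep(c("B1", "B2"), each = 10), 2)))
  delta <- 1  # planted group effect on every feature
  g <- as.numeric(meta$group == "RUS")
  base <- matrix(rnorm(nFeat * nSamp), nFeat, nSamp,
                 dimnames = list(sprintf("f%03d", 1:nFeat), meta$sample_id))
  shifted <- base + outer(rep(delta, nFeat), g) +
    outer(rep(2, nFeat), as.numeric(meta$batch == "B2"))
  m <- omx(shifted, scale = "log2")
  adj <- batchAdjust(m, meta, "batch")

  v <- omicsValues(adj)
  for (grp in levels(meta$group)) {
    inG <- meta$group == grp
    b1 <- rowMeans(v[, inG & meta$batch == "B1", drop = FALSE])
    b2 <- rowMeans(v[, inG & meta$batch == "B2", drop = FALSE])
    ## the systematic +2 shift is removed (per-feature means still carry
    ## sampling noise of order 1/sqrt(10), which is not a batch effect)
    expect_lt(abs(mean(b1 - b2)), 0.05)
    expect_lt(mean(abs(b1 - b2)), 0.5)
  }
  est <- rowMeans(v[, g == 1]) - rowMeans(v[, g == 0])
  expect_lt(abs(mean(est) - delta), 0.1)

  ## single batch level: identity
  meta1 <- meta; meta1$batch <- factor(rep("B1", nSamp))
  expect_lt(max(abs(omicsValues(batchAdjust(m, meta1, "batch")) - shifted)),
            1e-8)
})

test_that("batch adjustment refuses a batch confounded with group", {
  meta <- twoGroupMeta(4, 4, batches = data.frame(
    batch = rep(c("B1", "B2"), each = 4)))
  m <- omx(matrix(rnorm(80), 10, 8), samples = meta$sample_id)
  expect_error(batchAdjust(m, meta, "batch"), "confounded")
})

test_that("a no-batch-signal matrix is barely perturbed by adjustment", {
  ## batch levels large enough (80 samples each) that the empirical-Bayes
  ## batch-effect estimates, which are pure estimation noise here, stay small
  set.seed(77)
  meta <- twoGroupMeta(80, 80, batches = data.frame(
    batch = rep(rep(c("B1", "B2"), each = 40), 2)))
  m <- omx(matrix(rnorm(500 * 160), 500, 160), samples = meta$sample_id,
           scale = "log2")
  adj <- batchAdjust(m, meta, "batch")
  rms <- sqrt(mean((omicsValues(adj) - omicsValues(m))^2))
  expect_lt(rms, 0.05)
})

test_that("row Z-scoring standardizes and rejects constant features", {
  m <- omx(matrix(c(1, 2, 3), 1, 3))
  z <- zscoreRows(m)
  expect_identical(omicsScale(z), "zscore")
  expect_equal(unname(omicsValues(z)[1, ]), c(-1, 0, 1))

  const <- omx(rbind(ok = c(1, 2, 3), flat = c(2, 2, 2)))
  expect_error(zscoreRows(const), "flat")

  set.seed(5)
  r <- zscoreRows(omx(matrix(rnorm(60), 6, 10)))
  expect_lt(max(abs(rowMeans(omicsValues(r)))), 1e-12)
  expect_lt(max(abs(apply(omicsValues(r), 1, sd) - 1)), 1e-12)
})
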