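test_that("two-sample t matches the closed form and is antisymmetric", {
  m <- omx(matrix(c(1, 2, 3, 4, 5, 6), 1, 6), scale = "log2")
  meta <- twoGroupMeta(3, 3)
  res <- twoSampleT(m, meta)
  expect_equal(res$log2_fc, -3)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_raw, 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)
  expect_equal(res$p_raw, 0.0213, tolerance = 1e-2)

  ## swapping group labels negates t, p unchanged
  swapped <- twoGroupMeta(3, 3, labels = c("FIN", "RUS"))
  swapped$group <- factor(c(rep("FIN", 3), rep("RUS", 3)),
                          levels = c("RUS", "FIN"))
  ## same samples, opposite assignment
  meta2 <- meta
  meta2$group <- factor(rev(as.character(meta$group)),
                        levels = levels(meta$group))
  res2 <- twoSampleT(m, meta2)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p_raw, res$p_raw)
})

test_that("Welch variant agrees with stats::t.test per feature", {
  set.seed(11)
  meta <- twoGroupMeta(8, 12)
  v <- matrix(rnorm(20 * 20, sd = rep(c(1, 3), each = 10)), 20, 20)
  m <- omx(v, samples = meta$sample_id, scale = "log2")
  res <- twoSampleT(m, meta, welch = TRUE)
  for (i in c(1, 7, 20)) {
    tt <- t.test(v[i, 1:8], v[i, 9:20], var.equal = FALSE)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
  pooled <- twoSampleT(m, meta, welch = FALSE)
  tt <- t.test(v[3, 1:8], v[3, 9:20], var.equal = TRUE)
  expect_equal(pooled$statistic[3], unname(tt$statistic), tolerance = 1e-10)
})

test_that("moderated t with d0 = 0 is exactly the pooled t; flat features give p = 1", {
  set.seed(21)
  meta <- twoGroupMeta(6, 5)
  v <- matrix(rnorm(40 * 11), 40, 11)
  v[40, ] <- 1  # identical in both groups
  m <- omx(v, samples = meta$sample_id, scale = "log2")
  mod0 <- moderatedTTest(m, meta, d0 = 0)
  ord <- twoSampleT(m, meta)
  expect_equal(mod0$statistic[-40], ord$statistic[-40], tolerance = 1e-10)
  expect_equal(mod0$p_raw[-40], ord$p_raw[-40], tolerance = 1e-10)
  expect_equal(mod0$log2_fc[40], 0)
  expect_equal(mod0$p_raw[40], 1)
})

test_that("moderated t agrees with the limma empirical-Bayes fit", {
  set.seed(31)
  meta <- twoGroupMeta(10, 9)
  ## heteroscedastic features so variance moderation actually acts
  sds <- sqrt(1 / rgamma(300, shape = 4, rate = 4))
  v <- matrix(rnorm(300 * 19, sd = rep(sds, 19)), 300, 19)
  m <- omx(v, samples = meta$sample_id, scale = "log2")
  res <- moderatedTTest(m, meta)
  prior <- attr(res, "prior")

  design <- model.matrix(~ 0 + group, data = meta)
  colnames(design) <- levels(meta$group)
  fit <- limma::lmFit(v, design)
  fit <- limma::contrasts.fit(
    fit, limma::makeContrasts(RUS - FIN, levels = design))
  eb <- limma::eBayes(fit)
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s02, eb$s2.prior, tolerance = 1e-6)
  expect_equal(res$statistic, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p_raw, unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("huge prior df pools every posterior variance to s0^2", {
  set.seed(41)
  meta <- twoGroupMeta(5, 5)
  v <- matrix(rnorm(100 * 10, sd = rep(runif(100, 0.5, 3), 10)), 100, 10)
  m <- omx(v, samples = meta$sample_id, scale = "log2")
  res <- moderatedTTest(m, meta, d0 = 1e8)
  prior <- attr(res, "prior")
  ## reconstruct posterior variances from the reported statistics
  se <- res$log2_fc / res$statistic
  s2post <- se^2 / (1 / 5 + 1 / 5)
  expect_lt(max(abs(s2post / prior$s02 - 1), na.rm = TRUE), 1e-4)
})

test_that("null data give uniform p-values", {
  set.seed(51)
  meta <- twoGroupMeta(20, 20)
  m <- omx(matrix(rnorm(2000 * 40), 2000, 40), samples = meta$sample_id,
           scale = "log2")
  res <- moderatedTTest(m, meta)
  expect_gt(mean(res$p_raw < 0.05), 0.035)
  expect_lt(mean(res$p_raw < 0.05), 0.065)
  expect_lt(max(abs(res$statistic)), 6)
})

test_that("BH adjustment matches the hand step-up computation and guards its domain", {
  p <- c(0.005, 0.009, 0.04, 0.05, 0.2)
  expect_equal(bhAdjust(p), c(0.0225, 0.0225, 0.0625, 0.0625, 0.2))
  expect_equal(bhAdjust(rep(1, 4)), rep(1, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")

  ## monotone in p rank, and >= raw
  set.seed(61)
  for (i in 1:20) {
    pv <- runif(50)
    q <- bhAdjust(pv)
    expect_true(all(q >= pv - 1e-15))
    o <- order(pv)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("DE filters apply the inclusive FDR cut and the strict fold-change gate", {
  r <- data.frame(
    feature_id = c("a", "b", "c"),
    log2_fc = c(0.60, 0.58, 1.0),
    p_adj = c(0.04, 0.03, 0.05)
  )
  out <- applyDeFilters(r, alpha = 0.05, fcLog2 = 0.58, useFc = TRUE)
  expect_true(out$significant[3])            # p_adj = 0.05 exactly: kept
  expect_false(out$passes_fc[2])             # |fc| = 0.58 exactly: excluded
  expect_true(out$selected[1])               # 0.04 / 0.60: retained
  expect_false(out$selected[2])
  noFc <- applyDeFilters(r, useFc = FALSE)
  expect_true(all(noFc$selected == noFc$significant))
})

test_that("layer splitting follows the prefix rule with explicit-map precedence", {
  r <- data.frame(
    feature_id = c("NM_0001", "NR_0002", "XR_0003", "ENST0004"),
    layer = "mrna", log2_fc = 1:4, p_adj = rep(0.01, 4)
  )
  out <- splitLayers(r)
  expect_identical(out$mrna$feature_id, "NM_0001")
  expect_identical(out$lncrna$feature_id, c("NR_0002", "XR_0003", "ENST0004"))
  expect_true(all(out$lncrna$layer == "lncrna"))

  ## explicit map wins over the prefix
  out2 <- splitLayers(r, annotation = c(NR_0002 = "mrna"))
  expect_true("NR_0002" %in% out2$mrna$feature_id)

  bad <- data.frame(feature_id = "PROBE_1", log2_fc = 1, p_adj = 0.5)
  expect_error(splitLayers(bad), "PROBE_1")

  empty <- r[0, ]
  out3 <- splitLayers(empty)
  expect_identical(nrow(out3$mrna), 0L)
  expect_identical(nrow(out3$lncrna), 0L)
})
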