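test_that("cross-layer Pearson correlation matches hand values and cor.test", {
  a <- omx(rbind(l1 = c(1, 2, 3, 4)), layer = "lncrna")
  b <- omx(rbind(m1 = c(2, 4, 6, 8), m2 = c(8, 6, 4, 2), m3 = c(1, 3, 2, 4)),
           layer = "mrna")
  cm <- crossLayerCorrelation(a, b)
  expect_equal(unname(corValues(cm)[1, ]), c(1, -1, 0.8))
  expect_equal(corPvalues(cm)[1, "m1"], 0)
  expect_equal(corPvalues(cm)[1, "m2"], 0)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(corPvalues(cm)[1, "m3"], ct$p.value, tolerance = 1e-12)

  expect_error(crossLayerCorrelation(a, omx(matrix(1:3, 1, 3), layer = "mrna")),
               "sample ids")
  flat <- omx(rbind(l1 = rep(2, 4)), layer = "lncrna")
  expect_error(crossLayerCorrelation(flat, b), "zero-variance")
})

test_that("matrix correlation equals the per-pair loop computation", {
  set.seed(81)
  a <- omx(matrix(rnorm(8 * 12), 8, 12), layer = "lncrna", scale = "zscore")
  b <- omx(matrix(rnorm(6 * 12), 6, 12), layer = "mrna", scale = "zscore")
  cm <- crossLayerCorrelation(a, b)
  for (i in seq_len(8)) {
    for (j in seq_len(6)) {
      expect_equal(corValues(cm)[i, j],
                   cor(omicsValues(a)[i, ], omicsValues(b)[j, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("network thresholding is strict and matches an exhaustive scan", {
  ids <- function(p, n) list(sprintf("NR_%02d", 1:p), sprintf("NM_%02d", 1:n))
  mk <- function(r, p) new("CorrelationMatrix", r = r, p = p, n = 30L,
                           layerA = "lncrna", layerB = "mrna")
  ## single supra-threshold cell
  r <- matrix(0.1, 3, 3, dimnames = ids(3, 3)); r[2, 3] <- 0.96
  p <- matrix(1e-6, 3, 3, dimnames = ids(3, 3))
  net <- buildNetwork(mk(r, p), rMin = 0.95)
  expect_identical(nrow(networkEdges(net)), 1L)
  expect_identical(sideANodes(net), "NR_02")
  expect_identical(sideBNodes(net), "NM_03")

  ## boundary: r = 0.95 exactly is excluded (strict >)
  r[2, 3] <- 0.95
  expect_identical(nrow(networkEdges(buildNetwork(mk(r, p), rMin = 0.95))), 0L)

  ## signed mode ignores strong negatives; absolute keeps them
  r[1, 1] <- -0.99
  expect_identical(sideANodes(buildNetwork(mk(r, p), 0.95, mode = "signed")),
                   character())
  expect_identical(sideANodes(buildNetwork(mk(r, p), 0.95, mode = "absolute")),
                   "NR_01")

  ## exhaustive scan oracle on random instances
  set.seed(91)
  for (dims in list(c(20, 30), c(50, 50))) {
    r <- matrix(runif(prod(dims), -1, 1), dims[1],
                dimnames = ids(dims[1], dims[2]))
    p <- matrix(runif(prod(dims)), dims[1], dims[2],
                dimnames = ids(dims[1], dims[2]))
    net <- buildNetwork(mk(r, p), rMin = 0.6, pMax = 0.3)
    want <- character()
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      if (abs(r[i, j]) > 0.6 && p[i, j] < 0.3)
        want <- c(want, paste(rownames(r)[i], colnames(r)[j]))
    e <- networkEdges(net)
    expect_setequal(paste(e$source_id, e$target_id), want)
  }
  expect_error(buildNetwork(mk(r, p), rMin = 1.2), "rMin")
})

test_that("network restriction drops side-B nodes and newly isolated side-A nodes", {
  ids <- list(c("NR_1", "NR_2", "NR_3"), c("NM_1", "NM_2"))
  r <- matrix(c(0.99, 0.1, 0.1, 0.1, 0.98, 0.97), 3, 2, dimnames = ids)
  p <- matrix(1e-9, 3, 2, dimnames = ids)
  cm <- new("CorrelationMatrix", r = r, p = p, n = 20L,
            layerA = "lncrna", layerB = "mrna")
  net <- buildNetwork(cm, 0.95)
  expect_setequal(sideANodes(net), c("NR_1", "NR_2", "NR_3"))

  ## identity when keeping everything
  same <- restrictNetwork(net, sideBNodes(net))
  expect_identical(networkEdges(same), networkEdges(net))

  ## dropping NM_2 isolates NR_2 and NR_3
  only1 <- restrictNetwork(net, "NM_1")
  expect_identical(sideANodes(only1), "NR_1")

  ## empty restriction, and unknown ids warned
  expect_identical(nrow(networkEdges(restrictNetwork(net, character()))), 0L)
  expect_warning(restrictNetwork(net, c("NM_1", "NOPE")), "ignored")
})

test_that("median importance uses all opposite-side nodes with lexicographic ties", {
  ids <- list(c("NR_1", "NR_2"), c("NM_1", "NM_2", "NM_3"))
  r <- rbind(c(0.9, 0.7, 0.8), c(-0.96, 0.96, 0.2))
  dimnames(r) <- ids
  p <- matrix(1e-9, 2, 3, dimnames = ids)
  cm <- new("CorrelationMatrix", r = r, p = p, n = 20L,
            layerA = "lncrna", layerB = "mrna")
  net <- buildNetwork(cm, 0.5, pMax = NA)
  imp <- medianImportance(cm, net, axis = "a")
  expect_equal(imp$median_abs_r[imp$node_id == "NR_1"], 0.8)
  ## NR_2: |r| = (0.96, 0.96, 0.2) -> median 0.96, ranked first
  expect_identical(imp$node_id[1], "NR_2")

  ## ties broken lexicographically
  r2 <- rbind(c(0.9, 0.9, 0.9), c(0.9, 0.9, 0.9))
  dimnames(r2) <- ids
  cm2 <- new("CorrelationMatrix", r = r2, p = p, n = 20L,
             layerA = "lncrna", layerB = "mrna")
  net2 <- buildNetwork(cm2, 0.5, pMax = NA)
  imp2 <- medianImportance(cm2, net2, axis = "a")
  expect_identical(imp2$node_id, c("NR_1", "NR_2"))

  ## single opposite node: each importance is just that node's |r| to it
  one <- restrictNetwork(net, "NM_1")
  impOne <- medianImportance(cm, one, axis = "a")
  expect_identical(impOne$node_id, c("NR_2", "NR_1"))
  expect_equal(impOne$median_abs_r, c(0.96, 0.9))
  ## perfectly correlated node: importance 1
  rp <- rbind(c(1, 1, 1), c(0.2, 0.2, 0.2)); dimnames(rp) <- ids
  cmp <- new("CorrelationMatrix", r = rp, p = p, n = 20L,
             layerA = "lncrna", layerB = "mrna")
  netp <- buildNetwork(cmp, 0.5, pMax = NA)
  expect_equal(medianImportance(cmp, netp, axis = "a")$median_abs_r, 1)

  ## direction reported from a supplied effect vector
  impDir <- medianImportance(cm, net, axis = "b",
                             direction = c(NM_1 = -2, NM_2 = 1.5, NM_3 = 0.2))
  expect_identical(impDir$direction[impDir$node_id == "NM_1"], -1)
})

test_that("OTU co-abundance recovers planted couplings and rejects weak ones", {
  b <- smallCohort()
  tr <- b$truth
  ## build the z-scored layers directly from the generated log2 structure
  lnc <- zscoreRows(log2Transform(b$lncrna, 0))
  zHub <- OmicsMatrix(omicsValues(lnc)[tr$hub_lncrna, , drop = FALSE],
                      layer = "lncrna", scale = "zscore")
  otuLog <- log2Transform(b$otu, 1)
  zOtu <- zscoreRows(OmicsMatrix(
    omicsValues(otuLog)[tr$de_features$otu$feature_id, , drop = FALSE],
    layer = "otu", scale = "log2"))
  coab <- otuCoabundance(zHub, zOtu)
  expect_setequal(sideBNodes(coab$network), tr$coupled_otu)
  ## per-OTU edge signs match the planted coupling signs
  e <- networkEdges(coab$network)
  want <- setNames(tr$otu_couplings$sign,
                   paste(tr$otu_couplings$lncrna_id, tr$otu_couplings$otu_id))
  got <- setNames(sign(e$pearson_r), paste(e$source_id, e$target_id))
  shared <- intersect(names(got), names(want))
  expect_gt(length(shared), 0)
  expect_true(all(got[shared] == want[shared]))
  expect_true(all(coab$sign_consistency$consistency %in%
                    c("positive", "negative", "mixed")))

  ## couplings planted at r = 0.3 stay below the 0.5 threshold
  weak <- generateCohort(syntheticConfig(
    nMrna = 60, nLncrna = 40, nOtu = 30, nDeMrna = 20, nDeLncrna = 20,
    nDeOtu = 6, nPoolMrna = 10, nHubLncrna = 8, nHubMrna = 5,
    nAuxLncrna = 0, nAuxMrna = 0, nCoupledOtu = 4, otuCouplingR = 0.3,
    nDiseaseDecoys = 10, batchShiftSd = 0, seed = 5))
  wLnc <- zscoreRows(log2Transform(weak$lncrna, 0))
  wHub <- OmicsMatrix(omicsValues(wLnc)[weak$truth$hub_lncrna, , drop = FALSE],
                      layer = "lncrna", scale = "zscore")
  wOtu <- zscoreRows(OmicsMatrix(
    omicsValues(log2Transform(weak$otu, 1))[weak$truth$coupled_otu, ,
                                            drop = FALSE],
    layer = "otu", scale = "log2"))
  coabW <- otuCoabundance(wHub, wOtu)
  ## essentially empty at |r| > 0.5 (at most a lone sampling-noise edge,
  ## against 32 planted pairs that all pass when the coupling is 0.7)
  expect_lte(nrow(networkEdges(coabW$network)), 1L)
})
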