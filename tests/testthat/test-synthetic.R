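test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(hubTargetR = 1), "hubTargetR")
  expect_error(syntheticConfig(otuCouplingR = 1), "otuCouplingR")
  expect_error(syntheticConfig(hubTargetR = 0.5, otuCouplingR = 0.9),
               "infeasible")
  expect_error(syntheticConfig(nHubMrna = 60, nPoolMrna = 50), "pool")
  expect_error(syntheticConfig(nDeMrna = 5000), "DE counts")
  expect_error(syntheticConfig(nGroupA = 0), "positive")
  expect_s3_class(syntheticConfig(), "SyntheticConfig")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- fixtureConfig()
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(omicsValues(a$mrna), omicsValues(b$mrna))
  expect_identical(omicsValues(a$lncrna), omicsValues(b$lncrna))
  expect_identical(omicsValues(a$otu), omicsValues(b$otu))
  expect_identical(a$truth, b$truth)
  expect_identical(a$disease_genes, b$disease_genes)
  ## different seed differs
  c2 <- generateCohort(syntheticConfig(
    nGroupA = 21, nGroupB = 19, nMrna = 120, nLncrna = 100, nOtu = 40,
    nDeMrna = 30, nDeLncrna = 25, nDeOtu = 8, nPoolMrna = 20,
    nHubLncrna = 12, nHubMrna = 6, nAuxLncrna = 3, nAuxMrna = 4,
    nCoupledOtu = 3, nMicrobeSets = 4, nDecoySets = 4,
    nDiseaseDecoys = 30, nNegctl = 20, seed = 2))
  expect_false(identical(omicsValues(a$mrna), omicsValues(c2$mrna)))
})

test_that("planted hub correlations hit the analytic target at n = 144", {
  ## batch shifts off to expose the raw block structure the closed-form
  ## noise setting guarantees (the pipeline removes them via batch
  ## adjustment before correlating)
  b <- generateCohort(syntheticConfig(batchShiftSd = 0, seed = 17))
  tr <- b$truth
  lnc <- log2Transform(b$lncrna, 0)
  mrna <- log2Transform(b$mrna, 0)
  r <- cor(t(omicsValues(lnc)[tr$hub_lncrna, ]),
           t(omicsValues(mrna)[tr$hub_mrna, ]))
  ## Fisher-z band around 0.98 at n = 144: |r| within [0.95, 0.995] for
  ## at least 95% of the planted pairs
  inBand <- abs(r) >= 0.95 & abs(r) <= 0.995
  expect_gt(mean(inBand), 0.95)
  ## signs follow the planted sign products
  want <- matrix(tr$hub_edges$target_r,
                 nrow = length(tr$hub_lncrna), byrow = TRUE,
                 dimnames = list(tr$hub_lncrna, tr$hub_mrna))
  expect_true(all(sign(r) == sign(want)))
})

test_that("planted DE effects are recovered within sampling error", {
  cfg <- syntheticConfig(batchShiftSd = 0, seed = 19)
  b <- generateCohort(cfg)
  g <- b$metadata$group == "RUS"
  se <- cfg$noiseSd * sqrt(1 / sum(g) + 1 / sum(!g))
  for (layer in c("mrna", "lncrna")) {
    truthDe <- b$truth$de_features[[layer]]
    v <- log2(omicsValues(b[[layer]]))[truthDe$feature_id, , drop = FALSE]
    est <- rowMeans(v[, g, drop = FALSE]) - rowMeans(v[, !g, drop = FALSE])
    ## at least 99% of planted effects within 3 SE (hub features carry a
    ## slightly different residual scale, so allow the band to be crossed
    ## by isolated features only)
    expect_gt(mean(abs(est - truthDe$log2_effect) <= 3 * se), 0.97)
  }
})

test_that("the OTU table is integer counts whose log transform is finite", {
  b <- smallCohort()
  v <- omicsValues(b$otu)
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  expect_true(all(is.finite(log2(v + 1))))
})

test_that("a null configuration yields no detectable group structure", {
  nullCfg <- syntheticConfig(
    nMrna = 500, nLncrna = 50, nOtu = 20,
    nDeMrna = 0, nDeLncrna = 0, nDeOtu = 0, nPoolMrna = 0,
    nHubLncrna = 0, nHubMrna = 0, nAuxLncrna = 0, nAuxMrna = 0,
    nCoupledOtu = 0, nDiseaseDecoys = 20, batchShiftSd = 0,
    unexpressedFraction = 0, seed = 23)
  b <- generateCohort(nullCfg)
  lg <- log2Transform(b$mrna, 0)
  lg <- lg[setdiff(featureIds(lg), b$truth$negctl_ids), ]
  de <- applyDeFilters(moderatedTTest(lg, b$metadata))
  expect_lte(mean(de$significant), 0.01)
})

test_that("ground-truth manifest is internally consistent", {
  b <- smallCohort()
  tr <- b$truth
  expect_true(all(tr$hub_mrna %in% tr$pool_mrna))
  expect_true(all(tr$pool_mrna %in% tr$de_features$mrna$feature_id))
  expect_true(all(tr$hub_lncrna %in% tr$de_features$lncrna$feature_id))
  expect_true(all(tr$coupled_otu %in% tr$de_features$otu$feature_id))
  ## disease list overlaps the pool in exactly the hub genes
  expect_setequal(intersect(tr$disease_gene_list, tr$pool_mrna), tr$hub_mrna)
  ## decoy sets share no members with microbe-response sets
  microbe <- unique(unlist(geneSets(b$gene_sets)[tr$microbe_sets]))
  decoy <- unique(unlist(geneSets(b$gene_sets)[tr$decoy_sets]))
  expect_length(intersect(microbe, decoy), 0L)
  ## microbe sets jointly cover the pool
  expect_setequal(intersect(microbe, tr$pool_mrna), tr$pool_mrna)
  ## every referenced id exists in the matrices
  expect_true(all(tr$hub_lncrna %in% featureIds(b$lncrna)))
  expect_true(all(tr$disease_gene_list %in% featureIds(b$mrna)))
})

test_that("fixtures write seven artifacts, are seed-stable and reload faithfully", {
  dir <- withr::local_tempdir()
  b <- smallCohort()
  paths <- writeFixture(b, file.path(dir, "fx"))
  expect_length(paths, 7L)
  expect_true(all(file.exists(paths)))
  expect_error(writeFixture(b, file.path(dir, "fx")), "force")

  ## same seed, same bytes
  paths2 <- writeFixture(generateCohort(fixtureConfig()),
                         file.path(dir, "fx2"))
  expect_identical(unname(tools::md5sum(paths)), unname(tools::md5sum(paths2)))

  ## reload equals the in-memory bundle (full precision here)
  back <- readFixture(file.path(dir, "fx"))
  expect_lt(max(abs(omicsValues(back$mrna) - omicsValues(b$mrna))), 1e-9)
  expect_identical(omicsValues(back$otu), omicsValues(b$otu))
  expect_identical(back$disease_genes, b$disease_genes)
  expect_identical(geneSets(back$gene_sets), geneSets(b$gene_sets))

  ## the packaged fixture is the canonical configuration, rounded to 4
  ## decimals
  pk <- readFixture(fixturePath())
  expect_lt(max(abs(omicsValues(pk$mrna) - omicsValues(b$mrna))), 1e-4)
  expect_identical(omicsValues(pk$otu), omicsValues(b$otu))
})
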