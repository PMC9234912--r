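## Seeded generator for a two-group, batched, three-layer cohort with
## planted effects matching the statistical structure the cascade filters
## on, plus a ground-truth manifest for recovery testing.
##
## Generative model (single latent hub factor): per sample s, a group
## indicator g(s) and a hub factor h(s) = mu * g(s) + N(0,1), standardized to
## unit variance. Background features are i.i.d. Normal(baseline, noise_sd^2);
## planted DE features add a group effect delta drawn from the configured
## log2 range with random sign; hub features (both expression layers) are
## x_f(s) = baseline + a_f * h(s) + N(0, sigma^2) with sigma^2 = 1/r - 1 so
## that within-block Pearson r equals the target; coupled OTUs are
## log2-abundances b * sign * h(s) + noise with the noise set to hit the
## OTU-coupling target, then exponentiated and rounded to counts. A second,
## independent latent factor drives a small auxiliary block so that the
## pre-restriction co-expression network is strictly larger than the
## disease-refined hub.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions the cascade is designed around: 75 vs 69
#' samples, DE log2 effects in [0.58, 1.6] (a 1.5- to 3-fold change), a
#' 46-lncRNA x 20-mRNA hub at within-block Pearson r = 0.98, an auxiliary
#' 8 x 10 block on an independent factor, 5 OTUs coupled to the hub at
#' |r| = 0.7, and a 73-gene microbe-response pool from which the 20 hub genes
#' overlap the disease list.
#'
#' @param nGroupA,nGroupB sample counts for the two groups (labels
#'   \code{groupLabels[1]} = group A).
#' @param groupLabels two group labels; the first is group A in all signs.
#' @param nMrna,nLncrna,nOtu feature counts per layer.
#' @param nDeMrna,nDeLncrna,nDeOtu planted differential features per layer.
#' @param deLog2EffectRange interval the |log2 effect| of plain DE features
#'   is drawn from.
#' @param nPoolMrna planted microbe-response pool size (all DE mRNAs, all
#'   members of the planted microbe gene sets).
#' @param nHubLncrna,nHubMrna planted hub block sizes (hub mRNAs are the
#'   first \code{nHubMrna} pool genes and exactly the disease-list overlap).
#' @param nAuxLncrna,nAuxMrna auxiliary co-expression block driven by an
#'   independent latent factor (aux mRNAs are pool genes outside the hub).
#' @param hubTargetR target within-block Pearson r of hub and aux blocks.
#' @param nCoupledOtu number of OTUs coupled to the hub factor.
#' @param otuCouplingR target |r| between coupled OTUs and hub features
#'   (feasible only when \code{otuCouplingR <= sqrt(hubTargetR)}).
#' @param hubGroupMu group separation of the latent hub factor (before
#'   standardization).
#' @param noiseSd expression noise SD (log2 units).
#' @param otuNoiseSd OTU log2-abundance noise SD (microbial abundances are
#'   more dispersed than array intensities).
#' @param batchShiftSd SD of the per-batch, per-feature location shifts
#'   added to the expression layers.
#' @param nMicrobeSets,nDecoySets planted gene-set counts; decoy sets share
#'   no members with the microbe-response sets.
#' @param nDiseaseDecoys decoy entries in the disease gene list (drawn
#'   outside the pool so the pool overlap is exactly the hub).
#' @param nNegctl negative-control probes (baseline below background) that
#'   ride along in the mRNA matrix.
#' @param unexpressedFraction fraction of each expression layer planted
#'   below background, to exercise the detection filter.
#' @param seed integer seed; a fixed seed makes the whole bundle
#'   bit-identical across runs.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGroupA = 75L, nGroupB = 69L,
                            groupLabels = c("RUS", "FIN"),
                            nMrna = 2000L, nLncrna = 1500L, nOtu = 200L,
                            nDeMrna = 200L, nDeLncrna = 150L, nDeOtu = 20L,
                            deLog2EffectRange = c(0.58, 1.6),
                            nPoolMrna = 73L,
                            nHubLncrna = 46L, nHubMrna = 20L,
                            nAuxLncrna = 8L, nAuxMrna = 10L,
                            hubTargetR = 0.98,
                            nCoupledOtu = 5L, otuCouplingR = 0.7,
                            hubGroupMu = 2,
                            noiseSd = 1, otuNoiseSd = 2, batchShiftSd = 0.5,
                            nMicrobeSets = 7L, nDecoySets = 8L,
                            nDiseaseDecoys = 481L,
                            nNegctl = 50L, unexpressedFraction = 0.05,
                            seed = 1L) {
  cfg <- list(
    nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
    groupLabels = as.character(groupLabels),
    nMrna = as.integer(nMrna), nLncrna = as.integer(nLncrna),
    nOtu = as.integer(nOtu),
    nDeMrna = as.integer(nDeMrna), nDeLncrna = as.integer(nDeLncrna),
    nDeOtu = as.integer(nDeOtu),
    deLog2EffectRange = as.numeric(deLog2EffectRange),
    nPoolMrna = as.integer(nPoolMrna),
    nHubLncrna = as.integer(nHubLncrna), nHubMrna = as.integer(nHubMrna),
    nAuxLncrna = as.integer(nAuxLncrna), nAuxMrna = as.integer(nAuxMrna),
    hubTargetR = as.numeric(hubTargetR),
    nCoupledOtu = as.integer(nCoupledOtu),
    otuCouplingR = as.numeric(otuCouplingR),
    hubGroupMu = as.numeric(hubGroupMu),
    noiseSd = as.numeric(noiseSd), otuNoiseSd = as.numeric(otuNoiseSd),
    batchShiftSd = as.numeric(batchShiftSd),
    nMicrobeSets = as.integer(nMicrobeSets),
    nDecoySets = as.integer(nDecoySets),
    nDiseaseDecoys = as.integer(nDiseaseDecoys),
    nNegctl = as.integer(nNegctl),
    unexpressedFraction = as.numeric(unexpressedFraction),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (any(c(nGroupA, nGroupB, nMrna, nLncrna, nOtu) <= 0L))
      stop("sample and feature counts must be positive")
    if (length(groupLabels) != 2L || anyDuplicated(groupLabels))
      stop("two distinct group labels are required")
    if (length(deLog2EffectRange) != 2L ||
        any(deLog2EffectRange <= 0) || diff(deLog2EffectRange) < 0)
      stop("deLog2EffectRange must be a positive, non-decreasing interval")
    if (hubTargetR <= 0 || hubTargetR >= 1)
      stop("hubTargetR must lie strictly between 0 and 1")
    if (otuCouplingR <= 0 || otuCouplingR >= 1)
      stop("otuCouplingR must lie strictly between 0 and 1")
    if (otuCouplingR > sqrt(hubTargetR))
      stop("infeasible targets: otuCouplingR must be <= sqrt(hubTargetR)")
    if (nHubMrna + nAuxMrna > nPoolMrna)
      stop("hub plus auxiliary mRNAs must fit inside the pool")
    if (nPoolMrna > nDeMrna || nHubLncrna + nAuxLncrna > nDeLncrna ||
        nCoupledOtu > nDeOtu)
      stop("planted block sizes must fit inside the DE counts per layer")
    if (nDeMrna > nMrna || nDeLncrna > nLncrna || nDeOtu > nOtu)
      stop("DE counts must fit inside the feature counts")
    if (unexpressedFraction < 0 || unexpressedFraction >= 1)
      stop("unexpressedFraction must be in [0, 1)")
  })
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    paste0("SyntheticConfig: %d + %d samples (%s/%s); ",
           "%d mRNA / %d lncRNA / %d OTU; hub %d x %d @ r=%.2f; ",
           "%d OTUs coupled @ |r|=%.2f; seed %d\n"),
    x$nGroupA, x$nGroupB, x$groupLabels[1], x$groupLabels[2],
    x$nMrna, x$nLncrna, x$nOtu, x$nHubLncrna, x$nHubMrna, x$hubTargetR,
    x$nCoupledOtu, x$otuCouplingR, x$seed
  ))
  invisible(x)
}

## round-robin assignment of batch levels inside each group, so batches are
## balanced across groups and never confounded
.assignBatches <- function(group, levels) {
  out <- character(length(group))
  for (g in unique(group))
    out[group == g] <- rep_len(levels, sum(group == g))
  factor(out, levels = levels)
}

#' Configuration of the packaged example fixture
#'
#' The exact configuration that generated the fixture shipped under
#' \code{inst/extdata/fixture/}: a scaled-down cohort (21 + 19 samples,
#' 120 mRNA / 100 lncRNA / 40 OTU features, 12 x 6 hub, 3 coupled OTUs)
#' small enough to run the whole cascade in examples and tests in seconds.
#' Regenerating with this configuration reproduces the shipped files
#' (matrix values are written at 4 decimals).
#'
#' @return A \code{SyntheticConfig}.
#' @seealso [fixturePath()]
#' @export
fixtureConfig <- function() {
  syntheticConfig(
    nGroupA = 21L, nGroupB = 19L,
    nMrna = 120L, nLncrna = 100L, nOtu = 40L,
    nDeMrna = 30L, nDeLncrna = 25L, nDeOtu = 8L,
    nPoolMrna = 20L, nHubLncrna = 12L, nHubMrna = 6L,
    nAuxLncrna = 3L, nAuxMrna = 4L,
    nCoupledOtu = 3L,
    nMicrobeSets = 4L, nDecoySets = 4L,
    nDiseaseDecoys = 30L, nNegctl = 20L,
    seed = 1L
  )
}

#' Path to the packaged example fixture
#'
#' @return Directory of the seven shipped fixture files.
#' @export
fixturePath <- function() {
  system.file("extdata", "fixture", package = "OmicsCascade", mustWork = TRUE)
}

#' Generate the synthetic three-layer cohort
#'
#' Draws the full bundle under the model described in
#' [syntheticConfig()]: two expression layers (returned as raw intensities,
#' \eqn{2^{\log_2 x}}), an OTU count table, sample metadata with two batch
#' factors, planted microbe-response and decoy gene sets, a disease gene
#' list, and a ground-truth manifest of everything planted. A fixed seed
#' gives a bit-identical bundle.
#'
#' @param config a \code{SyntheticConfig}.
#' @return A list of class \code{SyntheticCohort}: \code{mrna},
#'   \code{lncrna}, \code{otu} (\linkS4class{OmicsMatrix}, raw scale),
#'   \code{metadata} (data.frame), \code{gene_sets}
#'   (\linkS4class{GeneSetCollection} with the surviving-feature universe
#'   left to the pipeline), \code{disease_genes} (character), \code{truth}
#'   (ground-truth manifest list).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$nGroupA + cfg$nGroupB
  sampleIds <- sprintf("S%03d", seq_len(n))
  group <- factor(rep(cfg$groupLabels, c(cfg$nGroupA, cfg$nGroupB)),
                  levels = cfg$groupLabels)
  g <- as.numeric(group == cfg$groupLabels[1L])
  meta <- data.frame(
    sample_id = sampleIds,
    group = group,
    labeling_batch = .assignBatches(group, c("L1", "L2")),
    array_batch = .assignBatches(group, c("A1", "A2", "A3")),
    row.names = sampleIds,
    stringsAsFactors = FALSE
  )

  ## latent factors, standardized to unit variance
  h <- as.numeric(scale(cfg$hubGroupMu * g + stats::rnorm(n)))
  h2 <- as.numeric(scale(cfg$hubGroupMu * g + stats::rnorm(n)))
  hDiff <- mean(h[g == 1]) - mean(h[g == 0])
  h2Diff <- mean(h2[g == 1]) - mean(h2[g == 0])
  hubSigma <- sqrt(1 / cfg$hubTargetR - 1)

  drawEffects <- function(k) {
    stats::runif(k, cfg$deLog2EffectRange[1L], cfg$deLog2EffectRange[2L]) *
      sample(c(-1, 1), k, replace = TRUE)
  }

  ## ---- expression layer builder (log2 scale) --------------------------
  ## layout per layer: [hub | aux | plain DE | background | unexpressed]
  buildExprLayer <- function(ids, nDe, nHub, nAux, hubSigns, auxSigns) {
    p <- length(ids)
    nUnexpr <- floor(cfg$unexpressedFraction * p)
    if (p - nUnexpr < nDe) stop("not enough expressed features for DE block")
    baseline <- stats::runif(p, 6, 12)
    if (nUnexpr > 0)
      baseline[(p - nUnexpr + 1L):p] <- 4  # below background (threshold ~5)
    x <- matrix(stats::rnorm(p * n, sd = cfg$noiseSd), p, n,
                dimnames = list(ids, sampleIds)) + baseline
    effects <- numeric(p)
    if (nHub > 0) {
      idx <- seq_len(nHub)
      x[idx, ] <- baseline[idx] + outer(hubSigns, h) +
        matrix(stats::rnorm(nHub * n, sd = hubSigma), nHub, n)
      effects[idx] <- hubSigns * hDiff
    }
    if (nAux > 0) {
      idx <- nHub + seq_len(nAux)
      x[idx, ] <- baseline[idx] + outer(auxSigns, h2) +
        matrix(stats::rnorm(nAux * n, sd = hubSigma), nAux, n)
      effects[idx] <- auxSigns * h2Diff
    }
    nPlain <- nDe - nHub - nAux
    if (nPlain > 0) {
      idx <- nHub + nAux + seq_len(nPlain)
      delta <- drawEffects(nPlain)
      x[idx, ] <- x[idx, ] + outer(delta, g)
      effects[idx] <- delta
    }
    list(log2 = x, effects = effects, deIds = ids[seq_len(nDe)],
         unexprIds = if (nUnexpr > 0) ids[(p - nUnexpr + 1L):p] else character())
  }

  mrnaIds <- sprintf("NM_%06d", seq_len(cfg$nMrna))
  lncPrefix <- rep(c("NR_", "XR_", "ENST"), length.out = cfg$nLncrna)
  lncrnaIds <- paste0(lncPrefix, sprintf("%06d", seq_len(cfg$nLncrna)))

  ## hub signs mirror the observed asymmetry: most hub lncRNAs up in group A,
  ## most hub mRNAs down
  hubLncSigns <- sample(c(1, -1), cfg$nHubLncrna, replace = TRUE,
                        prob = c(0.87, 0.13))
  hubMrnaSigns <- sample(c(1, -1), cfg$nHubMrna, replace = TRUE,
                         prob = c(0.15, 0.85))
  auxLncSigns <- sample(c(1, -1), cfg$nAuxLncrna, replace = TRUE)
  auxMrnaSigns <- sample(c(1, -1), cfg$nAuxMrna, replace = TRUE)

  mrnaLayer <- buildExprLayer(mrnaIds, cfg$nDeMrna, cfg$nHubMrna,
                              cfg$nAuxMrna, hubMrnaSigns, auxMrnaSigns)
  lncLayer <- buildExprLayer(lncrnaIds, cfg$nDeLncrna, cfg$nHubLncrna,
                             cfg$nAuxLncrna, hubLncSigns, auxLncSigns)

  hubMrna <- mrnaIds[seq_len(cfg$nHubMrna)]
  auxMrna <- mrnaIds[cfg$nHubMrna + seq_len(cfg$nAuxMrna)]
  poolMrna <- mrnaIds[seq_len(cfg$nPoolMrna)]
  hubLnc <- lncrnaIds[seq_len(cfg$nHubLncrna)]
  auxLnc <- lncrnaIds[cfg$nHubLncrna + seq_len(cfg$nAuxLncrna)]

  ## negative-control probes ride along in the mRNA matrix (baseline below
  ## background, as on a real array)
  negctlIds <- sprintf("NEGCTL_%03d", seq_len(cfg$nNegctl))
  negctl <- matrix(stats::rnorm(cfg$nNegctl * n, mean = 3, sd = cfg$noiseSd),
                   cfg$nNegctl, n, dimnames = list(negctlIds, sampleIds))
  mrnaLog2 <- rbind(mrnaLayer$log2, negctl)
  lncLog2 <- lncLayer$log2

  ## per-batch, per-feature location shifts on the expression layers
  for (bf in c("labeling_batch", "array_batch")) {
    for (lv in levels(meta[[bf]])) {
      inBatch <- meta[[bf]] == lv
      mrnaLog2[, inBatch] <- mrnaLog2[, inBatch] +
        stats::rnorm(nrow(mrnaLog2), sd = cfg$batchShiftSd)
      lncLog2[, inBatch] <- lncLog2[, inBatch] +
        stats::rnorm(nrow(lncLog2), sd = cfg$batchShiftSd)
    }
  }

  ## ---- OTU layer (log2 abundances -> rounded counts) ------------------
  otuIds <- sprintf("OTU_%04d", seq_len(cfg$nOtu))
  otuBaseline <- stats::runif(cfg$nOtu, 5, 10)
  ## coupled taxa are modeled as abundant genera, so that rounding the
  ## exponentiated log2 abundances to counts barely perturbs the coupling
  if (cfg$nCoupledOtu > 0)
    otuBaseline[seq_len(cfg$nCoupledOtu)] <-
      stats::runif(cfg$nCoupledOtu, 8, 10)
  otuLog2 <- matrix(stats::rnorm(cfg$nOtu * n, sd = cfg$otuNoiseSd),
                    cfg$nOtu, n, dimnames = list(otuIds, sampleIds)) +
    otuBaseline
  otuEffects <- numeric(cfg$nOtu)
  couplingSigma <- sqrt(cfg$hubTargetR / cfg$otuCouplingR^2 - 1)
  otuSigns <- ifelse(seq_len(cfg$nCoupledOtu) <= floor(0.4 * cfg$nCoupledOtu),
                     1, -1)
  if (cfg$nCoupledOtu > 0) {
    idx <- seq_len(cfg$nCoupledOtu)
    otuLog2[idx, ] <- otuBaseline[idx] + outer(otuSigns, h) +
      matrix(stats::rnorm(cfg$nCoupledOtu * n, sd = couplingSigma),
             cfg$nCoupledOtu, n)
    otuEffects[idx] <- otuSigns * hDiff
  }
  nPlainOtu <- cfg$nDeOtu - cfg$nCoupledOtu
  if (nPlainOtu > 0) {
    idx <- cfg$nCoupledOtu + seq_len(nPlainOtu)
    delta <- drawEffects(nPlainOtu)
    otuLog2[idx, ] <- otuLog2[idx, ] + outer(delta, g)
    otuEffects[idx] <- delta
  }
  otuCounts <- round(2^otuLog2)

  ## ---- gene sets and disease list --------------------------------------
  nonPoolMrna <- setdiff(mrnaIds, poolMrna)
  nMicrobe <- if (cfg$nPoolMrna > 0L) cfg$nMicrobeSets else 0L
  microbeNames <- sprintf("cellular_response_to_%s_%02d",
                          rep(c("bacterium", "microbial_stimulus"),
                              length.out = nMicrobe),
                          seq_len(nMicrobe))
  microbeSets <- lapply(seq_len(nMicrobe), function(i) {
    size <- sample(seq(ceiling(0.3 * cfg$nPoolMrna),
                       ceiling(0.8 * cfg$nPoolMrna)), 1L)
    sample(poolMrna, min(size, cfg$nPoolMrna))
  })
  ## make sure the union of microbe sets covers the whole pool
  uncovered <- if (nMicrobe > 0L)
    setdiff(poolMrna, unique(unlist(microbeSets))) else character()
  for (gid in uncovered) {
    i <- sample.int(nMicrobe, 1L)
    microbeSets[[i]] <- base::c(microbeSets[[i]], gid)
  }
  names(microbeSets) <- microbeNames
  decoyNames <- sprintf("%s_%02d",
                        rep(c("lipid_metabolic_process",
                              "neuron_differentiation",
                              "cilium_assembly", "dna_repair"),
                            length.out = cfg$nDecoySets),
                        seq_len(cfg$nDecoySets))
  ## decoys: background (non-DE) genes only, so they share no members with
  ## the microbe-response sets and carry no planted signal
  backgroundMrna <- setdiff(mrnaIds,
                            base::c(mrnaIds[seq_len(cfg$nDeMrna)],
                                    mrnaLayer$unexprIds))
  decoySets <- lapply(seq_len(cfg$nDecoySets), function(i) {
    sample(backgroundMrna, min(60L, length(backgroundMrna)))
  })
  names(decoySets) <- decoyNames
  gsc <- geneSetCollection(
    base::c(microbeSets, decoySets),
    stats::setNames(rep("planted synthetic category",
                        nMicrobe + cfg$nDecoySets),
                    base::c(microbeNames, decoyNames))
  )

  diseaseDecoys <- sample(nonPoolMrna, min(cfg$nDiseaseDecoys,
                                           length(nonPoolMrna)))
  diseaseGenes <- sample(base::c(hubMrna, diseaseDecoys))

  deTruth <- function(ids, effects, nDe) {
    data.frame(feature_id = ids[seq_len(nDe)],
               log2_effect = effects[seq_len(nDe)],
               direction = ifelse(effects[seq_len(nDe)] >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  truth <- list(
    seed = cfg$seed,
    group_labels = cfg$groupLabels,
    de_features = list(
      mrna = deTruth(mrnaIds, mrnaLayer$effects, cfg$nDeMrna),
      lncrna = deTruth(lncrnaIds, lncLayer$effects, cfg$nDeLncrna),
      otu = deTruth(otuIds, otuEffects, cfg$nDeOtu)
    ),
    hub_lncrna = hubLnc,
    hub_mrna = hubMrna,
    aux_lncrna = auxLnc,
    aux_mrna = auxMrna,
    pool_mrna = poolMrna,
    hub_edges = data.frame(
      lncrna_id = rep(hubLnc, each = cfg$nHubMrna),
      mrna_id = rep(hubMrna, times = cfg$nHubLncrna),
      target_r = cfg$hubTargetR *
        rep(hubLncSigns, each = cfg$nHubMrna) *
        rep(hubMrnaSigns, times = cfg$nHubLncrna),
      stringsAsFactors = FALSE
    ),
    otu_couplings = if (cfg$nCoupledOtu > 0) data.frame(
      lncrna_id = rep(hubLnc, each = cfg$nCoupledOtu),
      otu_id = rep(otuIds[seq_len(cfg$nCoupledOtu)], times = cfg$nHubLncrna),
      sign = rep(otuSigns, times = cfg$nHubLncrna) *
        rep(hubLncSigns, each = cfg$nCoupledOtu),
      stringsAsFactors = FALSE
    ) else data.frame(lncrna_id = character(), otu_id = character(),
                      sign = numeric(), stringsAsFactors = FALSE),
    coupled_otu = otuIds[seq_len(cfg$nCoupledOtu)],
    coupled_otu_signs = stats::setNames(otuSigns,
                                        otuIds[seq_len(cfg$nCoupledOtu)]),
    disease_gene_list = diseaseGenes,
    microbe_sets = microbeNames,
    decoy_sets = decoyNames,
    negctl_ids = negctlIds,
    unexpressed = list(mrna = mrnaLayer$unexprIds,
                       lncrna = lncLayer$unexprIds)
  )

  bundle <- list(
    mrna = OmicsMatrix(2^mrnaLog2, layer = "mrna", scale = "raw"),
    lncrna = OmicsMatrix(2^lncLog2, layer = "lncrna", scale = "raw"),
    otu = OmicsMatrix(otuCounts, layer = "otu", scale = "raw"),
    metadata = meta,
    gene_sets = gsc,
    disease_genes = diseaseGenes,
    truth = truth,
    config = cfg
  )
  class(bundle) <- "SyntheticCohort"
  bundle
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf(
    paste0("SyntheticCohort: %d samples; mRNA %d x %d (incl. %d controls), ",
           "lncRNA %d, OTU %d; %d gene sets; %d disease genes\n"),
    ncol(x$mrna), nrow(x$mrna), ncol(x$mrna), length(x$truth$negctl_ids),
    nrow(x$lncrna), nrow(x$otu), length(x$gene_sets),
    length(x$disease_genes)
  ))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the seven fixture artifacts in the package's canonical formats:
#' three matrices (\code{mrna.tsv}, \code{lncrna.tsv}, \code{otu.tsv}),
#' \code{metadata.tsv}, \code{gene_sets.gmt}, \code{disease_genes.txt} and
#' \code{manifest.json} (the ground-truth manifest plus the generating
#' configuration).
#'
#' @param bundle a \code{SyntheticCohort} from [generateCohort()].
#' @param outDir output directory.
#' @param force overwrite a non-empty existing directory.
#' @param digits decimal digits for matrix values (\code{NA} = full
#'   precision; the packaged fixture uses 4).
#' @return Named character vector of the seven written paths, invisibly.
#' @export
writeFixture <- function(bundle, outDir, force = FALSE, digits = NA) {
  stopifnot(inherits(bundle, "SyntheticCohort"))
  if (dir.exists(outDir) && length(list.files(outDir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- base::c(
    mrna = file.path(outDir, "mrna.tsv"),
    lncrna = file.path(outDir, "lncrna.tsv"),
    otu = file.path(outDir, "otu.tsv"),
    metadata = file.path(outDir, "metadata.tsv"),
    gene_sets = file.path(outDir, "gene_sets.gmt"),
    disease_genes = file.path(outDir, "disease_genes.txt"),
    manifest = file.path(outDir, "manifest.json")
  )
  writeOmicsMatrix(bundle$mrna, paths[["mrna"]], digits = digits)
  writeOmicsMatrix(bundle$lncrna, paths[["lncrna"]], digits = digits)
  writeOmicsMatrix(bundle$otu, paths[["otu"]], digits = 0)
  writeSampleMetadata(bundle$metadata, paths[["metadata"]])
  writeGeneSets(bundle$gene_sets, paths[["gene_sets"]])
  writeGeneList(bundle$disease_genes, paths[["disease_genes"]],
                comment = "synthetic disease gene list (planted)")
  manifest <- bundle$truth
  manifest$config <- unclass(bundle$config)
  writeRunManifest(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Read a fixture directory back into a cohort bundle
#'
#' @param dir a directory written by [writeFixture()].
#' @return A list with the same shape as [generateCohort()] output (the
#'   ground-truth manifest is returned as plain lists/data.frames).
#' @export
readFixture <- function(dir) {
  manifest <- readRunManifest(file.path(dir, "manifest.json"))
  bundle <- list(
    mrna = readExpressionMatrix(file.path(dir, "mrna.tsv"), "mrna", "raw"),
    lncrna = readExpressionMatrix(file.path(dir, "lncrna.tsv"), "lncrna", "raw"),
    otu = readExpressionMatrix(file.path(dir, "otu.tsv"), "otu", "raw"),
    metadata = readSampleMetadata(file.path(dir, "metadata.tsv")),
    gene_sets = readGeneSets(file.path(dir, "gene_sets.gmt")),
    disease_genes = readGeneList(file.path(dir, "disease_genes.txt")),
    truth = manifest,
    config = manifest$config
  )
  class(bundle) <- "SyntheticCohort"
  bundle
}
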