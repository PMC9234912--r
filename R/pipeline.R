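## Orchestration of the full cascade: preprocessing, per-layer differential
## analysis, overrepresentation and curation, cross-layer networks,
## median-|R| importance, OTU co-abundance, PCA reports, funnel counts and a
## machine-readable run manifest.

#' Parameters of the cascade
#'
#' Every threshold of the cascade in one validated list. Defaults are the
#' thresholds the method is defined with: FDR ceiling 0.05 (inclusive) for
#' all layers, a strict log2 fold-change gate of 0.58 (1.5-fold) on the mRNA
#' layer only, co-expression threshold |r| > 0.95, co-abundance thresholds
#' |r| > 0.5 and p < 0.05, top-15 category curation by keyword.
#'
#' @param alpha FDR ceiling per layer (inclusive).
#' @param fcLog2 strict log2 fold-change gate on the mRNA layer.
#' @param topN categories considered by the curation step.
#' @param keywords substrings selecting microbe-response categories.
#' @param setNames explicit category names (overrides keywords).
#' @param rMinExpr lncRNA:mRNA co-expression threshold (strict, on |r| in
#'   \code{"absolute"} mode).
#' @param exprMode \code{"absolute"} or \code{"signed"} co-expression
#'   thresholding.
#' @param rMinOtu,pMaxOtu lncRNA:OTU co-abundance thresholds (strict).
#' @param pMaxExpr p ceiling on co-expression edges.
#' @param exprPseudocount,otuPseudocount log2 pseudocounts (0 for array
#'   intensities, 1 for OTU counts where zeros occur).
#' @param minFraction detection filter: required fraction of samples above
#'   background.
#' @param batchFactors batch factor columns adjusted sequentially, in order.
#' @param negctlPattern regular expression identifying negative-control rows
#'   of the expression matrices.
#' @param welchOtu use Welch's t for the OTU layer instead of pooled t.
#' @param seed integer seed recorded in the manifest (the cascade itself is
#'   deterministic).
#' @return A validated list of class \code{CascadeParams}.
#' @export
cascadeParams <- function(alpha = 0.05, fcLog2 = 0.58,
                          topN = 15L,
                          keywords = c("bacterium", "microb"),
                          setNames = NULL,
                          rMinExpr = 0.95, exprMode = "absolute",
                          pMaxExpr = 0.05,
                          rMinOtu = 0.5, pMaxOtu = 0.05,
                          exprPseudocount = 0, otuPseudocount = 1,
                          minFraction = 0.5,
                          batchFactors = c("labeling_batch", "array_batch"),
                          negctlPattern = "^NEGCTL",
                          welchOtu = FALSE,
                          seed = 1L) {
  p <- list(alpha = alpha, fcLog2 = fcLog2, topN = as.integer(topN),
            keywords = keywords, setNames = setNames,
            rMinExpr = rMinExpr, exprMode = exprMode, pMaxExpr = pMaxExpr,
            rMinOtu = rMinOtu, pMaxOtu = pMaxOtu,
            exprPseudocount = exprPseudocount,
            otuPseudocount = otuPseudocount,
            minFraction = minFraction, batchFactors = batchFactors,
            negctlPattern = negctlPattern, welchOtu = isTRUE(welchOtu),
            seed = as.integer(seed))
  stopifnot(p$alpha > 0, p$alpha <= 1,
            p$fcLog2 >= 0,
            p$rMinExpr > 0, p$rMinExpr < 1,
            p$rMinOtu > 0, p$rMinOtu < 1,
            p$minFraction > 0, p$minFraction <= 1)
  class(p) <- "CascadeParams"
  p
}

.stageStop <- function(stage, detail) {
  stop(sprintf("cascade aborted at stage '%s': %s", stage, detail),
       call. = FALSE)
}

.requireNonEmpty <- function(x, stage, what) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n == 0L) .stageStop(stage, paste0("empty ", what))
  x
}

#' Run the full multi-layer cascade
#'
#' Executes the whole inference chain on in-memory objects:
#' \enumerate{
#'   \item expression layers (raw intensities, with negative-control rows)
#'     are log2-transformed jointly, detection-filtered against the
#'     negative-control background, quantile-normalized, batch-adjusted
#'     (one pass per batch factor, group preserved) and split into mRNA and
#'     lncRNA layers; the OTU counts are log2(x+1)-transformed;
#'   \item per-layer two-group tests (moderated t for the expression layers,
#'     two-sample t for OTUs) with BH FDR <= alpha; the fold-change gate
#'     applies to the mRNA layer only;
#'   \item overrepresentation of the gated mRNA genes against the gene-set
#'     collection (universe = mRNAs surviving the detection filter),
#'     curation of the top categories by keyword, pooling of their unique
#'     query genes;
#'   \item Z-scoring of significant features, the lncRNA:mRNA co-expression
#'     network at |r| > rMinExpr between all DE lncRNAs and the pooled
#'     genes, intersection of the pooled genes with the disease list,
#'     restriction of the network to the overlap, median-|R| importance of
#'     both sides;
#'   \item the lncRNA:OTU co-abundance network (|r| > rMinOtu, p < pMaxOtu)
#'     between the refined hub lncRNAs and the significant OTUs, with
#'     per-OTU sign consistency;
#'   \item PCA (2 components) and group-separation scores per layer on the
#'     significant features, and on the final hub lncRNA and OTU sets.
#' }
#' Any stage yielding an empty required set aborts with the stage name.
#'
#' @param mrna,lncrna \linkS4class{OmicsMatrix} raw expression layers
#'   (the mRNA matrix may carry negative-control rows).
#' @param otu \linkS4class{OmicsMatrix} raw OTU count table.
#' @param meta metadata data.frame (see [readSampleMetadata()]).
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param diseaseGenes character vector: the disease gene list.
#' @param params a \code{CascadeParams} list.
#' @return A list of class \code{CascadeResult}; see the individual elements
#'   (\code{de}, \code{enrichment}, \code{selected_sets},
#'   \code{pooled_genes}, \code{network_full}, \code{disease_overlap},
#'   \code{network_refined}, \code{importance_lncrna},
#'   \code{importance_mrna}, \code{otu_coabundance}, \code{pca},
#'   \code{separation}, \code{funnel}, \code{params}).
#' @export
runCascade <- function(mrna, lncrna, otu, meta, geneSets, diseaseGenes,
                       params = cascadeParams()) {
  stopifnot(inherits(params, "CascadeParams"))
  validateSampleMetadata(meta, mrna)

  ## ---- preprocess: joint expression path -------------------------------
  joint <- OmicsMatrix(rbind(omicsValues(mrna), omicsValues(lncrna)),
                       layer = "mrna", scale = "raw")
  jointLog <- log2Transform(joint, pseudocount = params$exprPseudocount)
  negctl <- grep(params$negctlPattern, featureIds(jointLog), value = TRUE)
  if (length(negctl) >= 2L) {
    bg <- computeBackground(jointLog, negctl)
    jointLog <- filterAboveBackground(jointLog, bg,
                                      minFraction = params$minFraction)
  } else {
    bg <- NULL
  }
  keep <- setdiff(featureIds(jointLog), negctl)
  jointLog <- jointLog[keep, ]
  .requireNonEmpty(featureIds(jointLog), "background_filter",
                   "expression feature set")
  jointLog <- quantileNormalize(jointLog)
  for (bf in intersect(params$batchFactors, names(meta)))
    jointLog <- batchAdjust(jointLog, meta, bf)

  layerMap <- stats::setNames(
    rep(c("mrna", "lncrna"), c(nrow(mrna), nrow(lncrna))),
    base::c(featureIds(mrna), featureIds(lncrna))
  )
  ids <- featureIds(jointLog)
  exprLog <- list(
    mrna = OmicsMatrix(omicsValues(jointLog)[layerMap[ids] == "mrna", ,
                                             drop = FALSE],
                       layer = "mrna", scale = "log2"),
    lncrna = OmicsMatrix(omicsValues(jointLog)[layerMap[ids] == "lncrna", ,
                                               drop = FALSE],
                         layer = "lncrna", scale = "log2")
  )
  otuLog <- log2Transform(otu, pseudocount = params$otuPseudocount)

  ## ---- differential analysis per layer ---------------------------------
  de <- list(
    mrna = applyDeFilters(moderatedTTest(exprLog$mrna, meta),
                          alpha = params$alpha, fcLog2 = params$fcLog2,
                          useFc = TRUE),
    lncrna = applyDeFilters(moderatedTTest(exprLog$lncrna, meta),
                            alpha = params$alpha, useFc = FALSE),
    otu = applyDeFilters(twoSampleT(otuLog, meta, welch = params$welchOtu),
                         alpha = params$alpha, useFc = FALSE)
  )
  sig <- lapply(de, function(r) r$feature_id[r$significant])
  gated <- de$mrna$feature_id[de$mrna$selected]
  for (ly in names(sig))
    .requireNonEmpty(sig[[ly]], paste0("de_", ly), "significant feature set")
  .requireNonEmpty(gated, "fc_gate", "fold-change-gated mRNA set")

  ## ---- enrichment and curation -----------------------------------------
  universe <- featureIds(exprLog$mrna)
  enr <- overrepresentationTest(gated, geneSets, universe = universe)
  selected <- selectCategories(enr, topN = params$topN,
                               keywords = params$keywords,
                               names = params$setNames,
                               descriptions = geneSetDescriptions(geneSets))
  .requireNonEmpty(selected, "category_selection", "selected category set")
  pooled <- poolUniqueGenes(geneSets, selected, gated)
  .requireNonEmpty(pooled, "gene_pooling", "pooled gene set")

  ## ---- co-expression network and disease refinement --------------------
  zLnc <- zscoreRows(OmicsMatrix(
    omicsValues(exprLog$lncrna)[sig$lncrna, , drop = FALSE],
    layer = "lncrna", scale = "log2"))
  zPool <- zscoreRows(OmicsMatrix(
    omicsValues(exprLog$mrna)[pooled, , drop = FALSE],
    layer = "mrna", scale = "log2"))
  cmFull <- crossLayerCorrelation(zLnc, zPool)
  netFull <- buildNetwork(cmFull, rMin = params$rMinExpr,
                          pMax = params$pMaxExpr, mode = params$exprMode)
  .requireNonEmpty(networkEdges(netFull), "coexpression_network", "edge set")

  overlap <- intersectGeneLists(pooled, diseaseGenes)
  .requireNonEmpty(overlap, "disease_overlap", "disease-gene overlap")
  netRefined <- restrictNetwork(netFull, intersect(overlap, sideBNodes(netFull)))
  .requireNonEmpty(networkEdges(netRefined), "network_refinement", "edge set")

  fcLnc <- stats::setNames(de$lncrna$log2_fc, de$lncrna$feature_id)
  fcMrna <- stats::setNames(de$mrna$log2_fc, de$mrna$feature_id)
  impLnc <- medianImportance(cmFull, netRefined, axis = "a", direction = fcLnc)
  impMrna <- medianImportance(cmFull, netRefined, axis = "b",
                              direction = fcMrna)

  ## ---- OTU co-abundance -------------------------------------------------
  zOtuSig <- zscoreRows(OmicsMatrix(
    omicsValues(otuLog)[sig$otu, , drop = FALSE],
    layer = "otu", scale = "log2"))
  hubLnc <- sideANodes(netRefined)
  zHubLnc <- OmicsMatrix(omicsValues(zLnc)[hubLnc, , drop = FALSE],
                         layer = "lncrna", scale = "zscore")
  coab <- otuCoabundance(zHubLnc, zOtuSig,
                         rMin = params$rMinOtu, pMax = params$pMaxOtu)

  ## ---- ordination --------------------------------------------------------
  zMrnaSig <- zscoreRows(OmicsMatrix(
    omicsValues(exprLog$mrna)[sig$mrna, , drop = FALSE],
    layer = "mrna", scale = "log2"))
  coabLnc <- sideANodes(coab$network)
  coabOtu <- sideBNodes(coab$network)
  pcaInputs <- list(
    mrna = zMrnaSig, lncrna = zLnc, otu = zOtuSig,
    hub_lncrna = if (length(coabLnc) >= 2L)
      OmicsMatrix(omicsValues(zLnc)[coabLnc, , drop = FALSE],
                  layer = "lncrna", scale = "zscore") else NULL,
    coupled_otu = if (length(coabOtu) >= 2L)
      OmicsMatrix(omicsValues(zOtuSig)[coabOtu, , drop = FALSE],
                  layer = "otu", scale = "zscore") else NULL
  )
  pca <- lapply(pcaInputs, function(m) {
    if (is.null(m)) NULL else pcaSamples(m, nComponents = 2L)
  })
  separation <- lapply(pca, function(p) {
    if (is.null(p)) NULL else groupSeparation(p, meta)
  })

  funnel <- data.frame(
    stage = base::c("expression_features", "de_mrna", "de_lncrna", "de_otu",
                    "fc_gated_mrna", "selected_categories", "pooled_genes",
                    "network_lncrna", "network_mrna", "disease_overlap",
                    "refined_lncrna", "refined_mrna",
                    "coabundance_lncrna", "coabundance_otu"),
    count = base::c(length(ids), lengths(sig[c("mrna", "lncrna", "otu")]),
                    length(gated), length(selected), length(pooled),
                    length(sideANodes(netFull)), length(sideBNodes(netFull)),
                    length(overlap),
                    length(sideANodes(netRefined)),
                    length(sideBNodes(netRefined)),
                    length(coabLnc), length(coabOtu)),
    stringsAsFactors = FALSE
  )

  out <- list(
    de = de, enrichment = enr, selected_sets = selected,
    pooled_genes = pooled,
    correlation_full = cmFull,
    network_full = netFull,
    disease_overlap = overlap,
    network_refined = netRefined,
    importance_lncrna = impLnc, importance_mrna = impMrna,
    otu_coabundance = coab,
    pca = pca, separation = separation,
    background = bg,
    funnel = funnel,
    params = params
  )
  class(out) <- "CascadeResult"
  out
}

#' @export
print.CascadeResult <- function(x, ...) {
  cat("CascadeResult\n")
  f <- x$funnel
  cat(paste0(sprintf("  %-22s %6d", f$stage, f$count), collapse = "\n"), "\n")
  invisible(x)
}

#' Funnel report of a cascade run
#'
#' Per-stage feature counts, the thresholds that produced them, and counts
#' as percentages of the stage they filter. The JSON twin of the run log.
#'
#' @param bundle a \code{CascadeResult} from [runCascade()].
#' @return A list with elements \code{stages} (data.frame \code{stage},
#'   \code{count}, \code{percent_of_previous}), \code{thresholds} and
#'   \code{flags} (stages with zero counts); serializable with
#'   [writeRunManifest()].
#' @export
reportFunnel <- function(bundle) {
  stopifnot(inherits(bundle, "CascadeResult"))
  f <- bundle$funnel
  ## the lncRNA funnel is the nested-filter chain
  chain <- base::c("de_lncrna", "network_lncrna", "refined_lncrna",
                   "coabundance_lncrna")
  counts <- f$count[match(chain, f$stage)]
  pct <- base::c(100, round(100 * counts[-1] / pmax(counts[-length(counts)], 1), 1))
  p <- bundle$params
  list(
    stages = f,
    lncrna_funnel = data.frame(stage = chain, count = counts,
                               percent_of_previous = pct,
                               stringsAsFactors = FALSE),
    thresholds = list(alpha = p$alpha, fc_log2 = p$fcLog2,
                      r_min_expression = p$rMinExpr,
                      r_min_otu = p$rMinOtu, p_max_otu = p$pMaxOtu,
                      top_n = p$topN),
    flags = f$stage[f$count == 0L]
  )
}

#' Check the structural contract of a funnel report
#'
#' Verifies the keys and column layout that downstream consumers of the
#' funnel JSON rely on.
#'
#' @param report a list from [reportFunnel()] (or re-read from JSON).
#' @return \code{TRUE}, or an error describing the violated key.
#' @export
validateFunnelReport <- function(report) {
  need <- base::c("stages", "lncrna_funnel", "thresholds", "flags")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("funnel report missing keys: ", paste(missing, collapse = ", "))
  if (!all(base::c("stage", "count") %in% names(report$stages)))
    stop("funnel report 'stages' must have 'stage' and 'count'")
  thr <- base::c("alpha", "fc_log2", "r_min_expression", "r_min_otu",
                 "p_max_otu", "top_n")
  missing <- setdiff(thr, names(report$thresholds))
  if (length(missing))
    stop("funnel report thresholds missing: ", paste(missing, collapse = ", "))
  TRUE
}

#' Read a cascade configuration from YAML
#'
#' The YAML mirrors the function arguments: an \code{inputs} block (paths to
#' the seven fixture artifacts, or \code{synthetic: true} with an optional
#' \code{synthetic_config} block passed to [syntheticConfig()]), and a
#' \code{params} block passed to [cascadeParams()].
#'
#' @param path path to a YAML file.
#' @return A list with elements \code{inputs}, \code{params}
#'   (\code{CascadeParams}) and \code{synthetic_config} (\code{NULL} or a
#'   \code{SyntheticConfig}).
#' @importFrom yaml read_yaml
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(cascadeParams, as.list(cfg$params %||% list()))
  syn <- if (isTRUE(cfg$inputs$synthetic) || is.null(cfg$inputs)) {
    do.call(syntheticConfig, as.list(cfg$synthetic_config %||% list()))
  } else NULL
  list(inputs = cfg$inputs, params = params, synthetic_config = syn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cascade from a configuration, writing all outputs
#'
#' Loads the inputs (fixture files, or a synthetic cohort generated from the
#' configuration), runs [runCascade()], and writes every stage output plus a
#' JSON run manifest (inputs, parameters, seed, funnel, output hashes) to
#' \code{outDir}.
#'
#' @param config a list from [readPipelineConfig()], or a path to a YAML
#'   configuration.
#' @param outDir output directory (created if absent).
#' @return The \code{CascadeResult}, invisibly; side effect: TSV/JSON
#'   outputs and \code{run_manifest.json} under \code{outDir}.
#' @importFrom tools md5sum
#' @export
runCascadeFromConfig <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic_config)) {
    bundle <- generateCohort(config$synthetic_config)
  } else {
    paths <- config$inputs
    bundle <- list(
      mrna = readExpressionMatrix(paths$mrna, "mrna", "raw"),
      lncrna = readExpressionMatrix(paths$lncrna, "lncrna", "raw"),
      otu = readExpressionMatrix(paths$otu, "otu", "raw"),
      metadata = readSampleMetadata(paths$metadata),
      gene_sets = readGeneSets(paths$gene_sets),
      disease_genes = readGeneList(paths$disease_genes)
    )
  }
  res <- runCascade(bundle$mrna, bundle$lncrna, bundle$otu, bundle$metadata,
                    bundle$gene_sets, bundle$disease_genes,
                    params = config$params)

  writeDe <- function(r, path) {
    out <- r
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeDe(res$de$mrna, file.path(outDir, "de_mrna.tsv"))
  writeDe(res$de$lncrna, file.path(outDir, "de_lncrna.tsv"))
  writeDe(res$de$otu, file.path(outDir, "de_otu.tsv"))
  enr <- res$enrichment
  enr$overlap_members <- vapply(enr$overlap_members, paste, character(1),
                                collapse = ",")
  utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneList(res$pooled_genes, file.path(outDir, "pooled_genes.txt"))
  writeGeneList(res$disease_overlap, file.path(outDir, "disease_overlap.txt"))
  writeNetwork(res$network_full, file.path(outDir, "network_full.tsv"))
  writeNetwork(res$network_refined, file.path(outDir, "network_refined.tsv"))
  writeNetwork(res$otu_coabundance$network,
               file.path(outDir, "network_otu.tsv"))
  utils::write.table(res$importance_lncrna,
                     file.path(outDir, "importance_lncrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$importance_mrna,
                     file.path(outDir, "importance_mrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeRunManifest(reportFunnel(res), file.path(outDir, "funnel.json"))

  outputs <- setdiff(list.files(outDir, full.names = TRUE),
                     file.path(outDir, "run_manifest.json"))
  manifest <- list(
    inputs = if (is.null(config$synthetic_config)) config$inputs else
      list(synthetic = TRUE, synthetic_config = unclass(config$synthetic_config)),
    params = unclass(config$params),
    seed = config$params$seed,
    funnel = res$funnel,
    output_md5 = as.list(tools::md5sum(sort(outputs)))
  )
  writeRunManifest(manifest, file.path(outDir, "run_manifest.json"))
  invisible(res)
}
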