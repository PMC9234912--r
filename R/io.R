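## Readers and writers for every external artifact of the cascade.
## Canonical matrix dialect: TSV, header cell (1,1) = "feature_id", header row
## of sample ids, first column feature ids, strictly numeric body ("." decimal
## separator). Absent or malformed cells are errors, never zeros.

#' Read a feature x sample matrix from TSV
#'
#' Parses the canonical tab-separated matrix dialect: first header cell
#' \code{feature_id}, remaining header cells sample ids, first column feature
#' ids, numeric body. Malformed numeric cells are reported with their row and
#' column; duplicate feature or sample ids and missing cells are rejected.
#'
#' @param path path to a TSV file.
#' @param layer data layer tag of the matrix (\code{"mrna"}, \code{"lncrna"},
#'   \code{"otu"}).
#' @param scale scale tag (\code{"raw"}, \code{"log2"}, \code{"zscore"}).
#' @return An \linkS4class{OmicsMatrix}.
#' @seealso [writeOmicsMatrix()] for the inverse operation.
#' @export
readExpressionMatrix <- function(path, layer, scale) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("matrix file must have a header and at least one feature row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "feature_id")
    stop("header cell (1,1) must be 'feature_id', found '", header[1L], "'")
  samples <- header[-1L]
  if (length(samples) == 0L) stop("no sample columns in ", path)
  if (anyDuplicated(samples)) stop("duplicate sample ids in ", path)
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop(sprintf("row %d has %d fields, expected %d",
                 which(nf != length(header))[1L] + 1L,
                 nf[nf != length(header)][1L], length(header)))
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- vapply(body, function(f) f[-1L], character(length(samples)))
  cells <- if (length(samples) == 1L) matrix(cells, nrow = 1L) else cells
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) | cells == "")
  if (length(bad)) {
    ## cells is samples x features (vapply transposes)
    j <- (bad[1L] - 1L) %/% length(samples) + 1L
    i <- (bad[1L] - 1L) %% length(samples) + 1L
    stop(sprintf("malformed numeric cell at feature '%s', sample '%s': '%s'",
                 ids[j], samples[i], cells[bad[1L]]))
  }
  values <- matrix(num, nrow = length(ids), ncol = length(samples),
                   byrow = TRUE, dimnames = list(ids, samples))
  OmicsMatrix(values, layer = layer, scale = scale)
}

#' Write an OmicsMatrix to TSV
#'
#' Writes the canonical matrix dialect read back by
#' [readExpressionMatrix()]. With \code{digits = NA} values are written at
#' full precision (round-trips to <= 1e-12).
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param path output file path.
#' @param digits number of decimal digits, or \code{NA} for full precision.
#' @return \code{path}, invisibly.
#' @export
writeOmicsMatrix <- function(m, path, digits = NA) {
  v <- omicsValues(m)
  body <- if (is.na(digits)) {
    format(v, digits = 17, trim = TRUE, scientific = FALSE)
  } else {
    format(round(v, digits), trim = TRUE, scientific = FALSE)
  }
  lines <- c(
    paste(c("feature_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], body[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample metadata (group and batch factors)
#'
#' Expects a TSV with columns \code{sample_id}, \code{group}, and zero or more
#' batch-factor columns. The group column must have exactly two non-empty
#' levels; group levels are ordered by first appearance (the first level is
#' "group A" in all effect signs).
#'
#' @param path path to a TSV file.
#' @return A data.frame with rownames = sample ids, a factor column
#'   \code{group}, and factor batch columns.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  rownames(df) <- df$sample_id
  df$group <- factor(df$group, levels = unique(df$group))
  if (nlevels(df$group) != 2L)
    stop("exactly two group labels are required, found: ",
         paste(levels(df$group), collapse = ", "))
  for (col in setdiff(names(df), c("sample_id", "group")))
    df[[col]] <- factor(df[[col]])
  validateSampleMetadata(df)
  df
}

#' Validate sample metadata, optionally against an OmicsMatrix
#'
#' Checks the two-group structure, and that every batch factor level carries
#' at least two samples (required for variance estimation). With \code{m}
#' given, also checks that every sample of the matrix appears exactly once.
#'
#' @param meta metadata data.frame as returned by [readSampleMetadata()].
#' @param m optional \linkS4class{OmicsMatrix} to cross-check samples against.
#' @return \code{meta}, invisibly.
#' @export
validateSampleMetadata <- function(meta, m = NULL) {
  grp <- meta$group
  if (is.null(grp) || length(unique(grp)) != 2L)
    stop("metadata must define exactly two non-empty groups")
  if (any(table(grp) == 0L)) stop("both groups must be non-empty")
  for (col in setdiff(names(meta), c("sample_id", "group"))) {
    tab <- table(meta[[col]])
    if (any(tab < 2L))
      stop(sprintf("batch factor '%s' has a level with fewer than 2 samples", col))
  }
  if (!is.null(m)) {
    if (!setequal(sampleIds(m), rownames(meta)))
      stop("metadata samples do not match matrix samples")
  }
  invisible(meta)
}

#' Write sample metadata to TSV
#'
#' @param meta metadata data.frame (see [readSampleMetadata()]).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
  out <- meta
  out$sample_id <- rownames(meta)
  out <- out[, c("sample_id", setdiff(names(out), "sample_id")), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, \code{name TAB description TAB member...}.
#' Lines with fewer than three fields are format errors (reported with their
#' line number); duplicated members within a set are collapsed.
#'
#' @param path path to a GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1L]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L))
    stop("GMT set with no members: ", nm[lengths(sets) == 0L][1L])
  desc <- vapply(fields, `[[`, character(1), 2L)
  names(desc) <- nm
  geneSetCollection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(gsc, path) {
  nm <- geneSetNames(gsc)
  desc <- geneSetDescriptions(gsc)
  lines <- vapply(nm, function(s) {
    paste(c(s, desc[[s]], geneSets(gsc)[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; \code{#} comment lines and blank lines are
#' skipped (matches knowledge-base export style lists).
#'
#' @param path path to a text file.
#' @return Character vector of unique gene ids, in file order.
#' @export
readGeneList <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write a plain-text gene list
#'
#' @param genes character vector of gene ids.
#' @param path output file path.
#' @param comment optional comment written as a leading \code{#} line.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(genes, path, comment = NULL) {
  lines <- as.character(genes)
  if (!is.null(comment)) lines <- c(paste0("# ", comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a bipartite network as an edge-list TSV
#'
#' Columns \code{source_id}, \code{source_layer}, \code{target_id},
#' \code{target_layer}, \code{pearson_r}, \code{p_value}; rows sorted by
#' source id then target id, so output is deterministic.
#'
#' @param network a \linkS4class{BipartiteCorrelationNetwork}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  e <- networkEdges(network)
  e <- e[order(e$source_id, e$target_id), , drop = FALSE]
  e$pearson_r <- format(e$pearson_r, digits = 17, trim = TRUE, scientific = TRUE)
  e$p_value <- format(e$p_value, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [writeNetwork()]
#'
#' @param path path to an edge-list TSV.
#' @return A data.frame of edges (the full network object is not
#'   reconstructed; thresholds live in the run manifest).
#' @export
readNetworkEdges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_id", "source_layer", "target_id", "target_layer",
            "pearson_r", "p_value")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and output-file hashes for a run, so that
#' any result can be traced to the exact configuration that produced it.
#'
#' @param manifest a named list (arbitrary nesting of scalars, vectors, lists).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @importFrom jsonlite write_json
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON run manifest
#'
#' @param path path to a manifest written by [writeRunManifest()].
#' @return A named list.
#' @importFrom jsonlite read_json
#' @export
readRunManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
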