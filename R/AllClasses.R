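#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors SimpleList metadata
NULL

.LAYERS <- c("mrna", "lncrna", "otu")
.SCALES <- c("raw", "log2", "zscore")

#' OmicsMatrix: a feature x sample matrix with a layer and scale tag
#'
#' The common currency of every stage of the cascade: a numeric
#' feature x sample matrix (stored as a \linkS4class{SummarizedExperiment})
#' carrying a data-layer tag (\code{"mrna"}, \code{"lncrna"} or \code{"otu"})
#' and a scale tag (\code{"raw"}, \code{"log2"} or \code{"zscore"}).
#' Feature and sample identifiers must be unique and every cell must be a
#' non-missing finite number; readers and constructors enforce this rather
#' than coercing silently.
#'
#' @slot layer character(1), one of \code{"mrna"}, \code{"lncrna"}, \code{"otu"}.
#' @slot scale character(1), one of \code{"raw"}, \code{"log2"}, \code{"zscore"}.
#'
#' @seealso [readExpressionMatrix()], [log2Transform()], [zscoreRows()]
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(layer = "character", scale = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of: %s", paste(.LAYERS, collapse = ", ")))
  if (length(object@scale) != 1L || !object@scale %in% .SCALES)
    msg <- c(msg, sprintf("'scale' must be one of: %s", paste(.SCALES, collapse = ", ")))
  v <- assay(object)
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v))))
    msg <- c(msg, "feature and sample identifiers are required")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate feature identifiers")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate sample identifiers")
  if (!is.numeric(v))
    msg <- c(msg, "matrix must be numeric")
  else if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "matrix contains missing or non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must be named with unique identifiers.
#' @param layer data layer: \code{"mrna"}, \code{"lncrna"} or \code{"otu"}.
#' @param scale value scale: \code{"raw"}, \code{"log2"} or \code{"zscore"}.
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("NM_1", "NM_2"), c("s1", "s2", "s3")))
#' OmicsMatrix(m, layer = "mrna", scale = "raw")
#' @export
OmicsMatrix <- function(values, layer, scale) {
  layer <- match.arg(layer, .LAYERS)
  scale <- match.arg(scale, .SCALES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = SimpleList(exprs = values))
  new("OmicsMatrix", se, layer = layer, scale = scale)
}

## internal: same ids/layer, new values and (optionally) scale
.withValues <- function(m, values, scale = omicsScale(m)) {
  OmicsMatrix(values, layer = omicsLayer(m), scale = scale)
}

#' @describeIn OmicsMatrix-accessors feature identifiers (row names)
#' @export
featureIds <- function(x) rownames(x)

#' @describeIn OmicsMatrix-accessors sample identifiers (column names)
#' @export
sampleIds <- function(x) colnames(x)

#' Accessors for OmicsMatrix
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @return \code{featureIds}/\code{sampleIds}: character vectors;
#'   \code{omicsValues}: the numeric matrix; \code{omicsLayer}/\code{omicsScale}:
#'   character(1) tags.
#' @name OmicsMatrix-accessors
NULL

#' @describeIn OmicsMatrix-accessors the numeric feature x sample matrix
#' @export
omicsValues <- function(x) assay(x, "exprs")

#' @describeIn OmicsMatrix-accessors the data-layer tag
#' @export
omicsLayer <- function(x) x@layer

#' @describeIn OmicsMatrix-accessors the scale tag
#' @export
omicsScale <- function(x) x@scale

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf(
    "OmicsMatrix [%s, %s]: %d features x %d samples\n",
    object@layer, object@scale, nrow(object), ncol(object)
  ))
})

#' GeneSetCollection: named gene sets with an optional background universe
#'
#' A stand-in for GO biological-process style collections: named sets of gene
#' identifiers with one-line descriptions, optionally carrying an explicit
#' background universe for overrepresentation testing. Members inside a set
#' are unique; set names are unique; empty sets are rejected.
#'
#' @slot sets named list of character vectors (unique members).
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @slot universe character vector of background gene ids (may be empty).
#' @seealso [readGeneSets()], [overrepresentationTest()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character", universe = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets) &&
      (is.null(nm) || anyDuplicated(nm) || any(nm == "")))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "set members must be character vectors")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "set members must be unique within a set")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "one description per set is required")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids; duplicated members
#'   within a set are collapsed.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to empty strings).
#' @param universe optional character vector of background gene ids.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
geneSetCollection <- function(sets, descriptions = NULL, universe = character()) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
  }
  new("GeneSetCollection",
    sets = sets,
    descriptions = descriptions[names(sets)],
    universe = unique(as.character(universe))
  )
}

#' @describeIn GeneSetCollection-accessors the named list of member vectors
#' @export
geneSets <- function(x) x@sets

#' Accessors for GeneSetCollection
#' @param x a \linkS4class{GeneSetCollection}.
#' @name GeneSetCollection-accessors
NULL

#' @describeIn GeneSetCollection-accessors set names
#' @export
geneSetNames <- function(x) names(x@sets)

#' @describeIn GeneSetCollection-accessors set descriptions
#' @export
geneSetDescriptions <- function(x) x@descriptions

#' @describeIn GeneSetCollection-accessors the explicit background universe
#' @export
geneSetUniverse <- function(x) x@universe

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf(
    "GeneSetCollection: %d sets (sizes %s), universe of %d ids\n",
    length(object@sets),
    if (length(object@sets)) paste(range(lengths(object@sets)), collapse = "-") else "0-0",
    length(object@universe)
  ))
})

#' CorrelationMatrix: dense cross-layer Pearson correlations
#'
#' Pairwise Pearson correlations between the features of two layers measured
#' on the same samples, with two-sided p-values from the t transform
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of freedom.
#'
#' @slot r numeric matrix of correlations, rows = layer-A features.
#' @slot p numeric matrix of two-sided p-values, same dimensions.
#' @slot n integer, number of samples every cell is computed from.
#' @slot layerA,layerB layer tags of the two sides.
#' @seealso [crossLayerCorrelation()], [buildNetwork()]
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(r = "matrix", p = "matrix", n = "integer",
                 layerA = "character", layerB = "character")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@r), dim(object@p)))
    msg <- c(msg, "'r' and 'p' dimensions differ")
  if (any(abs(object@r) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "|r| exceeds 1")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values outside [0, 1]")
  if (is.null(rownames(object@r)) || is.null(colnames(object@r)))
    msg <- c(msg, "row and column feature ids are required")
  if (object@n < 4L)
    msg <- c(msg, "at least 4 samples are required")
  if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationMatrix-accessors the correlation matrix
#' @export
corValues <- function(x) x@r

#' Accessors for CorrelationMatrix
#' @param x a \linkS4class{CorrelationMatrix}.
#' @name CorrelationMatrix-accessors
NULL

#' @describeIn CorrelationMatrix-accessors the p-value matrix
#' @export
corPvalues <- function(x) x@p

#' @describeIn CorrelationMatrix-accessors the sample size used for every cell
#' @export
corSampleSize <- function(x) x@n

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf(
    "CorrelationMatrix: %d %s features x %d %s features (n = %d samples)\n",
    nrow(object@r), object@layerA, ncol(object@r), object@layerB, object@n
  ))
})

#' BipartiteCorrelationNetwork: thresholded cross-layer edges
#'
#' A bipartite network whose edges connect features of two layers when their
#' Pearson correlation passes the recorded thresholds (strict \code{> rMin} on
#' \code{r} or \code{|r|} depending on \code{mode}, and \code{p < pMax} when a
#' p ceiling is set). Nodes with no passing edge are dropped, so every node
#' has degree >= 1 by construction.
#'
#' @slot edges data.frame with columns \code{source_id}, \code{source_layer},
#'   \code{target_id}, \code{target_layer}, \code{pearson_r}, \code{p_value},
#'   sorted by source then target id.
#' @slot layerA,layerB layer tags of the two sides.
#' @slot rMin,pMax recorded thresholds (\code{pMax} may be \code{NA} for none).
#' @slot mode \code{"absolute"} (threshold on |r|) or \code{"signed"} (on r).
#' @seealso [buildNetwork()], [restrictNetwork()], [writeNetwork()]
#' @exportClass BipartiteCorrelationNetwork
setClass("BipartiteCorrelationNetwork",
  representation(edges = "data.frame", layerA = "character", layerB = "character",
                 rMin = "numeric", pMax = "numeric", mode = "character")
)

setValidity("BipartiteCorrelationNetwork", function(object) {
  msg <- character()
  need <- c("source_id", "source_layer", "target_id", "target_layer",
            "pearson_r", "p_value")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, sprintf("edges must have columns: %s", paste(need, collapse = ", ")))
  if (!object@mode %in% c("absolute", "signed"))
    msg <- c(msg, "mode must be 'absolute' or 'signed'")
  if (nrow(object@edges) > 0 && all(need %in% names(object@edges))) {
    r <- object@edges$pearson_r
    ok <- if (object@mode == "absolute") abs(r) > object@rMin else r > object@rMin
    if (!all(ok))
      msg <- c(msg, "an edge violates the recorded r threshold")
    if (!is.na(object@pMax) && !all(object@edges$p_value < object@pMax))
      msg <- c(msg, "an edge violates the recorded p threshold")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BipartiteCorrelationNetwork-accessors the edge table
#' @export
networkEdges <- function(x) x@edges

#' Accessors for BipartiteCorrelationNetwork
#' @param x a \linkS4class{BipartiteCorrelationNetwork}.
#' @name BipartiteCorrelationNetwork-accessors
NULL

#' @describeIn BipartiteCorrelationNetwork-accessors side-A (source) node ids
#' @export
sideANodes <- function(x) sort(unique(x@edges$source_id))

#' @describeIn BipartiteCorrelationNetwork-accessors side-B (target) node ids
#' @export
sideBNodes <- function(x) sort(unique(x@edges$target_id))

setMethod("show", "BipartiteCorrelationNetwork", function(object) {
  cat(sprintf(
    "BipartiteCorrelationNetwork [%s:%s]: %d x %d nodes, %d edges (%s %s > %.3g%s)\n",
    object@layerA, object@layerB,
    length(sideANodes(object)), length(sideBNodes(object)), nrow(object@edges),
    object@mode, if (object@mode == "absolute") "|r|" else "r", object@rMin,
    if (is.na(object@pMax)) "" else sprintf(", p < %.3g", object@pMax)
  ))
})
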