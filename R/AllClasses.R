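#' @import methods
NULL

VARIANT_CLASSES <- c("silent", "missense", "nonsense", "splice_site",
                     "frameshift_indel", "inframe_indel",
                     "lost_start", "lost_stop", "other")

FEATURE_NAMES <- c("silent_fraction", "nonsense_fraction",
                   "splice_site_fraction", "missense_fraction",
                   "recurrent_missense_fraction", "frameshift_indel_fraction",
                   "inframe_indel_fraction", "lost_start_stop_fraction",
                   "missense_to_silent", "non_silent_to_silent",
                   "normalized_missense_position_entropy",
                   "normalized_mutation_entropy")

EXPRESSION_UNITS <- c("FPKM", "TPM", "LOG2_TPM")

#' Gene-by-sample expression matrix with an explicit unit tag
#'
#' Thin container for an expression matrix whose rows are genes (HGNC-style
#' symbols) and whose columns are tumor samples.  The unit tag records where
#' the values sit in the FPKM -> TPM -> log2(TPM+1) preprocessing chain, so
#' that downstream steps can refuse inputs at the wrong stage.
#'
#' @slot values numeric matrix, genes x samples, with unique non-empty
#'   row and column names.
#' @slot unit one of \code{"FPKM"}, \code{"TPM"}, \code{"LOG2_TPM"}.
#'   FPKM and TPM values must be non-negative.
#'
#' @seealso [fpkmToTpm()], [preprocessExpression()], [buildKnnNetwork()]
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@unit) != 1L || !object@unit %in% EXPRESSION_UNITS)
    msg <- c(msg, sprintf("'unit' must be one of %s",
                          paste(EXPRESSION_UNITS, collapse = ", ")))
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have gene row names and sample column names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (length(object@unit) == 1L && object@unit %in% c("FPKM", "TPM") &&
      is.numeric(v) && length(v) && min(v) < 0)
    msg <- c(msg, sprintf("%s values must be non-negative", object@unit))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with row and column names.
#' @param unit expression unit, one of \code{"FPKM"}, \code{"TPM"},
#'   \code{"LOG2_TPM"}.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 1, 8), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionMatrix(m, "FPKM")
#' @export
ExpressionMatrix <- function(values, unit = c("FPKM", "TPM", "LOG2_TPM")) {
  unit <- match.arg(unit)
  new("ExpressionMatrix", values = as.matrix(values), unit = unit)
}

#' Directed k-nearest-neighbor gene co-expression network
#'
#' For every gene, the k genes with the largest Pearson correlation to it
#' (self excluded), in strictly rank order.  The network is stored directed:
#' each gene owns its ordered neighbor list, which is exactly what the
#' tensorization step consumes.
#'
#' @slot k integer neighbor count.
#' @slot neighbors character matrix, genes x k; row i holds gene i's
#'   neighbors in descending-correlation order.
#' @slot weights numeric matrix, genes x k, the matching correlations;
#'   non-increasing along each row.
#'
#' @seealso [buildKnnNetwork()], [neighborsOf()]
#' @export
setClass("SimilarityNetwork",
         representation(k = "integer", neighbors = "matrix",
                        weights = "matrix"))

setValidity("SimilarityNetwork", function(object) {
  msg <- character()
  k <- object@k
  nb <- object@neighbors
  w <- object@weights
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (!is.character(nb)) msg <- c(msg, "'neighbors' must be character")
  if (!identical(dim(nb), dim(w)))
    msg <- c(msg, "'neighbors' and 'weights' dimensions differ")
  if (length(k) == 1L && !is.na(k) && ncol(nb) != k)
    msg <- c(msg, "'neighbors' must have k columns")
  if (is.null(rownames(nb)))
    msg <- c(msg, "'neighbors' must have gene row names")
  else {
    if (any(nb == rownames(nb)[row(nb)]))
      msg <- c(msg, "a gene appears in its own neighbor list")
    if (nrow(w) && any(w[, -1L, drop = FALSE] -
                       w[, -ncol(w), drop = FALSE] > 1e-12))
      msg <- c(msg, "weights must be non-increasing along each row")
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene CNN input matrix (gene + ranked neighbors)
#'
#' The 2k x n_f matrix fed to the convolutional classifier: the center
#' gene's scaled feature vector interleaved with its k neighbors' vectors,
#' so that each stride-2 convolution window pairs the gene with one
#' neighbor.
#'
#' @slot geneId center gene symbol.
#' @slot values numeric matrix with 2k rows and n_f columns.
#' @slot k integer neighbor count.
#' @slot nF integer feature dimension (12 for the mutation feature set).
#'
#' @seealso [buildTensor()]
#' @export
setClass("FeatureTensor",
         representation(geneId = "character", values = "matrix",
                        k = "integer", nF = "integer"))

setValidity("FeatureTensor", function(object) {
  msg <- character()
  if (nrow(object@values) != 2L * object@k)
    msg <- c(msg, "tensor must have exactly 2k rows")
  if (ncol(object@values) != object@nF)
    msg <- c(msg, "tensor must have n_f columns")
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "'geneId' must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Per-feature standardization parameters
#'
#' Column means and standard deviations learned from the training genes
#' only; applying the scaler centers and rescales each feature.  A feature
#' with zero spread gets scale 1, so constant columns map to zero rather
#' than NaN.
#'
#' @slot center named numeric vector of feature means.
#' @slot scale named numeric vector of feature standard deviations
#'   (zeros replaced by 1).
#'
#' @seealso [fitScaler()], [applyScaler()]
#' @export
setClass("FeatureScaler",
         representation(center = "numeric", scale = "numeric"))

setValidity("FeatureScaler", function(object) {
  msg <- character()
  if (length(object@center) != length(object@scale))
    msg <- c(msg, "'center' and 'scale' lengths differ")
  if (any(object@scale <= 0))
    msg <- c(msg, "'scale' entries must be positive")
  if (length(msg)) msg else TRUE
})

#' One-dimensional convolutional driver-gene classifier
#'
#' Holds the architecture configuration, the input geometry (k, n_f), the
#' layer weights, and the training history.  Built untrained by
#' [buildModel()], fitted by [trainModel()], applied by [predictProba()].
#'
#' @slot config list, see [cnnConfig()].
#' @slot k integer neighbor count of the input tensors.
#' @slot nF integer feature dimension of the input tensors.
#' @slot weights list of layer parameter matrices/vectors.
#' @slot history data.frame of per-epoch training/validation loss
#'   (empty until trained).
#' @slot trained logical.
#'
#' @export
setClass("DriverCNN",
         representation(config = "list", k = "integer", nF = "integer",
                        weights = "list", history = "data.frame",
                        trained = "logical"))
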