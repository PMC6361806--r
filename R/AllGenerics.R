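#' Gene identifiers of an object
#' @param x an object holding per-gene data.
#' @return character vector of gene symbols.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object holding per-sample data.
#' @return character vector of sample barcodes.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression unit tag
#' @param x an [ExpressionMatrix-class].
#' @return \code{"FPKM"}, \code{"TPM"} or \code{"LOG2_TPM"}.
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' Underlying expression matrix
#' @param x an [ExpressionMatrix-class].
#' @return the genes x samples numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Underlying tensor matrix
#' @param x a [FeatureTensor-class].
#' @return the 2k x n_f numeric matrix.
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' Neighbor count of a network or tensor
#' @param x a [SimilarityNetwork-class], [FeatureTensor-class] or
#'   [DriverCNN-class].
#' @return integer k.
#' @export
setGeneric("netK", function(x) standardGeneric("netK"))

#' Ranked neighbors of one gene
#' @param x a [SimilarityNetwork-class].
#' @param gene gene symbol.
#' @return data.frame with columns \code{neighbor} and \code{pcc}, in
#'   descending-correlation order.
#' @export
setGeneric("neighborsOf", function(x, gene) standardGeneric("neighborsOf"))

#' @describeIn ExpressionMatrix-class gene row names.
#' @param x object.
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn ExpressionMatrix-class sample column names.
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn ExpressionMatrix-class the unit tag.
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(x) x@unit)

#' @describeIn ExpressionMatrix-class the numeric matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              object@unit, nrow(object@values), ncol(object@values)))
})

#' @describeIn SimilarityNetwork-class source-gene row names.
#' @param x object.
#' @export
setMethod("geneIds", "SimilarityNetwork", function(x) rownames(x@neighbors))

#' @describeIn SimilarityNetwork-class the neighbor count k.
#' @export
setMethod("netK", "SimilarityNetwork", function(x) x@k)

#' @describeIn SimilarityNetwork-class ranked neighbors of one gene.
#' @param gene gene symbol.
#' @export
setMethod("neighborsOf", "SimilarityNetwork", function(x, gene) {
  if (!gene %in% rownames(x@neighbors))
    stop("gene '", gene, "' is not in the network", call. = FALSE)
  data.frame(neighbor = x@neighbors[gene, ], pcc = x@weights[gene, ],
             row.names = NULL)
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat(sprintf("SimilarityNetwork: %d genes, k = %d (directed kNN, PCC)\n",
              nrow(object@neighbors), object@k))
})

#' @describeIn FeatureTensor-class the center gene symbol.
#' @param x object.
#' @export
setMethod("geneIds", "FeatureTensor", function(x) x@geneId)

#' @describeIn FeatureTensor-class the 2k x n_f matrix.
#' @export
setMethod("tensorValues", "FeatureTensor", function(x) x@values)

#' @describeIn FeatureTensor-class the neighbor count k.
#' @export
setMethod("netK", "FeatureTensor", function(x) x@k)

setMethod("show", "FeatureTensor", function(object) {
  cat(sprintf("FeatureTensor '%s': %d x %d (k = %d)\n", object@geneId,
              nrow(object@values), ncol(object@values), object@k))
})

setMethod("show", "FeatureScaler", function(object) {
  cat(sprintf("FeatureScaler over %d features\n", length(object@center)))
})

#' @describeIn DriverCNN-class the neighbor count the model expects.
#' @param x object.
#' @export
setMethod("netK", "DriverCNN", function(x) x@k)

setMethod("show", "DriverCNN", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("DriverCNN (%s): %d CONV-POOL (%d filters) + %d FC ",
                     "(%d nodes), input %d x %d\n"),
              if (object@trained) "trained" else "untrained",
              cfg$ncl, cfg$ncn, cfg$nfl, cfg$nfn, 2L * object@k, object@nF))
})
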